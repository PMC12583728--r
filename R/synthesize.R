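#' Describe one synthetic buzz
#'
#' Convenience constructor for [BuzzSpec-class]. A buzz is a sum of
#' `nHarmonics` harmonics of `f0` with geometric amplitude decay, shaped by
#' an attack-sustain-release (or rectangular) envelope and scaled so the
#' noise-free peak equals `peakAccel`. Three harmonics with decay 0.5 give
#' a spectrum whose energy is not concentrated at f0, which is exactly what
#' a fundamental-frequency (rather than spectral-peak) estimator must cope
#' with.
#'
#' @param onset onset time in seconds.
#' @param duration buzz duration in seconds.
#' @param f0 fundamental frequency in Hz (0, 1000].
#' @param nHarmonics number of harmonics (default 3).
#' @param harmonicDecay amplitude ratio between consecutive harmonics
#'   (default 0.5).
#' @param peakAccel peak acceleration in m s^-2 (default 100).
#' @param envelope "asr" (default) or "rectangular". The default rises over
#'   10 % of the duration, sustains for 80 % and releases over 10 %, which
#'   avoids the broadband onset click a rectangular envelope would add.
#' @param attackFrac,releaseFrac attack/release fractions for "asr"; the
#'   rendered attack and release are capped at 50 ms, since real buzz
#'   onsets take tens of milliseconds regardless of buzz length.
#' @param f0JitterSd SD in Hz of a per-buzz random offset applied to f0.
#' @return a [BuzzSpec-class] object.
#' @examples
#' buzzSpec(onset = 1, duration = 2, f0 = 217)
#' @export
buzzSpec <- function(onset, duration, f0, nHarmonics = 3L,
                     harmonicDecay = 0.5, peakAccel = 100,
                     envelope = c("asr", "rectangular"),
                     attackFrac = 0.1, releaseFrac = 0.1,
                     f0JitterSd = 0) {
  envelope <- match.arg(envelope)
  new("BuzzSpec",
    onset = as.numeric(onset), duration = as.numeric(duration),
    f0 = as.numeric(f0), nHarmonics = as.integer(nHarmonics),
    harmonicDecay = as.numeric(harmonicDecay),
    peakAccel = as.numeric(peakAccel), envelope = envelope,
    attackFrac = as.numeric(attackFrac),
    releaseFrac = as.numeric(releaseFrac),
    f0JitterSd = as.numeric(f0JitterSd)
  )
}

#' Plan a synthetic recording
#'
#' @param buzzes list of [BuzzSpec-class] objects (pairwise disjoint in
#'   time).
#' @param samplingRate sampling rate in Hz; the field protocol used 20480.
#' @param totalDuration recording length in seconds; the protocol recorded
#'   60 s per bee.
#' @param noiseSd SD of additive Gaussian background noise, m s^-2.
#' @param seed integer seed for noise and frequency jitter.
#' @return a [RecordingPlan-class] object.
#' @examples
#' plan <- recordingPlan(
#'   buzzes = list(buzzSpec(1, 2, 217)),
#'   totalDuration = 5, noiseSd = 0.5
#' )
#' @export
recordingPlan <- function(buzzes = list(), samplingRate = 20480,
                          totalDuration = 60, noiseSd = 0, seed = 1L) {
  new("RecordingPlan",
    buzzes = buzzes, samplingRate = as.numeric(samplingRate),
    totalDuration = as.numeric(totalDuration),
    noiseSd = as.numeric(noiseSd), seed = as.integer(seed)
  )
}

setMethod("show", "RecordingPlan", function(object) {
  cat("RecordingPlan: ", length(object@buzzes), " buzzes over ",
    object@totalDuration, " s @ ", object@samplingRate,
    " Hz, noise SD ", object@noiseSd, " m s^-2, seed ", object@seed, "\n",
    sep = ""
  )
})

# Evaluate expr with a temporary RNG state so callers' streams are intact.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Synthesize a recording from a plan
#'
#' Renders each buzz as a sum of harmonics with geometric decay, applies
#' the envelope, rescales the noise-free burst so its maximum absolute
#' value equals the buzz's `peakAccel`, and adds Gaussian background noise
#' everywhere. Identical plans (including seed) give bit-identical traces.
#'
#' @param plan a [RecordingPlan-class].
#' @return a [Waveform-class] of length `totalDuration * samplingRate`.
#' @examples
#' w <- synthesizeRecording(recordingPlan(
#'   list(buzzSpec(0.5, 1, 200)), totalDuration = 2
#' ))
#' @export
synthesizeRecording <- function(plan) {
  stopifnot(is(plan, "RecordingPlan"))
  validObject(plan)
  fs <- plan@samplingRate
  n <- round(plan@totalDuration * fs)
  withSeed(plan@seed, {
    x <- numeric(n)
    for (b in plan@buzzes) {
      i0 <- floor(b@onset * fs) + 1L
      i1 <- min(n, floor((b@onset + b@duration) * fs))
      if (i1 < i0) next
      tt <- (seq(i0, i1) - i0) / fs
      f <- b@f0 + if (b@f0JitterSd > 0) stats::rnorm(1, 0, b@f0JitterSd) else 0
      phase <- stats::runif(1, 0, 2 * pi)
      y <- numeric(length(tt))
      for (h in seq_len(b@nHarmonics)) {
        y <- y + b@harmonicDecay^(h - 1) * sin(2 * pi * h * f * tt + h * phase)
      }
      y <- y * buzzEnvelope(length(tt), b, fs)
      m <- max(abs(y))
      if (m > 0) y <- y * (b@peakAccel / m)
      x[i0:i1] <- x[i0:i1] + y
    }
    if (plan@noiseSd > 0) x <- x + stats::rnorm(n, 0, plan@noiseSd)
    Waveform(x, fs, sprintf("synth-seed%d", plan@seed))
  })
}

buzzEnvelope <- function(len, spec, fs) {
  if (spec@envelope == "rectangular" || len < 4L) return(rep(1, len))
  # attack/release are fractions of the buzz but capped at 50 ms: insect
  # buzz onsets take tens of milliseconds regardless of buzz length
  cap <- max(1L, round(0.05 * fs))
  na <- max(1L, min(round(spec@attackFrac * len), cap))
  nr <- max(1L, min(round(spec@releaseFrac * len), cap))
  env <- rep(1, len)
  env[seq_len(na)] <- seq(0, 1, length.out = na + 1L)[-1]
  env[(len - nr + 1L):len] <- seq(1, 0, length.out = nr + 1L)[-1]
  env
}

#' Ground-truth manifest for a recording plan
#'
#' One row per buzz with onset, duration, fundamental frequency and peak
#' acceleration, ordered by onset — the scoring table that segmentation
#' and feature extraction are compared against.
#'
#' @param plan a [RecordingPlan-class].
#' @return a data.frame with columns onset_s, duration_s, f0_hz,
#'   peak_accel_ms2.
#' @export
groundTruthManifest <- function(plan) {
  stopifnot(is(plan, "RecordingPlan"))
  if (!length(plan@buzzes)) {
    return(data.frame(
      onset_s = numeric(), duration_s = numeric(),
      f0_hz = numeric(), peak_accel_ms2 = numeric()
    ))
  }
  man <- data.frame(
    onset_s = vapply(plan@buzzes, slot, numeric(1), "onset"),
    duration_s = vapply(plan@buzzes, slot, numeric(1), "duration"),
    f0_hz = vapply(plan@buzzes, slot, numeric(1), "f0"),
    peak_accel_ms2 = vapply(plan@buzzes, slot, numeric(1), "peakAccel")
  )
  man <- man[order(man$onset_s), , drop = FALSE]
  rownames(man) <- NULL
  man
}

#' Reference fixed-effect sets for buzz biomechanics
#'
#' Point estimates from mixed models of per-bee mean defensive-buzz
#' properties in Arctic bumblebees, used as the default generating values
#' of the simulator: fundamental frequency (Hz) or peak acceleration
#' (m s^-2) as a function of air or thorax temperature (deg C, linear and
#' quadratic), body mass (g) and distribution class (specialist vs
#' generalist contrast, specialist coded +1).
#'
#' @param model which effect set: frequency ~ air temperature
#'   ("freq_air"), acceleration ~ air temperature with quadratic
#'   ("accel_air"), frequency ~ thorax temperature with quadratic
#'   ("freq_thorax"), or acceleration ~ thorax temperature with quadratic
#'   ("accel_thorax").
#' @return named numeric vector of coefficients (response units per
#'   predictor unit).
#' @examples
#' referenceEffects("freq_air")
#' @export
referenceEffects <- function(model = c("freq_air", "accel_air",
                                       "freq_thorax", "accel_thorax")) {
  model <- match.arg(model)
  switch(model,
    freq_air = c(intercept = 185.02, t_air = 1.48, distribution = 0.91),
    accel_air = c(
      intercept = 27.00, t_air = 7.95, t_air_sq = -0.17,
      mass = 602.29, distribution = -34.13
    ),
    freq_thorax = c(
      intercept = 187.16, t_thorax = -6.17, t_thorax_sq = 0.21,
      distribution = 8.35
    ),
    accel_thorax = c(
      intercept = -241.64, t_thorax = 19.65, t_thorax_sq = -0.26,
      mass = 546.89, distribution = -28.52
    )
  )
}

#' Population parameters for the bee-level simulator
#'
#' Bundles the generating model of [simulateBeeDataset()]: fixed effects,
#' random-intercept SDs for species and caste, residual SD, the species and
#' caste roster, the mass range and the temperature design. The defaults
#' mirror the study system: 15 species (6 cold-habitat specialists, 9
#' generalists), workers and drones, masses 0.05-0.6 g, field air
#' temperatures uniform on 13.0-21.1 deg C, lab air temperatures on the
#' discrete 5-35 deg C ladder in 5 deg C steps, and thorax temperatures
#' spanning 16-44 deg C.
#'
#' @param fixedEffects named numeric vector; recognised names are
#'   intercept, t_air, t_air_sq, t_thorax, t_thorax_sq, mass,
#'   distribution. See [referenceEffects()].
#' @param sdSpecies,sdCaste SDs of the species and caste random
#'   intercepts (response units, >= 0).
#' @param sdResidual residual SD (response units, > 0 unless exactly 0 for
#'   noise-free checks).
#' @param nSpecies number of species (default 15).
#' @param nSpecialist how many species are cold-habitat specialists
#'   (default 6).
#' @param castes caste roster (default workers and drones, the castes with
#'   thorax temperature measurements).
#' @param massRange range of body mass in g.
#' @param airDesign "field", "lab", "combined" (field and lab bees in the
#'   study's 96:119 proportion), or a numeric vector of air temperatures
#'   to sample from.
#' @param thoraxRange range of thorax temperatures when no air-thorax link
#'   is supplied.
#' @param thoraxLink optional named list (lower, upper, midpoint, scale,
#'   noiseSd) generating thorax temperature from air temperature through
#'   the four-parameter logistic of [fitSigmoid()].
#' @return a validated list of class "PopulationParams".
#' @export
populationParams <- function(fixedEffects = referenceEffects("freq_air"),
                             sdSpecies = 15, sdCaste = 5, sdResidual = 30,
                             nSpecies = 15L, nSpecialist = 6L,
                             castes = c("worker", "drone"),
                             massRange = c(0.05, 0.6),
                             airDesign = "combined",
                             thoraxRange = c(16, 44),
                             thoraxLink = NULL) {
  if (sdSpecies < 0 || sdCaste < 0 || sdResidual < 0) {
    stop("random-effect and residual SDs must be >= 0")
  }
  if (any(massRange <= 0) || diff(massRange) < 0) {
    stop("massRange must be positive and non-decreasing")
  }
  if (is.character(airDesign)) {
    airDesign <- match.arg(airDesign, c("field", "lab", "combined"))
  } else if (!length(airDesign)) {
    stop("airDesign must be non-empty")
  }
  stopifnot(nSpecies >= 1L, nSpecialist <= nSpecies, length(castes) >= 1L)
  structure(
    list(
      fixedEffects = fixedEffects, sdSpecies = sdSpecies, sdCaste = sdCaste,
      sdResidual = sdResidual, nSpecies = as.integer(nSpecies),
      nSpecialist = as.integer(nSpecialist), castes = castes,
      massRange = massRange, airDesign = airDesign,
      thoraxRange = thoraxRange, thoraxLink = thoraxLink
    ),
    class = "PopulationParams"
  )
}

fourParamLogistic <- function(x, lower, upper, midpoint, scale) {
  lower + (upper - lower) / (1 + exp((midpoint - x) / scale))
}

#' Simulate a per-bee dataset with known ground truth
#'
#' Draws bees with species, caste, distribution class, mass and
#' temperatures according to the design in `params`, then generates the
#' per-bee mean response as fixed-effect linear predictor + species
#' intercept + caste intercept + residual, all Gaussian. The generating
#' draws are returned alongside (columns prefixed `gt_`) so recovery tests
#' can score fitted models against truth.
#'
#' @param params a [populationParams()] object.
#' @param nBees number of bees (>= species x castes so every level is
#'   seen).
#' @param response "frequency", "acceleration" or "duration"; names the
#'   response column.
#' @param seed integer seed.
#' @return data.frame with columns bee_id, species, caste, distribution,
#'   location, mass_g, t_air, t_thorax, the response column, and
#'   gt_linpred, gt_species_effect, gt_caste_effect, gt_residual.
#'   Attributes "fixedEffects" and "params" carry the generating values.
#' @examples
#' d <- simulateBeeDataset(populationParams(), nBees = 60, seed = 1)
#' head(d)
#' @export
simulateBeeDataset <- function(params, nBees,
                               response = c("frequency", "acceleration",
                                            "duration"),
                               seed = 1L) {
  stopifnot(inherits(params, "PopulationParams"))
  response <- match.arg(response)
  nLevels <- params$nSpecies * length(params$castes)
  if (nBees < nLevels) {
    stop("nBees must be >= nSpecies * number of castes (", nLevels, ")")
  }
  fe <- params$fixedEffects
  coefOf <- function(nm) if (nm %in% names(fe)) unname(fe[[nm]]) else 0
  withSeed(seed, {
    species <- factor(
      sprintf("sp%02d", 1 + (seq_len(nBees) - 1L) %% params$nSpecies),
      levels = sprintf("sp%02d", seq_len(params$nSpecies))
    )
    caste <- factor(
      params$castes[1 + (seq_len(nBees) - 1L) %/% params$nSpecies %%
        length(params$castes)],
      levels = params$castes
    )
    # cold-habitat specialists are a fixed attribute of the species
    specialist <- as.integer(species) <= params$nSpecialist
    distribution <- factor(ifelse(specialist, "specialist", "generalist"),
      levels = c("generalist", "specialist")
    )
    mass <- stats::runif(nBees, params$massRange[1], params$massRange[2])
    if (is.character(params$airDesign)) {
      labSteps <- seq(5, 35, by = 5)
      tair <- switch(params$airDesign,
        field = stats::runif(nBees, 13.0, 21.1),
        lab = sample(labSteps, nBees, replace = TRUE),
        combined = {
          nField <- round(nBees * 96 / 215)
          loc <- c(rep("field", nField), rep("lab", nBees - nField))
          ifelse(loc == "field",
            stats::runif(nBees, 13.0, 21.1),
            sample(labSteps, nBees, replace = TRUE)
          )
        }
      )
      location <- if (identical(params$airDesign, "combined")) {
        c(rep("field", round(nBees * 96 / 215)),
          rep("lab", nBees - round(nBees * 96 / 215)))
      } else {
        rep(params$airDesign, nBees)
      }
    } else {
      tair <- sample(params$airDesign, nBees, replace = TRUE)
      location <- rep("custom", nBees)
    }
    if (!is.null(params$thoraxLink)) {
      lk <- params$thoraxLink
      tth <- fourParamLogistic(tair, lk$lower, lk$upper, lk$midpoint,
        lk$scale)
      if (!is.null(lk$noiseSd) && lk$noiseSd > 0) {
        tth <- tth + stats::rnorm(nBees, 0, lk$noiseSd)
      }
    } else {
      tth <- stats::runif(nBees, params$thoraxRange[1], params$thoraxRange[2])
    }
    linpred <- coefOf("intercept") +
      coefOf("t_air") * tair + coefOf("t_air_sq") * tair^2 +
      coefOf("t_thorax") * tth + coefOf("t_thorax_sq") * tth^2 +
      coefOf("mass") * mass +
      coefOf("distribution") * as.numeric(distribution == "specialist")
    bSpecies <- stats::rnorm(params$nSpecies, 0, params$sdSpecies)
    bCaste <- stats::rnorm(length(params$castes), 0, params$sdCaste)
    resid <- stats::rnorm(nBees, 0, params$sdResidual)
    y <- linpred + bSpecies[as.integer(species)] +
      bCaste[as.integer(caste)] + resid
    out <- data.frame(
      bee_id = sprintf("bee%03d", seq_len(nBees)),
      species = species, caste = caste, distribution = distribution,
      location = location, mass_g = mass, t_air = tair, t_thorax = tth,
      gt_linpred = linpred,
      gt_species_effect = bSpecies[as.integer(species)],
      gt_caste_effect = bCaste[as.integer(caste)],
      gt_residual = resid
    )
    out[[response]] <- y
    attr(out, "fixedEffects") <- fe
    attr(out, "params") <- params
    attr(out, "seed") <- seed
    out
  })
}

#' Simulate bees under a known mass-acceleration power law
#'
#' Generates per-bee masses and peak accelerations on
#' `accel = k * mass^exponent` with multiplicative lognormal noise, the
#' generating model behind the allometric-scaling tests (isometry of the
#' thoracic muscles predicts exponent 0.67).
#'
#' @param nBees number of bees.
#' @param exponent generating scaling exponent (default 0.67).
#' @param k multiplicative constant, m s^-2 at 1 g.
#' @param sdLog SD of the lognormal noise on the natural-log scale.
#' @param massRange mass range in g.
#' @param seed integer seed.
#' @return data.frame with columns mass_g, peak_accel_ms2.
#' @export
simulateAllometricBees <- function(nBees, exponent = 0.67, k = 600,
                                   sdLog = 0.3, massRange = c(0.05, 0.6),
                                   seed = 1L) {
  withSeed(seed, {
    mass <- stats::runif(nBees, massRange[1], massRange[2])
    accel <- k * mass^exponent * exp(stats::rnorm(nBees, 0, sdLog))
    data.frame(mass_g = mass, peak_accel_ms2 = accel)
  })
}

#' Simulate air and thorax temperatures from a sigmoidal link
#'
#' Generates per-bee air temperatures over the combined field-lab range
#' and thorax temperatures from the four-parameter logistic plus Gaussian
#' noise — the generating analogue of the thermoregulation comparison.
#'
#' @param nBees number of bees.
#' @param lower,upper,midpoint,scale sigmoid parameters in deg C.
#' @param noiseSd SD of thorax-temperature noise in deg C.
#' @param airRange range of air temperatures sampled uniformly.
#' @param seed integer seed.
#' @return data.frame with columns t_air, t_thorax.
#' @export
simulateThermoregBees <- function(nBees, lower = 25, upper = 40,
                                  midpoint = 20, scale = 3, noiseSd = 2,
                                  airRange = c(5, 35), seed = 1L) {
  withSeed(seed, {
    air <- stats::runif(nBees, airRange[1], airRange[2])
    th <- fourParamLogistic(air, lower, upper, midpoint, scale) +
      stats::rnorm(nBees, 0, noiseSd)
    data.frame(t_air = air, t_thorax = th)
  })
}
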