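# Polynomial rolling hash of a config, so every output can carry a short
# fingerprint (stays below 2^31 to remain exact in doubles).
configHash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Configure an end-to-end synthetic study run
#'
#' Bundles everything [runPipeline()] needs: seed, output directory,
#' which stages to run, the synthetic scenario (recordings and bee-level
#' dataset), extraction settings, model specs, and bootstrap settings.
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @param outDir output directory (created if absent).
#' @param stages subset of c("synth", "extract", "model", "report"), run
#'   in that order.
#' @param nRecordings number of synthetic buzz recordings to render.
#' @param recordingDuration length of each recording in seconds.
#' @param nBees number of bees in the simulated per-bee dataset.
#' @param params a [populationParams()] for the bee-level simulator.
#' @param extraction an [extractionConfig()].
#' @param models named list of [modelSpec()] objects to fit.
#' @param nBoot bootstrap replicates for the thermal peak (0 to skip).
#' @return a list of class "PipelineConfig".
#' @export
pipelineConfig <- function(seed = 1L, outDir = tempfile("thermobuzz-run-"),
                           stages = c("synth", "extract", "model", "report"),
                           nRecordings = 3L, recordingDuration = 20,
                           nBees = 215L,
                           params = populationParams(
                             fixedEffects = referenceEffects("accel_air"),
                             sdResidual = 60
                           ),
                           extraction = extractionConfig(),
                           models = list(
                             tpc_air = modelSpec("acceleration",
                               c("t_air", "t_air_sq", "mass_g",
                                 "distribution"))
                           ),
                           nBoot = 200L) {
  stages <- match.arg(stages, c("synth", "extract", "model", "report"),
    several.ok = TRUE)
  structure(
    list(
      seed = as.integer(seed), outDir = outDir, stages = stages,
      nRecordings = as.integer(nRecordings),
      recordingDuration = recordingDuration, nBees = as.integer(nBees),
      params = params, extraction = extraction, models = models,
      nBoot = as.integer(nBoot)
    ),
    class = "PipelineConfig"
  )
}

#' Write or read a pipeline configuration as YAML
#'
#' Serialises the scalar settings, the population parameters and the
#' model specs of a [pipelineConfig()] to a structured text file, and
#' reads one back. Function-valued fields (data filters) are not
#' serialisable and must be re-attached in code.
#'
#' @param config a [pipelineConfig()].
#' @param path YAML file path.
#' @return `writePipelineConfig()` returns `path` invisibly;
#'   `readPipelineConfig()` returns a [pipelineConfig()].
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  y <- list(
    seed = config$seed, stages = config$stages,
    nRecordings = config$nRecordings,
    recordingDuration = config$recordingDuration,
    nBees = config$nBees, nBoot = config$nBoot,
    params = unclass(config$params),
    extraction = unclass(config$extraction),
    models = lapply(config$models, function(m) {
      list(response = m$response, fixed = m$fixed,
        randomIntercepts = m$randomIntercepts)
    })
  )
  y$params$fixedEffects <- as.list(config$params$fixedEffects)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @param outDir output directory for the run (not stored in the file).
#' @export
readPipelineConfig <- function(path, outDir = tempfile("thermobuzz-run-")) {
  y <- yaml::read_yaml(path)
  pp <- y$params
  params <- populationParams(
    fixedEffects = unlist(pp$fixedEffects),
    sdSpecies = pp$sdSpecies, sdCaste = pp$sdCaste,
    sdResidual = pp$sdResidual, nSpecies = pp$nSpecies,
    nSpecialist = pp$nSpecialist, castes = unlist(pp$castes),
    massRange = unlist(pp$massRange), airDesign = unlist(pp$airDesign),
    thoraxRange = unlist(pp$thoraxRange), thoraxLink = pp$thoraxLink
  )
  ex <- y$extraction
  pipelineConfig(
    seed = y$seed, outDir = outDir, stages = unlist(y$stages),
    nRecordings = y$nRecordings,
    recordingDuration = y$recordingDuration, nBees = y$nBees,
    params = params,
    extraction = do.call(extractionConfig, ex),
    models = lapply(y$models, function(m) {
      modelSpec(m$response, unlist(m$fixed),
        randomIntercepts = unlist(m$randomIntercepts) %||% character())
    }),
    nBoot = y$nBoot
  )
}

#' Run the synthetic study pipeline
#'
#' Executes the requested stages in order: `synth` renders seeded
#' recordings (WAV plus ground-truth manifest CSV) and a simulated
#' per-bee dataset; `extract` runs the buzz-extraction pipeline over the
#' recordings and writes per-buzz and per-bee CSVs; `model` fits the
#' configured models plus the allometric and thermoregulation analyses;
#' `report` renders figures from the stored outputs. A stage failure
#' aborts the downstream stages and is recorded in the returned manifest.
#' Identical config and seed give byte-identical tables.
#'
#' @param config a [pipelineConfig()].
#' @return the run manifest (list), also written to
#'   `manifest.json` in `outDir`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config_hash = configHash(config[setdiff(names(config), "outDir")]),
    seed = config$seed,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages_requested = config$stages,
    stages_completed = character(),
    outputs = character(), warnings = character(),
    r_version = as.character(getRversion())
  )
  addOut <- function(path) {
    manifest$outputs <<- c(manifest$outputs, basename(path))
    path
  }
  aborted <- FALSE
  for (stage in config$stages) {
    if (aborted) break
    res <- tryCatch(
      {
        switch(stage,
          synth = {
            for (i in seq_len(config$nRecordings)) {
              plan <- defaultRecordingPlan(config, i)
              w <- synthesizeRecording(plan)
              writeWaveformWav(w, addOut(file.path(config$outDir,
                sprintf("recording%02d.wav", i))))
              utils::write.csv(groundTruthManifest(plan),
                addOut(file.path(config$outDir,
                  sprintf("recording%02d_manifest.csv", i))),
                row.names = FALSE)
            }
            bees <- simulateBeeDataset(config$params, config$nBees,
              response = "acceleration", seed = config$seed)
            utils::write.csv(bees,
              addOut(file.path(config$outDir, "bees.csv")),
              row.names = FALSE)
          },
          extract = {
            wavs <- list.files(config$outDir, "^recording[0-9]+\\.wav$",
              full.names = TRUE)
            if (!length(wavs)) stop("no recordings to extract from")
            feats <- do.call(rbind, lapply(seq_along(wavs), function(i) {
              f <- extractFeatures(readWaveformWav(wavs[i]),
                config$extraction)
              if (nrow(f)) cbind(bee_id = sprintf("rec%02d", i), f) else NULL
            }))
            utils::write.csv(feats,
              addOut(file.path(config$outDir, "buzz_features.csv")),
              row.names = FALSE)
            means <- do.call(rbind, lapply(split(feats, feats$bee_id),
              function(d) perBeeMeans(d, d$bee_id[1])))
            utils::write.csv(means,
              addOut(file.path(config$outDir, "per_bee_means.csv")),
              row.names = FALSE)
          },
          model = {
            bees <- utils::read.csv(file.path(config$outDir, "bees.csv"))
            for (nm in names(config$models)) {
              sp <- config$models[[nm]]
              fit <- fitVibrationModel(sp, bees)
              utils::write.csv(fit@coefficients,
                addOut(file.path(config$outDir,
                  sprintf("model_%s_coefficients.csv", nm))),
                row.names = FALSE)
              utils::write.csv(type3Table(fit),
                addOut(file.path(config$outDir,
                  sprintf("model_%s_type3.csv", nm))),
                row.names = FALSE)
              hasQuad <- any(grepl("_sq$", sp$fixed))
              if (hasQuad && config$nBoot > 0) {
                pk <- bootstrapPeak(bees, sp, nBoot = config$nBoot,
                  seed = config$seed)
                jsonlite::write_json(
                  list(x_peak = pk@xPeak, y_peak = pk@yPeak,
                    x_ci = pk@xCi, y_ci = pk@yCi, n_boot = pk@nBoot,
                    n_failed = pk@nFailed, seed = pk@seed),
                  addOut(file.path(config$outDir,
                    sprintf("model_%s_peak.json", nm))),
                  auto_unbox = TRUE, digits = NA)
                utils::write.csv(pk@replicates,
                  addOut(file.path(config$outDir,
                    sprintf("model_%s_peak_replicates.csv", nm))),
                  row.names = FALSE)
                grid <- seq(min(bees$t_air), max(bees$t_air),
                  length.out = 200)
                utils::write.csv(predictCurve(fit, grid),
                  addOut(file.path(config$outDir,
                    sprintf("model_%s_curve.csv", nm))),
                  row.names = FALSE)
              }
            }
            if (all(c("mass_g", "acceleration") %in% names(bees))) {
              al <- testSlope(fitLogLog(bees$mass_g,
                pmax(bees$acceleration, 1e-6)))
              utils::write.csv(allometrySummary(al),
                addOut(file.path(config$outDir, "allometry.csv")),
                row.names = FALSE)
            }
            if (all(c("t_air", "t_thorax") %in% names(bees))) {
              s <- fitSigmoid(bees$t_air, bees$t_thorax)
              l <- fitLinearTR(bees$t_air, bees$t_thorax)
              utils::write.csv(compareTrModels(s, l),
                addOut(file.path(config$outDir, "thermoregulation.csv")),
                row.names = FALSE)
            }
          },
          report = {
            figs <- renderReport(config$outDir)
            for (nm in names(figs)) {
              f <- file.path(config$outDir, paste0("fig_", nm, ".pdf"))
              ggplot2::ggsave(f, figs[[nm]], width = 6, height = 4)
              addOut(f)
            }
          }
        )
        TRUE
      },
      error = function(e) conditionMessage(e)
    )
    if (isTRUE(res)) {
      manifest$stages_completed <- c(manifest$stages_completed, stage)
    } else {
      manifest$warnings <- c(manifest$warnings,
        sprintf("stage '%s' failed: %s; downstream stages skipped",
          stage, res))
      aborted <- TRUE
    }
  }
  jsonlite::write_json(manifest,
    file.path(config$outDir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# Default synthetic recording for pipeline runs: a handful of buzzes with
# study-like durations and frequencies, seeded per recording.
defaultRecordingPlan <- function(config, i) {
  seed <- config$seed * 1000L + i
  withSeed(seed, {
    nBuzz <- 5L
    dur <- config$recordingDuration
    onsets <- sort(stats::runif(nBuzz, 0.5, dur - 3))
    # enforce disjoint intervals with at least 0.3 s spacing
    durs <- pmin(stats::rlnorm(nBuzz, log(0.5), 0.5),
      c(diff(onsets), dur - 0.5 - onsets[nBuzz]) - 0.3)
    keep <- durs >= 0.15
    buzzes <- lapply(which(keep), function(k) {
      buzzSpec(onsets[k], durs[k], f0 = stats::runif(1, 120, 350),
        peakAccel = stats::runif(1, 50, 300))
    })
    recordingPlan(buzzes, totalDuration = dur, noiseSd = 1,
      seed = seed)
  })
}

#' Render figures from stored pipeline outputs
#'
#' Rebuilds the report figures purely from the CSV/JSON files a previous
#' [runPipeline()] left in `outDir` (so regeneration is idempotent and no
#' number appears in a figure that is not in a stored table): the
#' thermal-performance curve with its 95 % band and peak cross, the
#' per-bee scatter, and the sigmoid-versus-linear thermoregulation
#' overlay. Missing stage outputs yield a warning and a skipped panel.
#'
#' @param outDir directory containing pipeline outputs.
#' @return named list of ggplot objects.
#' @export
renderReport <- function(outDir) {
  figs <- list()
  beesPath <- file.path(outDir, "bees.csv")
  curvePaths <- list.files(outDir, "^model_.*_curve\\.csv$",
    full.names = TRUE)
  for (cp in curvePaths) {
    nm <- sub("_curve\\.csv$", "", basename(cp))
    curve <- utils::read.csv(cp)
    g <- ggplot2::ggplot(curve, ggplot2::aes(x = grid, y = predicted)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_low, ymax = ci_high),
        alpha = 0.25) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Temperature (deg C)", y = "Predicted response")
    if (file.exists(beesPath)) {
      bees <- utils::read.csv(beesPath)
      if (all(c("t_air", "acceleration") %in% names(bees))) {
        g <- g + ggplot2::geom_point(
          data = bees,
          ggplot2::aes(x = t_air, y = acceleration),
          inherit.aes = FALSE, alpha = 0.4, size = 0.8)
      }
    }
    pkPath <- file.path(outDir, paste0(nm, "_peak.json"))
    if (file.exists(pkPath)) {
      pk <- jsonlite::read_json(pkPath, simplifyVector = TRUE)
      g <- g + ggplot2::annotate("point", x = pk$x_peak, y = pk$y_peak,
        shape = 4, size = 4, stroke = 1.2)
    }
    figs[[nm]] <- g
  }
  if (file.exists(beesPath)) {
    bees <- utils::read.csv(beesPath)
    if (all(c("t_air", "t_thorax") %in% names(bees)) &&
        file.exists(file.path(outDir, "thermoregulation.csv"))) {
      s <- fitSigmoid(bees$t_air, bees$t_thorax)
      l <- fitLinearTR(bees$t_air, bees$t_thorax)
      grid <- seq(min(bees$t_air), max(bees$t_air), length.out = 200)
      ov <- rbind(
        data.frame(t_air = grid, t_thorax = predictSigmoid(s, grid),
          model = "sigmoid"),
        data.frame(t_air = grid,
          t_thorax = l@intercept + l@slope * grid, model = "linear")
      )
      figs$thermoregulation <-
        ggplot2::ggplot(bees, ggplot2::aes(x = t_air, y = t_thorax)) +
        ggplot2::geom_point(alpha = 0.4, size = 0.8) +
        ggplot2::geom_line(data = ov,
          ggplot2::aes(linetype = model)) +
        ggplot2::labs(x = "Air temperature (deg C)",
          y = "Thorax temperature (deg C)")
    }
  }
  if (!length(figs)) warning("no pipeline outputs found in ", outDir)
  figs
}
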