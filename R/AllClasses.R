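#' @import methods
NULL

#' Waveform: a uniformly sampled acceleration trace
#'
#' Container for a single-axis accelerometer trace: acceleration samples in
#' m s^-2 at a fixed sampling rate, with an opaque source label. This is the
#' raw material of the buzz-extraction pipeline.
#'
#' @slot samples numeric vector of acceleration values (m s^-2); all finite,
#'   at least two samples.
#' @slot samplingRate sampling rate in Hz (> 0).
#' @slot sourceId character label identifying the recording.
#'
#' @seealso [Waveform()] for the constructor, [synthesizeRecording()],
#'   [extractFeatures()].
#' @exportClass Waveform
setClass("Waveform",
  representation(
    samples = "numeric",
    samplingRate = "numeric",
    sourceId = "character"
  )
)

setValidity("Waveform", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0) {
    msg <- c(msg, "samplingRate must be a single positive number")
  }
  if (length(object@samples) < 2L) {
    msg <- c(msg, "a waveform needs at least 2 samples")
  }
  if (!all(is.finite(object@samples))) {
    msg <- c(msg, "all samples must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' BuzzSpec: ground-truth description of one synthetic buzz
#'
#' One harmonic buzz burst inside a synthetic recording: onset, duration,
#' fundamental frequency, harmonic structure, amplitude and envelope. These
#' are the quantities the extraction pipeline is later scored against.
#'
#' @slot onset onset time in seconds from recording start (>= 0).
#' @slot duration buzz duration in seconds (> 0).
#' @slot f0 fundamental frequency in Hz, in (0, 1000].
#' @slot nHarmonics integer number of harmonics of f0 (>= 1).
#' @slot harmonicDecay per-harmonic amplitude ratio in (0, 1]; harmonic k has
#'   relative amplitude harmonicDecay^(k - 1).
#' @slot peakAccel peak acceleration of the noise-free buzz in m s^-2 (> 0).
#' @slot envelope "asr" (attack-sustain-release) or "rectangular".
#' @slot attackFrac,releaseFrac attack and release fractions of the buzz
#'   duration for the "asr" envelope.
#' @slot f0JitterSd per-buzz frequency jitter SD in Hz (>= 0).
#'
#' @seealso [buzzSpec()], [recordingPlan()].
#' @exportClass BuzzSpec
setClass("BuzzSpec",
  representation(
    onset = "numeric",
    duration = "numeric",
    f0 = "numeric",
    nHarmonics = "integer",
    harmonicDecay = "numeric",
    peakAccel = "numeric",
    envelope = "character",
    attackFrac = "numeric",
    releaseFrac = "numeric",
    f0JitterSd = "numeric"
  )
)

setValidity("BuzzSpec", function(object) {
  msg <- character()
  if (object@onset < 0) msg <- c(msg, "onset must be >= 0")
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@f0 <= 0 || object@f0 > 1000) {
    msg <- c(msg, "f0 must lie in (0, 1000] Hz")
  }
  if (object@nHarmonics < 1L) msg <- c(msg, "nHarmonics must be >= 1")
  if (object@harmonicDecay <= 0 || object@harmonicDecay > 1) {
    msg <- c(msg, "harmonicDecay must lie in (0, 1]")
  }
  if (object@peakAccel <= 0) msg <- c(msg, "peakAccel must be > 0")
  if (!object@envelope %in% c("asr", "rectangular")) {
    msg <- c(msg, "envelope must be 'asr' or 'rectangular'")
  }
  if (object@attackFrac < 0 || object@releaseFrac < 0 ||
      object@attackFrac + object@releaseFrac > 1) {
    msg <- c(msg, "attackFrac + releaseFrac must lie in [0, 1]")
  }
  if (object@f0JitterSd < 0) msg <- c(msg, "f0JitterSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' RecordingPlan: blueprint for one synthetic recording
#'
#' Defines a synthetic accelerometer recording: total duration, sampling
#' rate, an ordered list of non-overlapping [BuzzSpec-class] bursts, the
#' background (sensor) noise level and a seed. Defaults mirror the field
#' protocol for defensive buzzing: 60 s traces sampled at 20,480 Hz.
#'
#' @slot buzzes list of [BuzzSpec-class] objects with pairwise disjoint
#'   intervals.
#' @slot samplingRate sampling rate in Hz (default 20480).
#' @slot totalDuration recording length in seconds (default 60).
#' @slot noiseSd SD of the additive Gaussian background noise in m s^-2.
#' @slot seed integer seed used when synthesizing.
#'
#' @seealso [recordingPlan()], [synthesizeRecording()],
#'   [groundTruthManifest()].
#' @exportClass RecordingPlan
setClass("RecordingPlan",
  representation(
    buzzes = "list",
    samplingRate = "numeric",
    totalDuration = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("RecordingPlan", function(object) {
  msg <- character()
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  if (object@totalDuration <= 0) msg <- c(msg, "totalDuration must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  for (b in object@buzzes) {
    if (!is(b, "BuzzSpec")) {
      msg <- c(msg, "buzzes must all be BuzzSpec objects")
      break
    }
  }
  if (!length(msg) && length(object@buzzes)) {
    on <- vapply(object@buzzes, slot, numeric(1), "onset")
    du <- vapply(object@buzzes, slot, numeric(1), "duration")
    if (any(on + du > object@totalDuration + 1e-9)) {
      msg <- c(msg, "every buzz must end before totalDuration")
    }
    o <- order(on)
    if (length(on) > 1L &&
        any(on[o][-1] < (on + du)[o][-length(on)] - 1e-9)) {
      msg <- c(msg, "buzz intervals must be pairwise disjoint")
    }
    fmax <- vapply(object@buzzes, function(b) b@f0 * b@nHarmonics, numeric(1))
    if (any(fmax >= object@samplingRate / 2)) {
      msg <- c(msg, "all modelled harmonics must lie below Nyquist")
    }
  }
  if (length(msg)) msg else TRUE
})

#' AllometryFit: log-log scaling of peak acceleration on body mass
#'
#' Result of regressing log peak acceleration on log body mass across bees,
#' together with an F test of the fitted exponent against a reference
#' (0.67 under isometric scaling of muscle cross-sectional area).
#'
#' @slot slope fitted scaling exponent (dimensionless).
#' @slot intercept intercept on the natural-log scale.
#' @slot slopeSe standard error of the exponent.
#' @slot n number of bees.
#' @slot reference reference exponent tested against (NA before testing).
#' @slot testF F statistic of slope == reference (1, n - 2 df).
#' @slot testP p-value of that test.
#' @slot fit the underlying [stats::lm] object.
#'
#' @seealso [fitLogLog()], [testSlope()].
#' @exportClass AllometryFit
setClass("AllometryFit",
  representation(
    slope = "numeric",
    intercept = "numeric",
    slopeSe = "numeric",
    n = "integer",
    reference = "numeric",
    testF = "numeric",
    testP = "numeric",
    fit = "ANY"
  )
)

setValidity("AllometryFit", function(object) {
  msg <- character()
  if (object@n < 3L) msg <- c(msg, "n must be >= 3")
  if (!is.na(object@slopeSe) && object@slopeSe <= 0) {
    msg <- c(msg, "slopeSe must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' VibrationFit: a fitted (mixed) model of per-bee buzz properties
#'
#' Wraps a fitted model of a per-bee mean buzz property (fundamental
#' frequency, peak acceleration or duration) on mass, temperature and
#' distribution class, with species and caste random intercepts when
#' requested. Stores the coefficient table, variance components, Type III
#' table with Satterthwaite denominator degrees of freedom, and the
#' conditional R^2 (variance explained by fixed plus random effects).
#'
#' @slot spec the [modelSpec()] the model was fitted from.
#' @slot fit underlying fit: an lmerModLmerTest (mixed) or lm (fixed only).
#' @slot coefficients data.frame with term, estimate, se.
#' @slot varcomps named numeric of random-intercept variances.
#' @slot residualVar residual variance.
#' @slot type3 data.frame with term, F, df_num, df_den, p.
#' @slot conditionalR2 conditional R^2 in [0, 1].
#' @slot nBees number of bees used after filtering.
#' @slot converged logical convergence flag.
#' @slot singular logical: TRUE when a variance component hit zero.
#'
#' @seealso [fitVibrationModel()], [type3Table()], [conditionalR2()].
#' @exportClass VibrationFit
setClass("VibrationFit",
  representation(
    spec = "list",
    fit = "ANY",
    coefficients = "data.frame",
    varcomps = "numeric",
    residualVar = "numeric",
    type3 = "data.frame",
    conditionalR2 = "numeric",
    nBees = "integer",
    converged = "logical",
    singular = "logical"
  )
)

setValidity("VibrationFit", function(object) {
  msg <- character()
  if (any(object@varcomps < 0)) msg <- c(msg, "variances must be >= 0")
  if (!is.na(object@conditionalR2) &&
      (object@conditionalR2 < 0 || object@conditionalR2 > 1)) {
    msg <- c(msg, "conditionalR2 must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' PeakEstimate: bootstrap estimate of a thermal-performance peak
#'
#' Location (temperature) and height of the maximum of a fitted quadratic
#' thermal-performance curve, with percentile bootstrap confidence
#' intervals from refitting the model on resampled bees.
#'
#' @slot xPeak peak temperature in degrees C.
#' @slot yPeak predicted response at the peak.
#' @slot xCi numeric length 2: 2.5 and 97.5 percentiles of the peak
#'   temperature across bootstrap replicates.
#' @slot yCi numeric length 2: same percentiles for the peak response.
#' @slot nBoot number of requested bootstrap replicates.
#' @slot nFailed replicates dropped for non-convergence.
#' @slot seed integer seed used.
#' @slot replicates data.frame with one row per successful replicate
#'   (x_peak, y_peak), kept for audit.
#'
#' @seealso [bootstrapPeak()], [quadraticVertex()].
#' @exportClass PeakEstimate
setClass("PeakEstimate",
  representation(
    xPeak = "numeric",
    yPeak = "numeric",
    xCi = "numeric",
    yCi = "numeric",
    nBoot = "integer",
    nFailed = "integer",
    seed = "integer",
    replicates = "data.frame"
  )
)

setValidity("PeakEstimate", function(object) {
  msg <- character()
  if (object@nBoot < 1L) msg <- c(msg, "nBoot must be >= 1")
  # the CI brackets the analytic vertex up to the argmax grid resolution,
  # so validity only enforces the ordering of the endpoints
  if (length(object@xCi) == 2L && !any(is.na(object@xCi)) &&
      object@xCi[1] > object@xCi[2] + 1e-12) {
    msg <- c(msg, "xCi endpoints must be ordered")
  }
  if (length(msg)) msg else TRUE
})

#' SigmoidFit: four-parameter logistic air-to-thorax temperature fit
#'
#' Least-squares fit of thorax temperature on air temperature with the
#' four-parameter logistic
#' \deqn{T_{thorax} = lower + (upper - lower) / (1 + exp((midpoint - T_{air}) / scale))}
#' capturing a minimum operating temperature at cold air and a plateau
#' below the critical thermal maximum at warm air.
#'
#' @slot lower low-air asymptote, degrees C.
#' @slot upper high-air asymptote, degrees C.
#' @slot midpoint air temperature of fastest change, degrees C.
#' @slot scale steepness parameter, degrees C (> 0).
#' @slot rss residual sum of squares (squared degrees C).
#' @slot aic Gaussian AIC (same likelihood convention as [fitLinearTR()]).
#' @slot pseudoR2 1 - RSS/TSS (can be negative for terrible fits; <= 1).
#' @slot converged logical.
#' @slot nIter iterations used by the Levenberg-Marquardt optimizer.
#' @slot n number of bees.
#' @slot fit the underlying [minpack.lm::nlsLM] object.
#'
#' @seealso [fitSigmoid()], [compareTrModels()].
#' @exportClass SigmoidFit
setClass("SigmoidFit",
  representation(
    lower = "numeric",
    upper = "numeric",
    midpoint = "numeric",
    scale = "numeric",
    rss = "numeric",
    aic = "numeric",
    pseudoR2 = "numeric",
    converged = "logical",
    nIter = "integer",
    n = "integer",
    fit = "ANY"
  )
)

setValidity("SigmoidFit", function(object) {
  msg <- character()
  if (object@scale <= 0) msg <- c(msg, "scale must be > 0")
  if (object@upper < object@lower) msg <- c(msg, "upper must be >= lower")
  if (object@pseudoR2 > 1 + 1e-12) msg <- c(msg, "pseudoR2 must be <= 1")
  if (length(msg)) msg else TRUE
})

#' LinearTRFit: linear air-to-thorax temperature fit
#'
#' Ordinary least-squares fit of thorax temperature on air temperature,
#' the linear alternative the sigmoid is compared against.
#'
#' @slot intercept intercept, degrees C.
#' @slot slope slope, dimensionless.
#' @slot rss residual sum of squares.
#' @slot aic Gaussian AIC on the same likelihood scale as [fitSigmoid()].
#' @slot r2 coefficient of determination.
#' @slot n number of bees.
#' @slot fit the underlying [stats::lm] object.
#'
#' @seealso [fitLinearTR()], [compareTrModels()].
#' @exportClass LinearTRFit
setClass("LinearTRFit",
  representation(
    intercept = "numeric",
    slope = "numeric",
    rss = "numeric",
    aic = "numeric",
    r2 = "numeric",
    n = "integer",
    fit = "ANY"
  )
)

setValidity("LinearTRFit", function(object) {
  if (object@rss < 0) "rss must be >= 0" else TRUE
})
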