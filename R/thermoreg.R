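# Shared Gaussian AIC so linear and sigmoid fits are compared on one
# likelihood convention: n log(rss/n) + n log(2 pi) + n + 2k, with k the
# number of mean parameters plus one for the error variance.
gaussianAic <- function(rss, n, kMean) {
  n * log(rss / n) + n * log(2 * pi) + n + 2 * (kMean + 1)
}

#' Fit the sigmoidal air-to-thorax temperature relationship
#'
#' Fits the four-parameter logistic
#' `thorax = lower + (upper - lower) / (1 + exp((midpoint - air) / scale))`
#' by Levenberg-Marquardt least squares ([minpack.lm::nlsLM()]). The two
#' asymptotes express the biology: at cold air the thorax is held at a
#' minimum operating temperature, at warm air it plateaus to avoid the
#' critical thermal maximum. Default starting values come from data
#' quantiles (asymptotes from the 5th/95th thorax percentiles, midpoint
#' at the median air temperature, scale at a quarter of the air range),
#' with up to 5 seeded random restarts on failure.
#'
#' @param air,thorax per-bee air and thorax temperatures in deg C (>= 5
#'   points, air not all equal).
#' @param init optional named list/vector of starting values (lower,
#'   upper, midpoint, scale).
#' @param maxIter maximum optimizer iterations (default 200).
#' @return a [SigmoidFit-class].
#' @examples
#' d <- simulateThermoregBees(215, seed = 1)
#' fitSigmoid(d$t_air, d$t_thorax)
#' @export
fitSigmoid <- function(air, thorax, init = NULL, maxIter = 200L) {
  stopifnot(length(air) == length(thorax))
  ok <- is.finite(air) & is.finite(thorax)
  air <- air[ok]; thorax <- thorax[ok]
  if (length(air) < 5L) stop("need at least 5 points")
  if (stats::sd(air) == 0) stop("air temperatures are all equal; degenerate")
  d <- data.frame(air = air, thorax = thorax)
  if (is.null(init)) {
    init <- list(
      lower = unname(stats::quantile(thorax, 0.05)),
      upper = unname(stats::quantile(thorax, 0.95)),
      midpoint = stats::median(air),
      scale = diff(range(air)) / 4
    )
  }
  tryFit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        thorax ~ lower + (upper - lower) / (1 + exp((midpoint - air) / scale)),
        data = d, start = start,
        lower = c(lower = -Inf, upper = -Inf, midpoint = -Inf, scale = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = maxIter)
      ),
      error = function(e) NULL
    )
  }
  fit <- tryFit(init)
  if (is.null(fit)) {
    restarts <- withSeed(17L, lapply(seq_len(5L), function(i) {
      list(
        lower = init$lower + stats::rnorm(1, 0, 2),
        upper = init$upper + stats::rnorm(1, 0, 2),
        midpoint = init$midpoint + stats::rnorm(1, 0, 3),
        scale = abs(init$scale * stats::runif(1, 0.3, 3))
      )
    }))
    for (st in restarts) {
      fit <- tryFit(st)
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit)) {
    stop("sigmoid fit failed to converge after random restarts (maxIter = ",
      maxIter, ")")
  }
  p <- as.list(stats::coef(fit))
  if (p$upper < p$lower) {
    # equivalent parameterisation with swapped asymptotes and flipped scale
    # never arises with positive-scale bounds, but guard anyway
    tmp <- p$lower; p$lower <- p$upper; p$upper <- tmp
  }
  rss <- sum(stats::resid(fit)^2)
  n <- length(air)
  tss <- sum((thorax - mean(thorax))^2)
  new("SigmoidFit",
    lower = p$lower, upper = p$upper, midpoint = p$midpoint,
    scale = p$scale, rss = rss,
    aic = gaussianAic(rss, n, kMean = 4),
    pseudoR2 = 1 - rss / tss,
    converged = fit$convInfo$isConv %||% TRUE,
    nIter = as.integer(fit$convInfo$finIter %||% NA_integer_),
    n = as.integer(n), fit = fit
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict thorax temperature from a sigmoid fit
#'
#' @param object a [SigmoidFit-class].
#' @param air air temperatures in deg C.
#' @return predicted thorax temperatures.
#' @export
predictSigmoid <- function(object, air) {
  stopifnot(is(object, "SigmoidFit"))
  fourParamLogistic(air, object@lower, object@upper, object@midpoint,
    object@scale)
}

setMethod("show", "SigmoidFit", function(object) {
  cat("Sigmoidal air-thorax fit (4-parameter logistic), n = ", object@n, "\n",
    "  asymptotes ", signif(object@lower, 4), " -> ",
    signif(object@upper, 4), " deg C, midpoint ",
    signif(object@midpoint, 4), " deg C, scale ",
    signif(object@scale, 4), "\n",
    "  RSS = ", signif(object@rss, 5), ", AIC = ", signif(object@aic, 5),
    ", pseudo-R^2 = ", signif(object@pseudoR2, 3), "\n", sep = "")
})

#' Fit the linear air-to-thorax temperature relationship
#'
#' Ordinary least squares of thorax on air temperature, with AIC on the
#' same Gaussian likelihood convention as [fitSigmoid()] so the two are
#' directly comparable.
#'
#' @param air,thorax per-bee temperatures in deg C (>= 3 points).
#' @return a [LinearTRFit-class].
#' @export
fitLinearTR <- function(air, thorax) {
  stopifnot(length(air) == length(thorax))
  ok <- is.finite(air) & is.finite(thorax)
  air <- air[ok]; thorax <- thorax[ok]
  if (length(air) < 3L) stop("need at least 3 points")
  fit <- stats::lm(thorax ~ air)
  rss <- sum(stats::resid(fit)^2)
  n <- length(air)
  new("LinearTRFit",
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    rss = rss, aic = gaussianAic(rss, n, kMean = 2),
    r2 = summary(fit)$r.squared, n = as.integer(n), fit = fit
  )
}

setMethod("show", "LinearTRFit", function(object) {
  cat("Linear air-thorax fit, n = ", object@n, "\n",
    "  thorax = ", signif(object@intercept, 4), " + ",
    signif(object@slope, 4), " x air\n",
    "  RSS = ", signif(object@rss, 5), ", AIC = ", signif(object@aic, 5),
    ", R^2 = ", signif(object@r2, 3), "\n", sep = "")
})

#' Compare sigmoidal and linear thermoregulation fits
#'
#' Tabulates RSS, AIC and (pseudo-)R^2 for both models fitted to the same
#' bees and flags the AIC-preferred model. Lower RSS and AIC indicate a
#' better fit.
#'
#' @param s a [SigmoidFit-class].
#' @param l a [LinearTRFit-class].
#' @return data.frame with one row per model: model, n_params, rss, aic,
#'   r2, preferred.
#' @export
compareTrModels <- function(s, l) {
  stopifnot(is(s, "SigmoidFit"), is(l, "LinearTRFit"))
  if (s@n != l@n) stop("models were fitted on different numbers of bees")
  out <- data.frame(
    model = c("sigmoid", "linear"),
    n_params = c(4L, 2L),
    rss = c(s@rss, l@rss),
    aic = c(s@aic, l@aic),
    r2 = c(s@pseudoR2, l@r2)
  )
  out$preferred <- out$aic == min(out$aic)
  out
}
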