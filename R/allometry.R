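#' Log-log scaling of acceleration on mass
#'
#' Ordinary least squares of log(peak acceleration) on log(body mass)
#' across bees. Under isometric scaling of the thoracic muscles the
#' exponent is 0.67: force tracks muscle cross-sectional area
#' (mass^(2/3)), so acceleration at a given mass is a volume-area
#' relationship. Natural logs are used internally; the exponent is
#' invariant to the base and to rescaling mass by a constant (which moves
#' only the intercept).
#'
#' @param mass per-bee body mass in g, strictly positive.
#' @param accel per-bee mean peak acceleration in m s^-2, strictly
#'   positive.
#' @return an [AllometryFit-class] (test slots NA until [testSlope()]).
#' @examples
#' d <- simulateAllometricBees(112, seed = 1)
#' fitLogLog(d$mass_g, d$peak_accel_ms2)
#' @export
fitLogLog <- function(mass, accel) {
  stopifnot(length(mass) == length(accel))
  bad <- which(!is.finite(mass) | !is.finite(accel) | mass <= 0 | accel <= 0)
  if (length(bad)) {
    stop("mass and acceleration must be positive and finite; offending rows: ",
      paste(utils::head(bad, 10), collapse = ", "))
  }
  if (length(mass) < 3L) stop("need at least 3 bees")
  fit <- stats::lm(log(accel) ~ log(mass))
  sm <- summary(fit)$coefficients
  new("AllometryFit",
    slope = unname(sm[2, 1]), intercept = unname(sm[1, 1]),
    slopeSe = unname(sm[2, 2]), n = length(mass),
    reference = NA_real_, testF = NA_real_, testP = NA_real_, fit = fit
  )
}

#' Test the scaling exponent against a reference
#'
#' Single-constraint linear-hypothesis F test of slope == reference with
#' 1 and n - 2 degrees of freedom; algebraically the square of the t
#' statistic (slope - reference) / se.
#'
#' @param fit an [AllometryFit-class] from [fitLogLog()].
#' @param reference reference exponent (default 0.67, the isometric
#'   hypothesis).
#' @return the fit with `reference`, `testF` and `testP` slots filled.
#' @export
testSlope <- function(fit, reference = 0.67) {
  stopifnot(is(fit, "AllometryFit"))
  tstat <- (fit@slope - reference) / fit@slopeSe
  Fstat <- tstat^2
  p <- stats::pf(Fstat, 1, fit@n - 2L, lower.tail = FALSE)
  fit@reference <- reference
  fit@testF <- Fstat
  fit@testP <- p
  fit
}

setMethod("show", "AllometryFit", function(object) {
  cat("Allometric scaling fit (log-log OLS), n = ", object@n, " bees\n",
    "  exponent: ", signif(object@slope, 4),
    " (SE ", signif(object@slopeSe, 3), ")\n", sep = "")
  if (!is.na(object@reference)) {
    cat("  H0 exponent = ", object@reference, ": F(1, ", object@n - 2L,
      ") = ", signif(object@testF, 3), ", p = ", signif(object@testP, 3),
      "\n", sep = "")
  }
})

#' Summarise an allometry fit as a one-row table
#'
#' @param fit an [AllometryFit-class].
#' @return data.frame with slope, slope_se, intercept, reference, F, p, n.
#' @export
allometrySummary <- function(fit) {
  stopifnot(is(fit, "AllometryFit"))
  data.frame(
    slope = fit@slope, slope_se = fit@slopeSe, intercept = fit@intercept,
    reference = fit@reference, F = fit@testF, p = fit@testP, n = fit@n
  )
}
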