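# Fixed-effect design matrix for new data, matching a VibrationFit.
fixedDesign <- function(fit, newdata) {
  spec <- structure(fit@spec, class = "ModelSpec")
  rhs <- paste(vapply(spec$fixed, termToExpr, character(1)), collapse = " + ")
  ff <- stats::as.formula(paste("~", rhs))
  frame <- if (is(fit@fit, "merMod")) fit@fit@frame else stats::model.frame(fit@fit)
  contr <- list()
  xlev <- list()
  for (cl in names(newdata)) {
    if (cl %in% names(frame) && is.factor(frame[[cl]])) {
      xlev[[cl]] <- levels(frame[[cl]])
      newdata[[cl]] <- factor(newdata[[cl]], levels = xlev[[cl]])
      contr[[cl]] <- attr(frame[[cl]], "contrasts")
      if (is.null(contr[[cl]])) contr[[cl]] <- stats::contr.sum(length(xlev[[cl]]))
    }
  }
  stats::model.matrix(ff, data = newdata,
    contrasts.arg = if (length(contr)) contr else NULL)
}

fixedCoefVcov <- function(fit) {
  if (is(fit@fit, "merMod")) {
    list(beta = lme4::fixef(fit@fit), V = as.matrix(stats::vcov(fit@fit)))
  } else {
    list(beta = stats::coef(fit@fit), V = stats::vcov(fit@fit))
  }
}

# Default held-at covariates: continuous at their sample mean, factors at
# their first (reference) level.
defaultHeldAt <- function(fit, excludeCols) {
  frame <- if (is(fit@fit, "merMod")) fit@fit@frame else stats::model.frame(fit@fit)
  spec <- structure(fit@spec, class = "ModelSpec")
  cols <- setdiff(
    unique(unlist(lapply(spec$fixed, termColumns))), excludeCols)
  held <- list()
  for (cl in cols) {
    v <- frame[[cl]]
    held[[cl]] <- if (is.factor(v)) levels(v)[1] else mean(v)
  }
  held
}

#' Population-level prediction curve with 95% confidence band
#'
#' Predicts the response over a temperature grid at fixed values of the
#' other covariates (by default: continuous covariates at their sample
#' mean, factors at their reference level), with random effects at zero.
#' The confidence band comes from the delta method on the fixed-effect
#' covariance: se^2 = diag(X V X').
#'
#' @param fit a [VibrationFit-class].
#' @param grid strictly increasing temperature values (deg C).
#' @param temperature name of the temperature column (default the one the
#'   model uses: "t_air" or "t_thorax").
#' @param heldAt named list overriding held covariate values.
#' @param level confidence level (default 0.95).
#' @return data.frame with grid, predicted, ci_low, ci_high; attribute
#'   "extrapolated" flags grid points outside the fitted temperature
#'   range, attribute "heldAt" records the covariate values used.
#' @export
predictCurve <- function(fit, grid, temperature = NULL, heldAt = NULL,
                         level = 0.95) {
  stopifnot(is(fit, "VibrationFit"))
  if (!fit@converged) stop("fit did not converge")
  if (is.null(temperature)) {
    spec <- structure(fit@spec, class = "ModelSpec")
    cols <- unique(unlist(lapply(spec$fixed, termColumns)))
    temperature <- intersect(c("t_air", "t_thorax"), cols)[1]
    if (is.na(temperature)) stop("no temperature term in the model")
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing")
  }
  held <- defaultHeldAt(fit, temperature)
  if (!is.null(heldAt)) held[names(heldAt)] <- heldAt
  newdata <- data.frame(tmp = grid)
  names(newdata) <- temperature
  for (nm in names(held)) newdata[[nm]] <- held[[nm]]
  X <- fixedDesign(fit, newdata)
  cv <- fixedCoefVcov(fit)
  pred <- as.vector(X %*% cv$beta)
  se <- sqrt(pmax(0, rowSums((X %*% cv$V) * X)))
  q <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(
    grid = grid, predicted = pred,
    ci_low = pred - q * se, ci_high = pred + q * se
  )
  frame <- if (is(fit@fit, "merMod")) fit@fit@frame else stats::model.frame(fit@fit)
  obs <- range(frame[[temperature]])
  attr(out, "extrapolated") <- grid < obs[1] | grid > obs[2]
  attr(out, "heldAt") <- held
  out
}

#' Analytic vertex of a quadratic thermal-performance curve
#'
#' For a model with linear coefficient b and quadratic coefficient c on
#' the temperature term (c < 0 for an interior maximum), the peak sits at
#' x = -b / (2c); the peak response is the full fixed-effect prediction
#' there at the held-at covariates.
#'
#' @param fit a [VibrationFit-class] whose spec includes the quadratic
#'   temperature term.
#' @param temperature temperature column name; default auto-detected.
#' @param heldAt named list overriding held covariate values.
#' @return list with xPeak (deg C) and yPeak (response units).
#' @examples
#' # printed coefficients b = 7.95, c = -0.17 put the vertex at 23.3824
#' -7.95 / (2 * -0.17)
#' @export
quadraticVertex <- function(fit, temperature = NULL, heldAt = NULL) {
  stopifnot(is(fit, "VibrationFit"))
  spec <- structure(fit@spec, class = "ModelSpec")
  if (is.null(temperature)) {
    cols <- unique(unlist(lapply(spec$fixed, termColumns)))
    temperature <- intersect(c("t_air", "t_thorax"), cols)[1]
  }
  b <- fit@coefficients$estimate[fit@coefficients$term == temperature]
  cq <- fit@coefficients$estimate[
    fit@coefficients$term == termToExpr(paste0(temperature, "_sq"))]
  if (!length(b) || !length(cq)) {
    stop("model must contain both linear and quadratic '", temperature,
      "' terms")
  }
  if (cq >= 0) {
    stop("quadratic coefficient is non-negative: no interior maximum")
  }
  xPeak <- -b / (2 * cq)
  yPeak <- predictCurve(fit,
    grid = xPeak, temperature = temperature, heldAt = heldAt)$predicted
  list(xPeak = xPeak, yPeak = yPeak)
}

#' Bootstrap confidence interval for the thermal-performance peak
#'
#' Nonparametric bootstrap resampling bees (rows of the per-bee table,
#' the independent sampling unit after per-bee averaging) with
#' replacement. Each replicate refits the model, predicts over a grid
#' spanning the observed temperature range, and records the temperature
#' and value of the maximum. The 2.5th and 97.5th percentiles of the
#' replicate vectors give the confidence intervals. Replicates that fail
#' to converge are dropped and counted; more than 20 % failures aborts
#' with advice to inspect the model and data.
#'
#' @param data per-bee data.frame.
#' @param spec a [modelSpec()] including linear and quadratic temperature
#'   terms.
#' @param nBoot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param gridLength number of grid points over the observed range
#'   (default 200).
#' @param heldAt named list overriding held covariate values.
#' @return a [PeakEstimate-class].
#' @export
bootstrapPeak <- function(data, spec, nBoot = 1000L, seed = 1L,
                          gridLength = 200L, heldAt = NULL) {
  stopifnot(inherits(spec, "ModelSpec"))
  cols <- unique(unlist(lapply(spec$fixed, termColumns)))
  temperature <- intersect(c("t_air", "t_thorax"), cols)[1]
  if (is.na(temperature) ||
      !any(grepl("_sq$", spec$fixed[startsWith(spec$fixed, temperature)]))) {
    stop("spec must include a quadratic temperature term")
  }
  full <- fitVibrationModel(spec, data)
  vtx <- quadraticVertex(full, temperature, heldAt)
  used <- specData(spec, data)
  obs <- range(used[[temperature]])
  grid <- seq(obs[1], obs[2], length.out = gridLength)
  n <- nrow(used)
  xs <- ys <- rep(NA_real_, nBoot)
  withSeed(seed, {
    for (r in seq_len(nBoot)) {
      idx <- sample.int(n, n, replace = TRUE)
      rep <- tryCatch(
        suppressMessages(suppressWarnings(
          fitVibrationModel(spec, used[idx, , drop = FALSE]))),
        error = function(e) NULL
      )
      if (is.null(rep) || !rep@converged) next
      pc <- tryCatch(
        predictCurve(rep, grid, temperature, heldAt),
        error = function(e) NULL
      )
      if (is.null(pc)) next
      k <- which.max(pc$predicted)
      xs[r] <- grid[k]
      ys[r] <- pc$predicted[k]
    }
  })
  ok <- is.finite(xs)
  if (mean(!ok) > 0.2) {
    stop(sum(!ok), "/", nBoot, " bootstrap replicates failed to converge; ",
      "inspect the model specification and data before trusting a peak CI")
  }
  xCi <- unname(stats::quantile(xs[ok], c(0.025, 0.975)))
  yCi <- unname(stats::quantile(ys[ok], c(0.025, 0.975)))
  new("PeakEstimate",
    xPeak = vtx$xPeak, yPeak = vtx$yPeak,
    xCi = xCi, yCi = yCi, nBoot = as.integer(nBoot),
    nFailed = as.integer(sum(!ok)), seed = as.integer(seed),
    replicates = data.frame(x_peak = xs[ok], y_peak = ys[ok])
  )
}

setMethod("show", "PeakEstimate", function(object) {
  cat("Thermal-performance peak (bootstrap, ", object@nBoot,
    " replicates, ", object@nFailed, " failed)\n",
    "  peak at ", signif(object@xPeak, 4), " deg C (95% CI ",
    signif(object@xCi[1], 4), ", ", signif(object@xCi[2], 4), ")\n",
    "  peak value ", signif(object@yPeak, 5), " (95% CI ",
    signif(object@yCi[1], 5), ", ", signif(object@yCi[2], 5), ")\n",
    sep = "")
})

#' Compare air- and thorax-temperature models of the same response
#'
#' Side-by-side comparison of two fits sharing the response and data
#' subset: coefficients, conditional R^2, and AIC from a maximum
#' likelihood refit (REML AICs are not comparable across different fixed
#' effects).
#'
#' @param fitAir,fitThorax two [VibrationFit-class] objects on the same
#'   bees.
#' @return list with `summary` (model, n, conditional_r2, aic, preferred
#'   flag) and `coefficients` (both coefficient tables stacked).
#' @export
compareAirThorax <- function(fitAir, fitThorax) {
  stopifnot(is(fitAir, "VibrationFit"), is(fitThorax, "VibrationFit"))
  if (fitAir@nBees != fitThorax@nBees) {
    stop("fits use different numbers of bees; refit on a common subset")
  }
  if (fitAir@spec$response != fitThorax@spec$response) {
    stop("fits model different responses")
  }
  mlAic <- function(f) {
    if (is(f@fit, "merMod")) {
      stats::AIC(lme4::refitML(f@fit))
    } else {
      stats::AIC(f@fit)
    }
  }
  aics <- c(mlAic(fitAir), mlAic(fitThorax))
  summary <- data.frame(
    model = c("air", "thorax"),
    n = c(fitAir@nBees, fitThorax@nBees),
    conditional_r2 = c(fitAir@conditionalR2, fitThorax@conditionalR2),
    aic = aics,
    preferred = aics == min(aics)
  )
  coefs <- rbind(
    cbind(model = "air", fitAir@coefficients),
    cbind(model = "thorax", fitThorax@coefficients)
  )
  list(summary = summary, coefficients = coefs)
}
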