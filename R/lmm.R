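#' Specify a per-bee vibration model
#'
#' Describes a model of a per-bee mean buzz property: the response column,
#' the ordered fixed terms and the random intercepts. A fixed term ending
#' in `_sq` denotes the square of the corresponding column (so "t_air_sq"
#' expands to `I(t_air^2)`), and interactions are written with `:`
#' (e.g. "mass_g:t_air"). At most one temperature variable (air or thorax)
#' should appear per model.
#'
#' @param response name of the response column ("frequency",
#'   "acceleration", "duration", or a feature column such as "f0_hz").
#' @param fixed character vector of fixed-effect terms.
#' @param randomIntercepts subset of c("species", "caste"); empty for a
#'   pure fixed-effects (OLS) model.
#' @param dataFilter optional function(data) -> logical vector selecting
#'   rows (e.g. the caste-complete species subset).
#' @return a list of class "ModelSpec".
#' @examples
#' modelSpec("frequency", c("t_air", "distribution"))
#' @export
modelSpec <- function(response, fixed,
                      randomIntercepts = c("species", "caste"),
                      dataFilter = NULL) {
  stopifnot(is.character(response), length(response) == 1L,
    is.character(fixed), length(fixed) >= 1L)
  if (length(randomIntercepts)) {
    randomIntercepts <- match.arg(randomIntercepts,
      c("species", "caste"), several.ok = TRUE)
  } else {
    randomIntercepts <- character()
  }
  structure(
    list(
      response = response, fixed = fixed,
      randomIntercepts = randomIntercepts, dataFilter = dataFilter
    ),
    class = "ModelSpec"
  )
}

# "t_air_sq" -> "I(t_air^2)"; other terms pass through.
termToExpr <- function(term) {
  ifelse(grepl("_sq$", term),
    paste0("I(", sub("_sq$", "", term), "^2)"), term)
}

# Order-insensitive canonical label, so "mass_g:t_air" matches the
# "t_air:mass_g" that terms() may produce.
normTerm <- function(term) {
  vapply(term, function(t) {
    paste(sort(strsplit(termToExpr(t), ":", fixed = TRUE)[[1]]),
      collapse = ":")
  }, character(1), USE.NAMES = FALSE)
}

# Base column names a term depends on.
termColumns <- function(term) {
  unique(sub("_sq$", "", unlist(strsplit(term, ":", fixed = TRUE))))
}

specFormula <- function(spec) {
  rhs <- paste(vapply(spec$fixed, termToExpr, character(1)), collapse = " + ")
  if (length(spec$randomIntercepts)) {
    rhs <- paste(rhs, paste(sprintf("(1 | %s)", spec$randomIntercepts),
      collapse = " + "), sep = " + ")
  }
  stats::as.formula(paste(spec$response, "~", rhs))
}

specData <- function(spec, data) {
  if (!is.null(spec$dataFilter)) data <- data[spec$dataFilter(data), , drop = FALSE]
  cols <- unique(c(spec$response,
    unlist(lapply(spec$fixed, termColumns)), spec$randomIntercepts))
  missingCols <- setdiff(cols, names(data))
  if (length(missingCols)) {
    stop("data lacks columns: ", paste(missingCols, collapse = ", "))
  }
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  if (any(!keep)) {
    message(sum(!keep), " bees dropped for missing values in model columns")
  }
  data <- data[keep, , drop = FALSE]
  # sum-to-zero contrasts so Type III marginal tests are meaningful
  for (cl in cols) {
    if (is.character(data[[cl]])) data[[cl]] <- factor(data[[cl]])
    if (is.factor(data[[cl]])) {
      data[[cl]] <- droplevels(data[[cl]])
      if (nlevels(data[[cl]]) > 1L) {
        stats::contrasts(data[[cl]]) <- stats::contr.sum(nlevels(data[[cl]]))
      }
    }
  }
  data
}

#' Fit a vibration model (mixed or fixed effects)
#'
#' Fits the model described by a [modelSpec()] to a per-bee table. With
#' random intercepts the model is fitted by REML through
#' [lmerTest::lmer()]; Type III F tests use Satterthwaite denominator
#' degrees of freedom. Without random intercepts the model reduces to
#' ordinary least squares via [stats::lm()] with classical Type III
#' (marginal) F tests. All factors are given sum-to-zero contrasts. A
#' singular fit (a variance component estimated at zero) is flagged, not
#' fatal.
#'
#' @param spec a [modelSpec()].
#' @param data per-bee data.frame (e.g. from [simulateBeeDataset()]).
#' @return a [VibrationFit-class].
#' @examples
#' d <- simulateBeeDataset(populationParams(), nBees = 120, seed = 1)
#' f <- fitVibrationModel(modelSpec("frequency",
#'   c("t_air", "distribution")), d)
#' type3Table(f)
#' @export
fitVibrationModel <- function(spec, data) {
  stopifnot(inherits(spec, "ModelSpec"))
  data <- specData(spec, data)
  form <- specFormula(spec)
  mixed <- length(spec$randomIntercepts) > 0L
  if (mixed) {
    for (g in spec$randomIntercepts) {
      if (nlevels(factor(data[[g]])) < 2L) {
        stop("random grouping '", g, "' needs >= 2 levels")
      }
    }
    fit <- lmerTest::lmer(form, data = data, REML = TRUE)
    singular <- lme4::isSingular(fit, tol = 1e-5)
    # only genuine optimizer failure counts as non-convergence; scaling
    # and singularity notes do not invalidate the fit
    msgs <- unlist(fit@optinfo$conv$lme4$messages)
    conv <- !any(grepl("failed to converge", msgs, ignore.case = TRUE))
    sm <- summary(fit)$coefficients
    coefs <- data.frame(
      term = rownames(sm), estimate = sm[, "Estimate"],
      se = sm[, "Std. Error"],
      df = if ("df" %in% colnames(sm)) sm[, "df"] else NA_real_,
      row.names = NULL
    )
    vc <- as.data.frame(lme4::VarCorr(fit))
    resVar <- vc$vcov[vc$grp == "Residual"]
    varcomps <- stats::setNames(
      vc$vcov[vc$grp != "Residual"], vc$grp[vc$grp != "Residual"])
    a3 <- tryCatch(
      stats::anova(fit, type = 3, ddf = "Satterthwaite"),
      error = function(e) NULL
    )
    if (!is.null(a3) && nrow(a3)) {
      type3 <- data.frame(
        term = rownames(a3), F = a3[, "F value"],
        df_num = a3[, "NumDF"], df_den = a3[, "DenDF"],
        p = a3[, "Pr(>F)"], row.names = NULL
      )
    } else {
      # boundary fit where Satterthwaite is undefined: Wald z fallback
      z <- coefs$estimate / coefs$se
      type3 <- data.frame(
        term = coefs$term, F = z^2, df_num = 1, df_den = Inf,
        p = 2 * stats::pnorm(-abs(z)), row.names = NULL
      )
      type3 <- type3[type3$term != "(Intercept)", , drop = FALSE]
    }
    eta <- as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit))
  } else {
    fit <- stats::lm(form, data = data)
    singular <- FALSE
    conv <- TRUE
    sm <- summary(fit)$coefficients
    coefs <- data.frame(
      term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
      df = fit$df.residual, row.names = NULL
    )
    varcomps <- stats::setNames(numeric(), character())
    resVar <- summary(fit)$sigma^2
    d1 <- stats::drop1(fit, test = "F")
    d1 <- d1[-1, , drop = FALSE]
    type3 <- data.frame(
      term = rownames(d1), F = d1[, "F value"],
      df_num = d1[, "Df"], df_den = fit$df.residual,
      p = d1[, "Pr(>F)"], row.names = NULL
    )
    eta <- as.vector(stats::fitted(fit))
  }
  varF <- stats::var(eta)
  r2c <- (varF + sum(varcomps)) / (varF + sum(varcomps) + resVar)
  new("VibrationFit",
    spec = unclass(spec), fit = fit, coefficients = coefs,
    varcomps = varcomps, residualVar = resVar, type3 = type3,
    conditionalR2 = min(1, max(0, r2c)), nBees = nrow(data),
    converged = conv, singular = singular
  )
}

setMethod("show", "VibrationFit", function(object) {
  cat("VibrationFit: ", deparse(specFormula(structure(object@spec,
    class = "ModelSpec"))), "\n", sep = "")
  cat("  n = ", object@nBees, " bees; conditional R^2 = ",
    signif(object@conditionalR2, 3),
    if (object@singular) "; singular fit (a variance component at zero)",
    "\n", sep = "")
  tab <- object@coefficients
  tab$estimate <- signif(tab$estimate, 4)
  tab$se <- signif(tab$se, 3)
  print(tab[, c("term", "estimate", "se")], row.names = FALSE)
})

#' Type III table of a vibration fit
#'
#' Per-term marginal F statistics; for mixed fits the denominator degrees
#' of freedom use the Satterthwaite approximation, for fixed-effect fits
#' the classical residual degrees of freedom.
#'
#' @param fit a [VibrationFit-class].
#' @return data.frame with term, F, df_num, df_den, p.
#' @export
type3Table <- function(fit) {
  stopifnot(is(fit, "VibrationFit"))
  if (!fit@converged) stop("fit did not converge; Type III table unavailable")
  fit@type3
}

#' Conditional R-squared of a vibration fit
#'
#' Variance explained by fixed plus random effects:
#' (var_fixed + sum var_random) / (var_fixed + sum var_random +
#' var_residual), with var_fixed the variance of the fixed-effect linear
#' predictor over the data.
#'
#' @param fit a [VibrationFit-class].
#' @return a number in [0, 1].
#' @export
conditionalR2 <- function(fit) {
  stopifnot(is(fit, "VibrationFit"))
  fit@conditionalR2
}

#' Extract one fixed effect with its Wald confidence interval
#'
#' @param fit a [VibrationFit-class].
#' @param term a term as given to [modelSpec()] (e.g. "t_air",
#'   "t_air_sq").
#' @param level confidence level (default 0.95).
#' @return list with estimate, se, ci (length 2), df.
#' @export
fixedEffect <- function(fit, term, level = 0.95) {
  stopifnot(is(fit, "VibrationFit"))
  nm <- termToExpr(term)
  row <- fit@coefficients[normTerm(fit@coefficients$term) == normTerm(term), ]
  if (!nrow(row)) {
    stop("term '", term, "' not in the fitted model (looked for '", nm, "')")
  }
  df <- row$df
  q <- if (is.finite(df) && df > 0) {
    stats::qt(1 - (1 - level) / 2, df)
  } else {
    stats::qnorm(1 - (1 - level) / 2)
  }
  list(
    estimate = row$estimate, se = row$se,
    ci = c(row$estimate - q * row$se, row$estimate + q * row$se), df = df
  )
}

#' Stepwise removal of non-significant reducible terms
#'
#' Starting from the full model, iteratively removes the least significant
#' interaction term with Type III p above `alpha`, refitting after each
#' removal; once no removable interaction remains, optionally considers
#' further reducible terms (by default quadratic terms and "location").
#' Main effects are never removed.
#'
#' @param spec the full [modelSpec()].
#' @param data per-bee data.frame.
#' @param alpha removal threshold (default 0.05).
#' @param alsoReduce additional removable terms once interactions are
#'   resolved; defaults to the quadratic terms and "location".
#' @return the final [modelSpec()], with attribute "removalLog" — a
#'   data.frame of (step, term, p) for each removal.
#' @export
stepwiseReduce <- function(spec, data, alpha = 0.05,
                           alsoReduce = NULL) {
  stopifnot(inherits(spec, "ModelSpec"))
  if (is.null(alsoReduce)) {
    alsoReduce <- c(grep("_sq$", spec$fixed, value = TRUE),
      intersect("location", spec$fixed))
  }
  log <- data.frame(step = integer(), term = character(), p = numeric())
  step <- 0L
  phases <- list(
    function(s) grep(":", s$fixed, value = TRUE),
    function(s) intersect(alsoReduce, s$fixed)
  )
  for (phase in phases) {
    repeat {
      candidates <- phase(spec)
      if (!length(candidates)) break
      fit <- fitVibrationModel(spec, data)
      t3 <- fit@type3
      t3$term_spec <- NA_character_
      for (trm in candidates) {
        hit <- which(normTerm(t3$term) == normTerm(trm))
        if (length(hit)) t3$term_spec[hit[1]] <- trm
      }
      t3 <- t3[!is.na(t3$term_spec), , drop = FALSE]
      if (!nrow(t3)) break
      worst <- t3[which.max(t3$p), ]
      if (worst$p <= alpha) break
      step <- step + 1L
      log <- rbind(log, data.frame(step = step, term = worst$term_spec,
        p = worst$p))
      spec$fixed <- setdiff(spec$fixed, worst$term_spec)
    }
  }
  attr(spec, "removalLog") <- log
  spec
}
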