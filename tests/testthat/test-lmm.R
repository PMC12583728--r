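quiet <- function(expr) suppressMessages(suppressWarnings(expr))

test_that("the mixed model collapses to OLS when group variances are zero", {
  fe <- referenceEffects("accel_air")
  p <- populationParams(fixedEffects = fe, sdSpecies = 0, sdCaste = 0,
    sdResidual = 40)
  d <- simulateBeeDataset(p, nBees = 150, response = "acceleration",
    seed = 12)
  spec <- modelSpec("acceleration",
    c("t_air", "t_air_sq", "mass_g", "distribution"))
  mixed <- quiet(fitVibrationModel(spec, d))
  olsSpec <- modelSpec("acceleration",
    c("t_air", "t_air_sq", "mass_g", "distribution"),
    randomIntercepts = character())
  ols <- quiet(fitVibrationModel(olsSpec, d))
  expect_true(mixed@singular)
  expect_equal(mixed@coefficients$estimate, ols@coefficients$estimate,
    tolerance = 1e-6)
})

test_that("adding a constant to the response shifts only the intercept", {
  p <- populationParams(sdResidual = 20)
  d <- simulateBeeDataset(p, nBees = 120, seed = 21)
  spec <- modelSpec("frequency", c("t_air", "distribution"))
  f1 <- quiet(fitVibrationModel(spec, d))
  d$frequency <- d$frequency + 50
  f2 <- quiet(fitVibrationModel(spec, d))
  co1 <- f1@coefficients
  co2 <- f2@coefficients
  i1 <- co1$term == "(Intercept)"
  expect_equal(co2$estimate[i1] - co1$estimate[i1], 50, tolerance = 1e-6)
  expect_equal(co2$estimate[!i1], co1$estimate[!i1], tolerance = 1e-6)
})

test_that("Type III reduces to classical ANOVA in the balanced one-factor
           case and to squared t for single-df terms", {
  set.seed(5)
  d <- data.frame(
    caste = factor(rep(c("worker", "drone"), each = 30)),
    species = factor(rep(sprintf("sp%02d", 1:6), times = 10))
  )
  d$frequency <- 200 + 10 * (d$caste == "drone") + rnorm(60, 0, 8)
  spec <- modelSpec("frequency", "caste", randomIntercepts = character())
  fit <- quiet(fitVibrationModel(spec, d))
  a1 <- anova(lm(frequency ~ caste, data = d))
  expect_equal(type3Table(fit)$F, a1$`F value`[1], tolerance = 1e-10)
  expect_equal(type3Table(fit)$p, a1$`Pr(>F)`[1], tolerance = 1e-10)

  # mixed model: F for a continuous 1-df term equals its squared t
  p <- populationParams(sdResidual = 25)
  db <- simulateBeeDataset(p, nBees = 120, seed = 31)
  fm <- quiet(fitVibrationModel(
    modelSpec("frequency", c("t_air", "distribution")), db))
  t3 <- type3Table(fm)
  co <- fm@coefficients
  tAir <- co$estimate[co$term == "t_air"] / co$se[co$term == "t_air"]
  expect_equal(t3$F[t3$term == "t_air"], tAir^2, tolerance = 1e-8)
})

test_that("Type III results do not depend on the order of terms", {
  p <- populationParams(fixedEffects = referenceEffects("accel_air"),
    sdResidual = 50)
  d <- simulateBeeDataset(p, nBees = 150, response = "acceleration",
    seed = 41)
  s1 <- modelSpec("acceleration",
    c("t_air", "t_air_sq", "mass_g", "distribution"))
  s2 <- modelSpec("acceleration",
    c("distribution", "mass_g", "t_air_sq", "t_air"))
  t1 <- type3Table(quiet(fitVibrationModel(s1, d)))
  t2 <- type3Table(quiet(fitVibrationModel(s2, d)))
  t2 <- t2[match(t1$term, t2$term), ]
  expect_equal(t1$F, t2$F, tolerance = 1e-6)
  expect_equal(t1$p, t2$p, tolerance = 1e-6)
})

test_that("conditional R-squared matches its analytic limits and a known
           variance partition", {
  # perfect fixed-effect fit: R2 = 1
  fe <- referenceEffects("freq_air")
  d0 <- simulateBeeDataset(noiseFreeParams(fe), nBees = 60, seed = 3)
  f0 <- quiet(fitVibrationModel(
    modelSpec("frequency", c("t_air", "distribution"),
      randomIntercepts = character()), d0))
  expect_equal(conditionalR2(f0), 1, tolerance = 1e-6)

  # intercept-only model: no explained variance
  set.seed(8)
  dn <- data.frame(frequency = rnorm(80), t_air = runif(80, 5, 35))
  fn <- quiet(fitVibrationModel(
    modelSpec("frequency", "t_air", randomIntercepts = character()), dn))
  expect_lt(conditionalR2(fn), 0.1)

  # simulated partition: compare against the ground-truth decomposition
  p <- populationParams(fixedEffects = c(intercept = 0, t_air = 3),
    sdSpecies = 20, sdCaste = 0, sdResidual = 25)
  r2s <- vapply(1:30, function(s) {
    d <- simulateBeeDataset(p, nBees = 300, seed = s)
    fit <- quiet(fitVibrationModel(
      modelSpec("frequency", "t_air", randomIntercepts = "species"), d))
    truth <- (var(d$gt_linpred) + 20^2) / (var(d$gt_linpred) + 20^2 + 25^2)
    conditionalR2(fit) - truth
  }, numeric(1))
  expect_lt(abs(mean(r2s)), 0.05)
})

test_that("fixed-effect confidence intervals cover the generating value at
           close to the nominal rate", {
  p <- populationParams(fixedEffects = referenceEffects("freq_air"),
    sdSpecies = 15, sdCaste = 5, sdResidual = 30)
  spec <- modelSpec("frequency", c("t_air", "distribution"))
  hits <- vapply(1:100, function(s) {
    d <- simulateBeeDataset(p, 215, seed = s)
    fe <- fixedEffect(quiet(fitVibrationModel(spec, d)), "t_air")
    fe$ci[1] <= 1.48 && 1.48 <= fe$ci[2]
  }, logical(1))
  expect_gte(sum(hits), 93)
})

test_that("Type III tests hold their size for a null term", {
  # distribution has a true zero effect; nominal 5% test (the generating
  # model matches the fitted fixed-effects model: no group variance)
  p <- populationParams(
    fixedEffects = c(intercept = 185, t_air = 1.48, distribution = 0),
    sdSpecies = 0, sdCaste = 0, sdResidual = 30
  )
  spec <- modelSpec("frequency", c("t_air", "distribution"),
    randomIntercepts = character())
  # 2000 replicates keep the Monte-Carlo error of the rate well inside
  # the acceptance band
  pvals <- vapply(1:2000, function(s) {
    d <- simulateBeeDataset(p, 90, seed = 5000 + s)
    t3 <- type3Table(quiet(fitVibrationModel(spec, d)))
    t3$p[t3$term == "distribution"]
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("stepwise reduction drops null interactions and keeps real ones", {
  baseFe <- c(intercept = 27, t_air = 4, mass = 300)
  spec <- modelSpec("acceleration", c("t_air", "mass_g", "mass_g:t_air"),
    randomIntercepts = character())

  # no interactions present: spec unchanged
  plain <- modelSpec("acceleration", c("t_air", "mass_g"),
    randomIntercepts = character())
  d1 <- simulateBeeDataset(
    populationParams(fixedEffects = baseFe, sdSpecies = 0, sdCaste = 0,
      sdResidual = 30), 100, "acceleration", seed = 1)
  red <- stepwiseReduce(plain, d1)
  expect_equal(red$fixed, plain$fixed)

  # a strong true interaction survives; a null one is removed
  keptNull <- keptReal <- logical(20)
  for (s in 1:20) {
    d <- simulateBeeDataset(
      populationParams(fixedEffects = baseFe, sdSpecies = 0, sdCaste = 0,
        sdResidual = 30), 150, "acceleration", seed = 100 + s)
    dReal <- d
    dReal$acceleration <- dReal$acceleration +
      40 * dReal$mass_g * dReal$t_air
    keptReal[s] <- "mass_g:t_air" %in%
      quiet(stepwiseReduce(spec, dReal))$fixed
    keptNull[s] <- "mass_g:t_air" %in%
      quiet(stepwiseReduce(spec, d))$fixed
  }
  expect_gte(sum(keptReal), 19)
  expect_lte(sum(keptNull), 5)
})

test_that("rows with missing mass are dropped with a message when mass is
           modelled", {
  p <- populationParams(fixedEffects = referenceEffects("accel_air"),
    sdResidual = 50)
  d <- simulateBeeDataset(p, 120, "acceleration", seed = 61)
  d$mass_g[1:6] <- NA  # e.g. queens whose mass was never measured
  spec <- modelSpec("acceleration",
    c("t_air", "t_air_sq", "mass_g", "distribution"))
  expect_message(
    fit <- suppressWarnings(fitVibrationModel(spec, d)),
    "6 bees dropped"
  )
  expect_equal(fit@nBees, 114L)
})
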