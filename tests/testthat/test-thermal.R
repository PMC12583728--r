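quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# Noise-free quadratic dataset with a known vertex, fitted by OLS.
vertexFixture <- function(b = 7.95, cq = -0.17, seed = 1,
                          sdResidual = 0, nBees = 120) {
  fe <- c(intercept = 27, t_air = b, t_air_sq = cq, mass = 600)
  p <- populationParams(fixedEffects = fe, sdSpecies = 0, sdCaste = 0,
    sdResidual = sdResidual)
  d <- simulateBeeDataset(p, nBees, "acceleration", seed = seed)
  spec <- modelSpec("acceleration", c("t_air", "t_air_sq", "mass_g"),
    randomIntercepts = character())
  list(data = d, spec = spec,
    fit = quiet(fitVibrationModel(spec, d)))
}

test_that("predictions reproduce the generating polynomial exactly for a
           noise-free fit", {
  fx <- vertexFixture()
  grid <- seq(5, 35, by = 1)
  pc <- predictCurve(fx$fit, grid)
  held <- attr(pc, "heldAt")
  truth <- 27 + 7.95 * grid - 0.17 * grid^2 + 600 * held$mass_g
  expect_equal(pc$predicted, truth, tolerance = 1e-8)
  expect_true(all(pc$ci_low <= pc$predicted & pc$predicted <= pc$ci_high))
})

test_that("the confidence band widens toward the grid edges for a noisy
           quadratic fit", {
  fx <- vertexFixture(sdResidual = 40, nBees = 215)
  grid <- seq(5, 35, length.out = 101)
  pc <- predictCurve(fx$fit, grid)
  w <- pc$ci_high - pc$ci_low
  mid <- which.min(w)
  expect_gt(w[1], w[mid])
  expect_gt(w[101], w[mid])
  expect_true(mid > 20 && mid < 80)
})

test_that("predictions are invariant to consistent temperature centring", {
  fx <- vertexFixture(sdResidual = 40, nBees = 215)
  d2 <- fx$data
  d2$t_air <- d2$t_air - 20
  fit2 <- quiet(fitVibrationModel(fx$spec, d2))
  grid <- seq(8, 32, length.out = 25)
  p1 <- predictCurve(fx$fit, grid)
  p2 <- predictCurve(fit2, grid - 20)
  expect_equal(p1$predicted, p2$predicted, tolerance = 1e-6)
})

test_that("the quadratic vertex is the closed form -b/(2c) and matches a
           fine-grid argmax", {
  fx <- vertexFixture(b = 7.95, cq = -0.17)
  v <- quadraticVertex(fx$fit)
  expect_equal(round(v$xPeak, 4), 23.3824)
  expect_equal(v$xPeak, -7.95 / (2 * -0.17), tolerance = 1e-6)

  grid <- seq(5, 35, by = 0.01)
  pc <- predictCurve(fx$fit, grid)
  expect_lt(abs(grid[which.max(pc$predicted)] - v$xPeak), 0.011)

  # symmetric quadratic peaks at zero
  fx0 <- vertexFixture(b = 0, cq = -0.2)
  expect_equal(quadraticVertex(fx0$fit)$xPeak, 0, tolerance = 1e-6)

  # convex curves have no interior maximum
  fxPos <- vertexFixture(b = -6.17, cq = 0.21)
  expect_error(quadraticVertex(fxPos$fit), "no interior maximum")
})

test_that("the bootstrap peak degenerates to the vertex without noise and
           its percentiles match an independent quantile computation", {
  fx <- vertexFixture(b = 8.5, cq = -0.17)
  pk <- bootstrapPeak(fx$data, fx$spec, nBoot = 50, seed = 2,
    gridLength = 200)
  gridStep <- diff(range(fx$data$t_air)) / 199
  expect_lt(diff(pk@xCi), gridStep + 1e-9)
  expect_equal(pk@xPeak, 25, tolerance = 1e-6)

  # noisy case: recompute the percentile endpoints by hand (type-7)
  fxN <- vertexFixture(b = 8.5, cq = -0.17, sdResidual = 60, nBees = 215)
  pkN <- bootstrapPeak(fxN$data, fxN$spec, nBoot = 100, seed = 3)
  manualQ <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  xs <- pkN@replicates$x_peak
  expect_equal(pkN@xCi[1], manualQ(xs, 0.025), tolerance = 1e-10)
  expect_equal(pkN@xCi[2], manualQ(xs, 0.975), tolerance = 1e-10)
  expect_equal(pkN@nFailed + nrow(pkN@replicates), 100L)
})

test_that("the bootstrap is reproducible under a fixed seed", {
  fx <- vertexFixture(b = 8.5, cq = -0.17, sdResidual = 60, nBees = 150)
  p1 <- bootstrapPeak(fx$data, fx$spec, nBoot = 40, seed = 9)
  p2 <- bootstrapPeak(fx$data, fx$spec, nBoot = 40, seed = 9)
  expect_identical(p1@replicates, p2@replicates)
})

test_that("air- and thorax-temperature models are compared on a common
           likelihood footing", {
  # response driven by thorax temperature only
  fe <- c(intercept = -240, t_thorax = 19.65, t_thorax_sq = -0.26)
  p <- populationParams(fixedEffects = fe, sdSpecies = 10, sdCaste = 3,
    sdResidual = 40)
  wins <- vapply(1:10, function(s) {
    d <- simulateBeeDataset(p, 215, "acceleration", seed = 200 + s)
    fa <- quiet(fitVibrationModel(
      modelSpec("acceleration", c("t_air", "t_air_sq")), d))
    ft <- quiet(fitVibrationModel(
      modelSpec("acceleration", c("t_thorax", "t_thorax_sq")), d))
    cmp <- compareAirThorax(fa, ft)
    cmp$summary$conditional_r2[2] > cmp$summary$conditional_r2[1]
  }, logical(1))
  expect_gte(sum(wins), 9)

  # identical predictors give identical fits and zero AIC difference
  d <- simulateBeeDataset(p, 120, "acceleration", seed = 7)
  d$t_air <- d$t_thorax
  fa <- quiet(fitVibrationModel(
    modelSpec("acceleration", c("t_air", "t_air_sq")), d))
  ft <- quiet(fitVibrationModel(
    modelSpec("acceleration", c("t_thorax", "t_thorax_sq")), d))
  cmp <- compareAirThorax(fa, ft)
  expect_equal(diff(cmp$summary$aic), 0, tolerance = 1e-6)
  expect_equal(cmp$summary$conditional_r2[1],
    cmp$summary$conditional_r2[2], tolerance = 1e-8)

  # AIC identity: 2k - 2 logLik on the ML refit
  mlFit <- lme4::refitML(fa@fit)
  k <- attr(logLik(mlFit), "df")
  expect_equal(cmp$summary$aic[1],
    as.numeric(2 * k - 2 * logLik(mlFit)), tolerance = 1e-8)
})
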