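test_that("synthesis is deterministic and an empty plan gives silence", {
  empty <- recordingPlan(totalDuration = 1, noiseSd = 0, seed = 3)
  expect_true(all(samples(synthesizeRecording(empty)) == 0))
  expect_equal(nSamples(synthesizeRecording(empty)), 20480)

  plan <- tonePlan(noiseSd = 0.5, seed = 7)
  w1 <- synthesizeRecording(plan)
  w2 <- synthesizeRecording(plan)
  expect_identical(samples(w1), samples(w2))

  other <- tonePlan(noiseSd = 0.5, seed = 8)
  expect_false(identical(samples(w1), samples(synthesizeRecording(other))))
})

test_that("the noise-free waveform is homogeneous in peak acceleration", {
  w1 <- synthesizeRecording(tonePlan(peakAccel = 50))
  w2 <- synthesizeRecording(tonePlan(peakAccel = 100))
  expect_equal(samples(w2), 2 * samples(w1), tolerance = 1e-12)
  expect_equal(max(abs(samples(w2))), 100, tolerance = 1e-9)
})

test_that("ground-truth manifest mirrors the plan", {
  plan <- recordingPlan(
    list(
      buzzSpec(5, 0.4, 150), buzzSpec(1, 0.3, 200), buzzSpec(9, 0.6, 300)
    ),
    totalDuration = 12
  )
  man <- groundTruthManifest(plan)
  expect_equal(nrow(man), 3)
  expect_true(all(diff(man$onset_s) > 0))
  expect_lte(sum(man$duration_s), 12)

  expect_equal(nrow(groundTruthManifest(recordingPlan(totalDuration = 1))), 0)
})

test_that("invalid plans are rejected", {
  overlapping <- list(buzzSpec(1, 2, 200), buzzSpec(2, 1, 300))
  expect_error(
    synthesizeRecording(recordingPlan(overlapping, totalDuration = 10)),
    "disjoint"
  )
  aboveNyquist <- list(buzzSpec(1, 1, 900, nHarmonics = 20L))
  expect_error(
    synthesizeRecording(recordingPlan(aboveNyquist, totalDuration = 10)),
    "Nyquist"
  )
  expect_error(buzzSpec(1, 1, 1500), "f0")
})

test_that("noise-free simulated bees sit exactly on the fixed-effect surface
           and OLS recovers the generating coefficients", {
  fe <- referenceEffects("accel_air")
  d <- simulateBeeDataset(noiseFreeParams(fe), nBees = 120,
    response = "acceleration", seed = 2)
  expect_equal(d$acceleration, d$gt_linpred, tolerance = 1e-12)

  ols <- lm(acceleration ~ t_air + I(t_air^2) + mass_g + distribution,
    data = d)
  est <- coef(ols)
  expect_equal(unname(est["(Intercept)"]), fe[["intercept"]],
    tolerance = 1e-6)
  expect_equal(unname(est["t_air"]), fe[["t_air"]], tolerance = 1e-6)
  expect_equal(unname(est["I(t_air^2)"]), fe[["t_air_sq"]],
    tolerance = 1e-6)
  expect_equal(unname(est["mass_g"]), fe[["mass"]], tolerance = 1e-6)
  expect_equal(unname(est["distributionspecialist"]),
    fe[["distribution"]], tolerance = 1e-6)
})

test_that("a concave generating surface is maximised at the design
           temperature nearest the analytic vertex", {
  fe <- c(intercept = 27, t_air = 7.95, t_air_sq = -0.17)
  p <- populationParams(fixedEffects = fe, sdSpecies = 0, sdCaste = 0,
    sdResidual = 0, airDesign = "lab")
  d <- simulateBeeDataset(p, nBees = 210, response = "acceleration",
    seed = 4)
  byTemp <- tapply(d$acceleration, d$t_air, mean)
  vertex <- -fe[["t_air"]] / (2 * fe[["t_air_sq"]])
  steps <- as.numeric(names(byTemp))
  expect_equal(
    steps[which.max(byTemp)],
    steps[which.min(abs(steps - vertex))]
  )
})

test_that("simulator rejects invalid parameters", {
  expect_error(populationParams(sdSpecies = -1), "SDs")
  expect_error(
    simulateBeeDataset(populationParams(), nBees = 10, seed = 1),
    "nBees"
  )
})

test_that("simulated datasets are reproducible and carry ground truth", {
  p <- populationParams()
  d1 <- simulateBeeDataset(p, nBees = 60, seed = 9)
  d2 <- simulateBeeDataset(p, nBees = 60, seed = 9)
  expect_identical(d1, d2)
  expect_true(all(c("gt_linpred", "gt_species_effect", "gt_caste_effect",
    "gt_residual") %in% names(d1)))
  expect_equal(
    d1$frequency,
    d1$gt_linpred + d1$gt_species_effect + d1$gt_caste_effect +
      d1$gt_residual,
    tolerance = 1e-12
  )
  # every species and caste level is present
  expect_equal(nlevels(droplevels(d1$species)), 15)
  expect_setequal(levels(droplevels(d1$caste)), c("worker", "drone"))
})

test_that("allometric and thermoregulation simulators honour their
           generating models", {
  d <- simulateAllometricBees(500, exponent = 0.67, k = 600, sdLog = 0,
    seed = 1)
  expect_equal(log(d$peak_accel_ms2),
    log(600) + 0.67 * log(d$mass_g), tolerance = 1e-12)

  th <- simulateThermoregBees(100, lower = 25, upper = 40, midpoint = 20,
    scale = 3, noiseSd = 0, seed = 2)
  expect_equal(
    th$t_thorax,
    25 + 15 / (1 + exp((20 - th$t_air) / 3)),
    tolerance = 1e-12
  )
})
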