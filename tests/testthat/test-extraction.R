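test_that("high-pass filter rejects DC and the deep stopband while
           passing buzz frequencies", {
  fs <- 20480
  wDC <- Waveform(rep(5, fs), fs)
  expect_lt(abs(mean(samples(highpass(wDC)))), 1e-6)

  w200 <- sineWave(200)
  expect_equal(midAmp(samples(highpass(w200))), 1, tolerance = 0.02)

  w1 <- sineWave(1)
  expect_lt(midAmp(samples(highpass(w1))), 0.05)

  short <- Waveform(rnorm(100), fs)
  expect_error(highpass(short), "shorter than the filter window")
})

test_that("segmentation applies the minimum-duration filter and locates
           onsets within 25 ms", {
  plan <- recordingPlan(
    list(
      buzzSpec(5, 0.05, 200), buzzSpec(20, 0.5, 250), buzzSpec(40, 2.0, 300)
    ),
    totalDuration = 60, noiseSd = 1, seed = 2
  )
  segs <- segmentBuzzes(highpass(synthesizeRecording(plan)))
  # only the 0.5 s and 2.0 s buzzes survive the 0.1 s minimum
  expect_equal(nrow(segs), 2)
  expect_equal(segs$start_s, c(20, 40), tolerance = 0.025)
  expect_equal(segs$end_s, c(20.5, 42), tolerance = 0.025)
  expect_true(all(diff(as.vector(t(segs[, c("start_sample", "end_sample")])))
    > 0))
})

test_that("a silent recording yields no segments, not an error", {
  w <- Waveform(numeric(20480), 20480)
  expect_equal(nrow(segmentBuzzes(w)), 0)
  expect_equal(nrow(extractFeatures(w)), 0)
})

test_that("peak acceleration is the smoothed maximum and is homogeneous", {
  fs <- 20480
  w <- sineWave(200, amp = 1)
  x <- samples(w)
  # oracle: 2-sample moving mean of the absolute signal, brute force
  sm <- (abs(x[-1]) + abs(x[-length(x)])) / 2
  expect_equal(
    peakAcceleration(w, 1, nSamples(w)), max(sm), tolerance = 1e-10
  )
  # the smoothed peak of a sampled unit sine sits just below 1
  expect_equal(peakAcceleration(w, 1, nSamples(w)), max(sm),
    tolerance = 0.01)

  w3 <- Waveform(3 * x, fs)
  expect_equal(
    peakAcceleration(w3, 1, nSamples(w3)),
    3 * peakAcceleration(w, 1, nSamples(w)),
    tolerance = 1e-12
  )

  spike <- numeric(1000)
  spike[500] <- 8
  ws <- Waveform(spike, fs)
  expect_equal(peakAcceleration(ws, 1, 1000), 4)
})

test_that("cepstral f0 tracks the fundamental, not the loudest harmonic,
           and flags out-of-range tones", {
  fs <- 20480
  w <- sineWave(217)
  f0 <- fundamentalFrequency(w, 1, nSamples(w))
  expect_lt(abs(as.numeric(f0) - 217), quefrencyBin(217))

  # strongest energy on the third harmonic; f0 must still be 150
  t <- seq(1 / fs, 2, by = 1 / fs)
  x <- 0.3 * sin(2 * pi * 150 * t) + 0.5 * sin(2 * pi * 300 * t) +
    1.0 * sin(2 * pi * 450 * t)
  # brute-force autocorrelation oracle confirms the 150 Hz period
  ac <- acf(x[1:4096], lag.max = 200, plot = FALSE)$acf[-1]
  lagRange <- 30:200  # periods between ~100 and ~680 Hz
  expect_equal(fs / lagRange[which.max(ac[lagRange])], 150,
    tolerance = 0.01)
  est <- fundamentalFrequency(Waveform(x, fs), 1, length(x))
  expect_lt(abs(as.numeric(est) - 150), quefrencyBin(150))

  # a tone above f0Max yields a flagged missing value, not an estimate
  w15 <- sineWave(1500)
  est15 <- fundamentalFrequency(w15, 1, nSamples(w15))
  expect_true(is.na(est15))
  expect_equal(attr(est15, "nValid"), 0)

  expect_error(fundamentalFrequency(w, 1, 256), "shorter than one")
})

test_that("pure tones across the estimator's range are recovered within
           one quefrency bin", {
  set.seed(31)
  freqs <- runif(20, 85, 1000)
  for (f in freqs) {
    w <- sineWave(f, duration = 0.5)
    est <- as.numeric(fundamentalFrequency(w, 1, nSamples(w)))
    expect_lt(abs(est - f), quefrencyBin(f))
  }
})

test_that("extraction round-trips noise-free synthetic recordings against
           the manifest", {
  plan <- recordingPlan(
    list(
      buzzSpec(1, 0.4, 140, peakAccel = 60),
      buzzSpec(3, 0.8, 217, peakAccel = 120),
      buzzSpec(6, 0.3, 180, peakAccel = 90),
      buzzSpec(8, 1.5, 320, peakAccel = 200),
      buzzSpec(11, 0.6, 250, peakAccel = 150)
    ),
    totalDuration = 13, noiseSd = 0.5, seed = 5
  )
  man <- groundTruthManifest(plan)
  feats <- extractFeatures(synthesizeRecording(plan))
  expect_equal(nrow(feats), nrow(man))
  expect_equal(feats$start_s, man$onset_s, tolerance = 0.025)
  expect_equal(feats$duration_s, man$duration_s, tolerance = 0.05)
  expect_equal(feats$peak_accel_ms2, man$peak_accel_ms2, tolerance = 0.05)
  for (i in seq_len(nrow(man))) {
    expect_lt(abs(feats$f0_hz[i] - man$f0_hz[i]),
      quefrencyBin(man$f0_hz[i]))
  }
})

test_that("features are invariant to pre/post silence and to signal
           scaling (except peak, which scales)", {
  base <- tonePlan(onset = 0.5, duration = 1, totalDuration = 2.5)
  shifted <- tonePlan(onset = 1.5, duration = 1, totalDuration = 4.5)
  f1 <- extractFeatures(synthesizeRecording(base))
  f2 <- extractFeatures(synthesizeRecording(shifted))
  expect_equal(f1$duration_s, f2$duration_s, tolerance = 1e-3)
  expect_equal(f1$f0_hz, f2$f0_hz, tolerance = 1e-6)
  expect_equal(f1$peak_accel_ms2, f2$peak_accel_ms2, tolerance = 1e-3)
  expect_equal(f2$start_s - f1$start_s, 1, tolerance = 1e-3)

  w <- synthesizeRecording(base)
  wScaled <- Waveform(5 * samples(w), samplingRate(w))
  fs1 <- extractFeatures(w)
  fs5 <- extractFeatures(wScaled)
  expect_equal(fs5$duration_s, fs1$duration_s)
  expect_equal(fs5$f0_hz, fs1$f0_hz, tolerance = 1e-9)
  expect_equal(fs5$peak_accel_ms2, 5 * fs1$peak_accel_ms2,
    tolerance = 1e-9)
})

test_that("per-bee means are arithmetic means with NA-f0 exclusion", {
  feats <- data.frame(
    buzz_index = 1:3, start_s = c(1, 3, 5), end_s = c(2, 4, 6),
    duration_s = c(1, 1, 1), peak_accel_ms2 = c(50, 100, 150),
    f0_hz = c(100, 300, NA)
  )
  m <- perBeeMeans(feats, "beeA")
  expect_equal(m$n_buzzes, 3L)
  expect_equal(m$peak_accel_ms2, 100)
  expect_equal(m$f0_hz, 200)  # NA excluded from the f0 mean only
  # brute-force recomputation oracle
  expect_equal(m$duration_s, sum(feats$duration_s) / 3)

  expect_warning(m0 <- perBeeMeans(feats[0, ], "beeB"), "no buzzes")
  expect_true(is.na(m0$f0_hz))
  expect_equal(m0$n_buzzes, 0L)
})

test_that("synthesized buzzes with adequate SNR are detected end to end", {
  set.seed(11)
  for (rep in 1:3) {
    f0 <- runif(1, 120, 400)
    dur <- runif(1, 0.2, 1.5)
    plan <- recordingPlan(
      list(buzzSpec(1, dur, f0, peakAccel = 100)),
      totalDuration = dur + 2.5, noiseSd = 2, seed = rep
    )
    feats <- extractFeatures(synthesizeRecording(plan))
    expect_equal(nrow(feats), 1)
    expect_equal(feats$start_s, 1, tolerance = 0.025)
    expect_lt(abs(feats$f0_hz - f0), quefrencyBin(f0))
  }
})
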