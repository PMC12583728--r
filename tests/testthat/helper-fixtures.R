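# Small builders shared across tests. Everything is generated in code;
# no fixture files.

# One-buzz plan at the study's grand-mean buzz frequency.
tonePlan <- function(f0 = 217, duration = 2, onset = 1, totalDuration = 4,
                     noiseSd = 0, nHarmonics = 3L, peakAccel = 100,
                     seed = 1L) {
  recordingPlan(
    list(buzzSpec(onset, duration, f0,
      nHarmonics = nHarmonics, peakAccel = peakAccel)),
    totalDuration = totalDuration, noiseSd = noiseSd, seed = seed
  )
}

# A waveform holding a bare sine, for filter/feature unit tests.
sineWave <- function(freq, fs = 20480, duration = 2, amp = 1) {
  t <- seq(1 / fs, duration, by = 1 / fs)
  Waveform(amp * sin(2 * pi * freq * t), fs)
}

# Mid-signal amplitude, avoiding filter edge effects.
midAmp <- function(x) {
  n <- length(x)
  max(abs(x[(n %/% 4):(3 * n %/% 4)]))
}

# Quefrency-bin width (Hz) of the cepstral f0 estimator at frequency f.
quefrencyBin <- function(f, fs = 20480) {
  k <- round(fs / f)
  fs / k - fs / (k + 1)
}

# Noise-free parameters on a known fixed-effect surface.
noiseFreeParams <- function(fixedEffects) {
  populationParams(
    fixedEffects = fixedEffects,
    sdSpecies = 0, sdCaste = 0, sdResidual = 0
  )
}
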