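---
title: "Models and methods behind thermobuzz"
author: "thermobuzz authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermobuzz}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermobuzz)
```

## The scientific problem

Bumblebees power flight, defence and buzz-pollination with the same
indirect flight muscles. During non-flight buzzing the wings are
decoupled, so an accelerometer pressed to the thorax reads the muscle
output directly: each buzz has a duration (s), a peak acceleration
(m s^-2^, the amplitude measure) and a fundamental frequency (Hz, the
muscle contraction rate — distinct from the spectrally loudest
harmonic). thermobuzz implements the full analysis chain for such
recordings: signal-level feature extraction, per-bee averaging,
allometric scaling tests, mixed-effects thermal-performance models with
a bootstrap confidence interval for the performance peak, and the
sigmoidal air-to-thorax thermoregulation comparison. A seeded synthetic
module generates both waveforms and bee-level datasets with known
ground truth, so every stage is testable without field data.

## Signal processing

**High-pass filter.** Accelerometer traces carry low-frequency handling
and body-movement noise. `highpass()` removes everything below 20 Hz.
Because recordings are analysed offline and whole, the filter is applied
in the frequency domain over the entire trace: components below the
cutoff are zeroed and the transition to full passband is shaped by a
raised-cosine (Hann) taper whose width is `samplingRate /
filterWindowLen` (40 Hz at the defaults). The response is real and even,
so the filter is exactly zero phase — buzz onsets are not shifted — and
the stopband is genuinely deep: a 1 Hz component is removed essentially
completely while a 200 Hz buzz component passes within 2 %. A time-domain
FIR kernel of a few hundred taps cannot separate 1 Hz from a 20 Hz
cutoff at a 20 kHz sampling rate (the transition band of a 512-tap
Hann-windowed design spans tens of Hz), which is why the offline
full-signal form was chosen.

**Segmentation.** The amplitude envelope is a 10 ms moving RMS of the
filtered signal: RMS is insensitive to the single-sample spike
artifacts contact accelerometry produces. A buzz is a maximal run where
the envelope exceeds 8 % of its maximum over the whole recording — a
relative threshold, because contact coupling makes absolute amplitudes
recording-specific; the fraction is a per-recording override in
`extractionConfig()`. Sub-threshold dips shorter than 20 ms are merged
(an amplitude-modulated buzz should not split), and runs shorter than
0.1 s are discarded as non-buzzes. Indices are 1-based and inclusive,
the natural R convention; times in seconds are the primary coordinate.

**Peak acceleration** is the maximum of a 2-sample moving average of
the absolute filtered signal within the segment: enough smoothing to
suppress isolated spikes, little enough to preserve the oscillation
peak.

**Fundamental frequency.** Frames of 512 samples with 50 % overlap are
Hann-windowed; the real cepstrum of each frame is searched over
quefrencies corresponding to fundamentals up to 1000 Hz. The cepstral
peak tracks the spacing of the harmonic comb, which makes it robust to
buzzes whose energy is concentrated in an upper harmonic — the
spectral peak would be an octave (or more) wrong. Two numerical
choices matter here. First, the candidate must be an *interior local
maximum* of the cepstrum band: the global maximum often sits on the
monotone tail of the spectral-envelope component at the band edge,
which carries no periodicity information. Second, the quantised
cepstral candidate (resolution one quefrency bin, about f0^2/fs) is
refined at the nearest spectral partial, parabolically interpolated on
a 4x zero-padded spectrum; this removes both the quantisation and the
bias the decaying cepstral envelope induces. A frame yields a value
only if the refined partial is tonal — at least ten times the median
spectral magnitude — and carries at least 5 % of the strongest
partial's magnitude; the latter rejects rahmonic aliases of tones above
the 1000 Hz ceiling, which are flagged missing rather than
misreported. The buzz-level estimate is the median over valid frames,
robust to octave errors at buzz edges. With a 512-sample frame the
estimator's domain starts at two periods per frame, 80 Hz at the field
sampling rate; recorded buzz fundamentals (81-444 Hz) lie inside it.

## The synthetic-data generator

`synthesizeRecording()` renders each buzz as a sum of `nHarmonics`
harmonics of f0 with geometric amplitude decay (defaults 3 and 0.5 — a
spectrum that genuinely exercises an f0-vs-spectral-peak estimator),
shaped by an attack-sustain-release envelope (10 %/80 %/10 % of the
buzz, attack and release capped at 50 ms since real buzz onsets take
tens of milliseconds regardless of buzz length), rescaled so the
noise-free maximum equals the specified peak acceleration, plus white
Gaussian background noise. The defaults mirror the field protocol:
60 s recordings at 20,480 Hz. What it does *not* emulate: coupling
variation between thorax and accelerometer (modelled only as per-buzz
amplitude differences, not contact mechanics), frequency drift within
a buzz beyond a single per-buzz jitter draw, and non-Gaussian sensor
artifacts. Passing round-trip tests therefore demonstrate correctness
of the pipeline's algorithms, not robustness to every field artifact —
the per-recording threshold override exists precisely because field
recordings sometimes need manual adjustment.

`simulateBeeDataset()` draws per-bee mean responses from the same
structure the mixed models assume: a fixed-effect linear predictor
(intercept, air or thorax temperature with optional quadratic, mass,
distribution-class contrast) plus independent Gaussian species and
caste intercepts plus residual noise. The roster mirrors the study
system: 15 species (6 cold-habitat specialists, 9 generalists), workers
and drones, masses uniform on 0.05-0.6 g, field air temperatures
uniform on 13.0-21.1 deg C, lab air temperatures on the 5-35 deg C
ladder in 5 deg C steps, and a combined design mixing field and lab
bees 96:119. Thorax temperatures are uniform on 16-44 deg C (the
observed span) unless a sigmoidal air-thorax link is supplied.
`referenceEffects()` carries the reference coefficient sets used as
generating values. Ground-truth draws are returned in `gt_` columns so
recovery tests can score against truth. Buzz counts per bee are a
plain parameter of the pipeline scenario — the data give only an
average (about 52), not a distribution, so none is asserted.

## Statistical models

**Mixed models.** `fitVibrationModel()` fits REML mixed models through
`lmerTest` (or OLS via `lm` when no random intercepts are requested,
as in the caste-complete subset analysis). All factors get sum-to-zero
contrasts — Type III marginal tests are contrast-dependent, so this is
fixed and documented rather than left to session options. Type III F
tests use Satterthwaite denominator degrees of freedom; when a fit is
singular at the variance boundary and the Satterthwaite computation is
unavailable, large-sample Wald z tests are reported instead and
labelled by their infinite denominator df. A singular fit (a variance
component at zero) is flagged, not fatal: with only two caste levels
that boundary is often touched. Non-convergence means genuine
optimizer failure; scaling notes do not invalidate a fit. The
conditional R^2 is Nakagawa-Schielzeth: (var_fixed + sum var_random) /
(var_fixed + sum var_random + var_residual), with var_fixed the
variance of the fixed-effect predictor over the data. Bees missing a
modelled covariate (queens without mass measurements, in the field
data) are dropped with a logged count.

**Stepwise reduction** removes the least-significant interaction term
with Type III p above 0.05, refits, repeats; once interactions are
resolved it considers the optional reducible terms (quadratic terms,
location). Main effects are never removed, and the removal log is
attached to the returned spec.

**Allometry.** `fitLogLog()` regresses log acceleration on log mass
(natural logs; the exponent is base- and unit-invariant), and
`testSlope()` tests the exponent against 0.67 — the isometric
expectation, since muscle force tracks cross-sectional area and hence
mass^(2/3) — as a single-constraint F test, the square of the t
statistic. The global isometry model deliberately omits species, caste
and temperature, matching the subset-free formulation; the mixed-model
variants live in the modelling module.

**Thermal-performance curves.** `predictCurve()` gives population-level
predictions (random effects at zero) at held covariates — continuous
covariates at their sample means, factors at the reference level — with
a delta-method band from the fixed-effect covariance.
`quadraticVertex()` locates the peak analytically at -b/(2c). With the
reference acceleration coefficients (b = 7.95, c = -0.17) the closed
form gives 23.38 deg C; a full-model, full-data prediction rounds to
25 deg C, and the package documents this gap rather than forcing the
rounded value: the vertex of the printed coefficients and the argmax of
the full prediction differ legitimately. `bootstrapPeak()` resamples
bees — the independent sampling unit once buzzes are averaged per bee —
refits, predicts on a 200-point grid over the observed temperature
range, and takes 2.5/97.5 percentiles of the recorded argmax and
maximum. Replicates that fail to converge are dropped and counted;
more than 20 % failures aborts with advice rather than reporting a CI
built on a selected subset.

**Thermoregulation.** The air-thorax relationship is fitted as a
four-parameter logistic (two asymptotes: a minimum operating
temperature the thorax is heated to at cold air, and a plateau below
the critical thermal maximum at warm air) by Levenberg-Marquardt
(`minpack.lm`), initialised from data quantiles with up to five seeded
random restarts. The parameterisation is a package choice: the
biology fixes only "sigmoidal". Both the sigmoid and the linear
alternative report AIC from the same Gaussian likelihood formula,
n log(RSS/n) + n log(2 pi) + n + 2k with k counting mean parameters
plus the error variance — so a model with identical residuals but two
extra parameters scores exactly 4 AIC higher, and the comparison is
fair by construction. Printed RSS/AIC values from any particular field
dataset are data-dependent reference points, not reproduction targets.
The pseudo-R^2 is 1 - RSS/TSS about the mean; it can be negative for
a terrible fit and is stored raw.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit integer seed and restores
the caller's RNG state, so identical inputs give bit-identical outputs.
The package's own simulation checks run at the study's scale where that
is what the check is about — 215 bees, 15 species, 100-seed replicate
loops for coefficient recovery and interval coverage, 500 seeds for
test size, 200 bootstrap replicates per outer replicate for peak-CI
coverage — and at smaller sizes for algebraic identities where scale is
irrelevant. The bootstrap-coverage check uses the fixed-effects model
path: with zero generating group variances the mixed and OLS fits
coincide, and the OLS refit makes the 100 x 200 replicate loop cheap.

## Known limitations

* The f0 estimator is undefined below two periods per analysis frame
  (80 Hz at defaults); buzzes below that need a longer `f0WindowLen`.
* Segmentation assumes the recording contains genuine silence between
  buzzes; a recording that is one continuous buzz yields one segment,
  and a recording of pure noise with no buzz will still have an
  envelope maximum to threshold against.
* The simulator's random intercepts are independent Gaussians; no
  phylogenetic covariance between species is modelled.
* No TDMS reader: acquisition-format conversion happens upstream, and
  the package consumes WAV or two-column tab-delimited text.
* Formal TPC families (Sharpe-Schoolfield, Briere) are out of scope;
  the thermal models are polynomial mixed models plus the logistic
  thermoregulation fit.
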