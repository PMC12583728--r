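#' Extraction parameters
#'
#' All numeric knobs of the buzz-extraction pipeline, with defaults from
#' the field protocol: a 20 Hz high-pass (transition shaped by a Hann
#' taper whose width is set by a 512-sample window), segmentation at 8 %
#' of the recording's maximum envelope, a 0.1 s minimum buzz duration, a
#' 2-sample smoother for peak acceleration, and cepstral f0 analysis with
#' 512-sample frames, 50 % overlap and a 1000 Hz ceiling.
#'
#' @param highpassCutoff high-pass cutoff in Hz.
#' @param filterWindowLen filter window length in samples; the high-pass
#'   transition band spans `samplingRate / filterWindowLen` Hz above the
#'   cutoff.
#' @param thresholdFraction segmentation threshold as a fraction of the
#'   maximum smoothed envelope of the whole filtered recording, in (0, 1).
#'   Recordings are uncalibrated, so the threshold is relative and can be
#'   overridden per recording.
#' @param minDuration minimum buzz duration in seconds.
#' @param smoothWindow moving-average window (samples) applied to the
#'   absolute signal before taking the peak.
#' @param envelopeWindow RMS envelope window in seconds used for
#'   segmentation; RMS is robust to single-sample spike artifacts.
#' @param mergeGap sub-threshold gaps shorter than this (seconds) are
#'   merged so an amplitude-modulated buzz is not split.
#' @param f0WindowLen cepstral analysis frame length in samples.
#' @param f0Overlap frame overlap fraction in [0, 1).
#' @param f0Max maximum admissible fundamental frequency in Hz.
#' @return a validated list of class "ExtractionConfig".
#' @examples
#' extractionConfig(thresholdFraction = 0.1)
#' @export
extractionConfig <- function(highpassCutoff = 20, filterWindowLen = 512L,
                             thresholdFraction = 0.08, minDuration = 0.1,
                             smoothWindow = 2L, envelopeWindow = 0.01,
                             mergeGap = 0.02, f0WindowLen = 512L,
                             f0Overlap = 0.5, f0Max = 1000) {
  stopifnot(
    highpassCutoff > 0, filterWindowLen >= 8,
    thresholdFraction > 0, thresholdFraction < 1,
    minDuration > 0, smoothWindow >= 1, envelopeWindow > 0,
    mergeGap >= 0, f0WindowLen >= 32, f0Overlap >= 0, f0Overlap < 1,
    f0Max > 0
  )
  structure(
    list(
      highpassCutoff = highpassCutoff,
      filterWindowLen = as.integer(filterWindowLen),
      thresholdFraction = thresholdFraction, minDuration = minDuration,
      smoothWindow = as.integer(smoothWindow),
      envelopeWindow = envelopeWindow, mergeGap = mergeGap,
      f0WindowLen = as.integer(f0WindowLen), f0Overlap = f0Overlap,
      f0Max = f0Max
    ),
    class = "ExtractionConfig"
  )
}

#' Zero-phase high-pass filter
#'
#' Removes low-frequency noise (handling artifacts, body movement) below
#' the cutoff. The filter is applied in the frequency domain over the
#' whole recording: components below the cutoff are zeroed and the
#' transition to full passband is shaped by a raised-cosine (Hann) taper
#' of width `samplingRate / filterWindowLen` Hz. The response is real and
#' even, so the filter is exactly zero-phase and buzz onsets are not
#' shifted; the DC component is removed entirely.
#'
#' @param w a [Waveform-class].
#' @param cfg an [extractionConfig()].
#' @return the filtered [Waveform-class], same length.
#' @examples
#' t <- seq(0, 1, by = 1 / 4096)[-1]
#' w <- Waveform(5 + sin(2 * pi * 200 * t), 4096)
#' mean(samples(highpass(w)))
#' @export
highpass <- function(w, cfg = extractionConfig()) {
  stopifnot(is(w, "Waveform"))
  fs <- w@samplingRate
  if (cfg$highpassCutoff >= fs / 2) {
    stop("high-pass cutoff must be below the Nyquist frequency")
  }
  n <- length(w@samples)
  if (cfg$filterWindowLen > n) {
    stop("signal shorter than the filter window (", cfg$filterWindowLen,
      " samples); cannot filter")
  }
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # folded (two-sided) frequency axis
  bw <- fs / cfg$filterWindowLen
  gain <- ifelse(f < cfg$highpassCutoff, 0,
    ifelse(f >= cfg$highpassCutoff + bw, 1,
      0.5 * (1 - cos(pi * (f - cfg$highpassCutoff) / bw))
    )
  )
  y <- Re(stats::fft(stats::fft(w@samples) * gain, inverse = TRUE)) / n
  Waveform(y, fs, w@sourceId)
}

# Centered moving-RMS envelope, O(n) via cumulative sums.
movingRms <- function(x, win) {
  win <- max(1L, as.integer(win))
  cs <- cumsum(c(0, x^2))
  n <- length(x)
  half <- win %/% 2
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) - 1L + (win - half))
  sqrt((cs[hi + 1L] - cs[lo + 1L]) / (hi - lo))
}

#' Segment a filtered recording into buzzes
#'
#' Computes a moving-RMS amplitude envelope, thresholds it at
#' `thresholdFraction` of its maximum over the whole recording, merges
#' super-threshold runs separated by gaps shorter than `mergeGap`, and
#' discards runs shorter than `minDuration`. An all-zero recording yields
#' zero segments.
#'
#' @param w a high-pass filtered [Waveform-class].
#' @param cfg an [extractionConfig()].
#' @return data.frame with one row per buzz: start_sample, end_sample
#'   (1-based, inclusive), start_s, end_s, duration_s. Ordered and
#'   pairwise disjoint.
#' @export
segmentBuzzes <- function(w, cfg = extractionConfig()) {
  stopifnot(is(w, "Waveform"))
  fs <- w@samplingRate
  empty <- data.frame(
    start_sample = integer(), end_sample = integer(),
    start_s = numeric(), end_s = numeric(), duration_s = numeric()
  )
  env <- movingRms(w@samples, round(cfg$envelopeWindow * fs))
  emax <- max(env)
  if (emax <= 0) return(empty)
  above <- env >= cfg$thresholdFraction * emax
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (!nrow(runs)) return(empty)
  # merge runs separated by short sub-threshold dips
  gapMax <- round(cfg$mergeGap * fs)
  keepStart <- runs$start[1]
  merged <- list()
  curEnd <- runs$end[1]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - curEnd - 1L <= gapMax) {
        curEnd <- runs$end[i]
      } else {
        merged[[length(merged) + 1L]] <- c(keepStart, curEnd)
        keepStart <- runs$start[i]
        curEnd <- runs$end[i]
      }
    }
  }
  merged[[length(merged) + 1L]] <- c(keepStart, curEnd)
  m <- do.call(rbind, merged)
  out <- data.frame(start_sample = m[, 1], end_sample = m[, 2])
  out$duration_s <- (out$end_sample - out$start_sample + 1L) / fs
  out <- out[out$duration_s >= cfg$minDuration, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out$start_s <- (out$start_sample - 1L) / fs
  out$end_s <- out$end_sample / fs
  rownames(out) <- NULL
  out[, c("start_sample", "end_sample", "start_s", "end_s", "duration_s")]
}

#' Smoothed peak acceleration of a segment
#'
#' Maximum of the `smoothWindow`-sample moving average of the absolute
#' signal within the segment — the amplitude measure of a buzz. Smoothing
#' over two samples suppresses single-sample spike artifacts while
#' preserving the true peak of an oscillation.
#'
#' @param w a [Waveform-class].
#' @param startSample,endSample 1-based inclusive sample indices.
#' @param cfg an [extractionConfig()].
#' @return peak acceleration in m s^-2.
#' @export
peakAcceleration <- function(w, startSample, endSample,
                             cfg = extractionConfig()) {
  stopifnot(is(w, "Waveform"),
    startSample >= 1, endSample <= length(w@samples),
    startSample <= endSample)
  y <- abs(w@samples[startSample:endSample])
  k <- cfg$smoothWindow
  if (k <= 1L || length(y) < k) return(max(y))
  sm <- stats::filter(y, rep(1 / k, k), sides = 1)
  max(sm, na.rm = TRUE)
}

# One frame of cepstral f0 analysis. The cepstral peak fixes the octave
# (it tracks the harmonic comb, not the loudest partial); the estimate is
# then refined at the nearest spectral partial, parabolically
# interpolated on a zero-padded spectrum, which removes the quefrency
# quantisation and the envelope-induced bias a raw cepstral peak carries.
frameF0 <- function(fr, fs, f0Max, pad = 4L) {
  wl <- length(fr)
  h <- 0.5 * (1 - cos(2 * pi * (seq_len(wl) - 1) / wl))
  z <- c(fr * h, numeric((pad - 1L) * wl))
  N <- length(z)
  mag <- Mod(stats::fft(z))
  mmax <- max(mag[-1])
  if (mmax <= 0) return(NA_real_)
  cep <- Re(stats::fft(log(mag + 1e-6 * max(mag)), inverse = TRUE)) / N
  kmin <- max(2L, ceiling(fs / f0Max))
  kmax <- wl %/% 2  # need >= 2 periods per frame
  if (kmin >= kmax) return(NA_real_)
  # search a couple of bins below kmin too, so fundamentals just under
  # f0Max (whose quefrency sits at the band edge) are not lost; the
  # refined estimate is gated on f0Max below
  kk <- seq(max(2L, kmin - 2L), kmax)
  band <- cep[kk + 1L]
  # the candidate must be an interior local maximum: the global max often
  # sits on the monotone tail of the spectral-envelope component at the
  # band edge, which carries no periodicity information
  isMax <- which(diff(sign(diff(band))) == -2) + 1L
  if (!length(isMax)) return(NA_real_)
  kpk <- kk[isMax[which.max(band[isMax])]]
  f0c <- fs / kpk  # cepstral candidate, quantised to one quefrency bin
  binHz <- fs / wl
  df <- fs / N
  lo <- max(2L, floor((f0c - binHz) / df))
  hi <- min(N %/% 2 - 1L, ceiling((f0c + binHz) / df))
  if (lo >= hi) return(NA_real_)
  j <- lo + which.max(mag[(lo:hi) + 1L]) - 1L
  # validity: the candidate partial must be tonal (well above the
  # spectral background) and carry real energy relative to the strongest
  # partial; rejects noise frames and rahmonic aliases of tones > f0Max
  if (mag[j + 1L] < 0.05 * mmax) return(NA_real_)
  if (mag[j + 1L] < 10 * stats::median(mag[-1])) return(NA_real_)
  y0 <- mag[j]; y1 <- mag[j + 1L]; y2 <- mag[j + 2L]
  dj <- if (y0 - 2 * y1 + y2 < 0) 0.5 * (y0 - y2) / (y0 - 2 * y1 + y2) else 0
  f0 <- (j + dj) * df
  if (f0 > f0Max) return(NA_real_)  # out-of-range fundamentals are flagged
  f0
}

#' Fundamental frequency of a segment
#'
#' Frame-wise cepstral f0 estimation: each `f0WindowLen`-sample frame
#' (with `f0Overlap` overlap) is Hann-windowed and its real cepstrum
#' searched over the quefrencies corresponding to fundamentals in
#' (2 * samplingRate / f0WindowLen, f0Max]. The cepstral peak fixes the
#' octave — it tracks the spacing of the harmonic comb, not the loudest
#' partial — and the estimate is then refined at the nearest spectral
#' partial. A frame yields a value only if that partial is tonal (well
#' above the spectral background) and carries energy relative to the
#' strongest partial; the latter rejects rahmonic aliases of tones above
#' `f0Max`. The buzz-level estimate is the median of valid frames,
#' robust to octave errors at the buzz edges.
#'
#' @param w a [Waveform-class].
#' @param startSample,endSample 1-based inclusive segment bounds; the
#'   segment must span at least one analysis frame.
#' @param cfg an [extractionConfig()].
#' @return the fundamental frequency in Hz, or `NA_real_` when no frame
#'   yields a valid estimate; attributes "nFrames" and "nValid" count the
#'   frames analysed and retained.
#' @examples
#' fs <- 20480
#' t <- seq(0, 2, by = 1 / fs)[-1]
#' w <- Waveform(sin(2 * pi * 217 * t), fs)
#' fundamentalFrequency(w, 1, nSamples(w))
#' @export
fundamentalFrequency <- function(w, startSample, endSample,
                                 cfg = extractionConfig()) {
  stopifnot(is(w, "Waveform"))
  fs <- w@samplingRate
  if (cfg$f0Max >= fs / 2) {
    stop("f0Max must be below the Nyquist frequency")
  }
  wl <- cfg$f0WindowLen
  seg <- w@samples[startSample:endSample]
  if (length(seg) < wl) {
    stop("segment shorter than one analysis frame (", wl, " samples)")
  }
  hop <- max(1L, round(wl * (1 - cfg$f0Overlap)))
  starts <- seq(1L, length(seg) - wl + 1L, by = hop)
  vals <- vapply(starts, function(s) {
    frameF0(seg[s:(s + wl - 1L)], fs, cfg$f0Max)
  }, numeric(1))
  ok <- !is.na(vals)
  res <- if (any(ok)) stats::median(vals[ok]) else NA_real_
  attr(res, "nFrames") <- length(starts)
  attr(res, "nValid") <- sum(ok)
  res
}

#' Extract per-buzz features from a raw recording
#'
#' Composition of the pipeline: high-pass filter, envelope segmentation,
#' then per-segment duration, smoothed peak acceleration and cepstral
#' fundamental frequency. A segment whose f0 analysis fails (too short
#' for a frame, or no valid frame) is kept with `f0_hz = NA` and the
#' remaining segments are still processed.
#'
#' @param w a raw [Waveform-class].
#' @param cfg an [extractionConfig()].
#' @return data.frame with one row per buzz: buzz_index, start_s, end_s,
#'   duration_s, peak_accel_ms2, f0_hz.
#' @examples
#' plan <- recordingPlan(list(buzzSpec(0.5, 1.5, 217)), totalDuration = 3,
#'   noiseSd = 0.5)
#' extractFeatures(synthesizeRecording(plan))
#' @export
extractFeatures <- function(w, cfg = extractionConfig()) {
  hp <- highpass(w, cfg)
  segs <- segmentBuzzes(hp, cfg)
  out <- data.frame(
    buzz_index = seq_len(nrow(segs)),
    start_s = segs$start_s, end_s = segs$end_s,
    duration_s = segs$duration_s,
    peak_accel_ms2 = rep(NA_real_, nrow(segs)),
    f0_hz = rep(NA_real_, nrow(segs))
  )
  for (i in seq_len(nrow(segs))) {
    out$peak_accel_ms2[i] <- peakAcceleration(
      hp, segs$start_sample[i], segs$end_sample[i], cfg)
    f0 <- tryCatch(
      fundamentalFrequency(hp, segs$start_sample[i], segs$end_sample[i], cfg),
      error = function(e) NA_real_
    )
    out$f0_hz[i] <- as.numeric(f0)
  }
  out
}

#' Per-bee mean buzz features
#'
#' Averages buzz-level features within a bee — the per-bee means used as
#' the statistical unit in all downstream models. Buzzes whose f0 was
#' flagged missing are excluded from the f0 mean only.
#'
#' @param features data.frame from [extractFeatures()].
#' @param beeId label for the bee.
#' @return one-row data.frame: bee_id, n_buzzes, duration_s,
#'   peak_accel_ms2, f0_hz (arithmetic means). With zero buzzes a row of
#'   NAs is returned with a warning.
#' @export
perBeeMeans <- function(features, beeId = "bee") {
  if (!nrow(features)) {
    warning("no buzzes for bee '", beeId, "'; returning missing record")
    return(data.frame(
      bee_id = beeId, n_buzzes = 0L, duration_s = NA_real_,
      peak_accel_ms2 = NA_real_, f0_hz = NA_real_
    ))
  }
  data.frame(
    bee_id = beeId,
    n_buzzes = nrow(features),
    duration_s = mean(features$duration_s),
    peak_accel_ms2 = mean(features$peak_accel_ms2),
    f0_hz = if (all(is.na(features$f0_hz))) NA_real_ else
      mean(features$f0_hz, na.rm = TRUE)
  )
}
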