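#' Write a waveform as a WAV file
#'
#' Writes mono IEEE-float (32-bit) WAV with the sampling rate in the
#' header. Acceleration values are stored as-is (m s^-2), so round trips
#' through [readWaveformWav()] are lossless to single precision.
#'
#' @param w a [Waveform-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeWaveformWav <- function(w, path) {
  stopifnot(is(w, "Waveform"))
  x <- w@samples
  fs <- as.integer(round(w@samplingRate))
  con <- file(path, "wb")
  on.exit(close(con))
  dataBytes <- length(x) * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataBytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")  # IEEE float
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 4L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataBytes), con, size = 4, endian = "little")
  writeBin(x, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a WAV file as a waveform
#'
#' Reads mono (or first-channel) PCM 16-bit or IEEE-float 32-bit WAV; the
#' sampling rate in the header wins.
#'
#' @param path input file path.
#' @param sourceId label for the waveform; default the file name.
#' @return a [Waveform-class].
#' @export
readWaveformWav <- function(path, sourceId = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAV file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4) stop("no data chunk found in ", path)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        code = readBin(con, "integer", 1, size = 2, endian = "little"),
        channels = readBin(con, "integer", 1, size = 2, endian = "little"),
        rate = readBin(con, "integer", 1, size = 4, endian = "little")
      )
      readBin(con, "raw", sz - 8L)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      x <- if (fmt$code == 3L) {
        readBin(con, "numeric", sz / 4L, size = 4, endian = "little")
      } else if (fmt$code == 1L) {
        readBin(con, "integer", sz / 2L, size = 2, signed = TRUE,
          endian = "little") / 32768
      } else {
        stop("unsupported WAV format code ", fmt$code)
      }
      if (fmt$channels > 1L) x <- x[seq(1, length(x), by = fmt$channels)]
      return(Waveform(x, fmt$rate, sourceId))
    } else {
      readBin(con, "raw", sz + (sz %% 2L))
    }
  }
}

#' Write a waveform as two-column tab-delimited text
#'
#' Columns are time in seconds and acceleration in m s^-2, matching the
#' text export convention of the acquisition pipeline.
#'
#' @param w a [Waveform-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeWaveformTxt <- function(w, path) {
  stopifnot(is(w, "Waveform"))
  t <- (seq_along(w@samples) - 1) / w@samplingRate
  utils::write.table(
    data.frame(time_s = t, accel_ms2 = w@samples),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a two-column tab-delimited waveform
#'
#' Expects time (s) and acceleration (m s^-2) columns; the sampling rate
#' is inferred from the median time step.
#'
#' @param path input file path.
#' @param sourceId label for the waveform; default the file name.
#' @return a [Waveform-class].
#' @export
readWaveformTxt <- function(path, sourceId = basename(path)) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (ncol(d) < 2L) stop("expected two columns (time, acceleration) in ", path)
  dt <- stats::median(diff(d[[1]]))
  if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate from ", path)
  Waveform(d[[2]], 1 / dt, sourceId)
}

#' Read or guess a waveform file
#'
#' Dispatches on extension: `.wav` via [readWaveformWav()], anything else
#' via [readWaveformTxt()].
#'
#' @param path input file path.
#' @return a [Waveform-class].
#' @export
readWaveform <- function(path) {
  if (grepl("\\.wav$", path, ignore.case = TRUE)) {
    readWaveformWav(path)
  } else {
    readWaveformTxt(path)
  }
}
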