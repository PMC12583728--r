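#' Accessor generics
#'
#' Accessors for the package's S4 containers: `samples()` and
#' `samplingRate()` return a waveform's data and rate, `sourceId()` its
#' label, and `nSamples()` / `duration()` its size in samples and seconds.
#'
#' @param x an object, usually a [Waveform-class].
#' @param ... ignored.
#' @return `samples()` a numeric vector; `samplingRate()`, `duration()` a
#'   single number; `sourceId()` a character scalar; `nSamples()` an
#'   integer.
#' @name waveform-accessors
NULL

#' @rdname waveform-accessors
#' @export
setGeneric("samples", function(x, ...) standardGeneric("samples"))

#' @rdname waveform-accessors
#' @export
setGeneric("samplingRate", function(x, ...) standardGeneric("samplingRate"))

#' @rdname waveform-accessors
#' @export
setGeneric("sourceId", function(x, ...) standardGeneric("sourceId"))

#' @rdname waveform-accessors
#' @export
setGeneric("nSamples", function(x, ...) standardGeneric("nSamples"))

#' @rdname waveform-accessors
#' @export
setGeneric("duration", function(x, ...) standardGeneric("duration"))
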