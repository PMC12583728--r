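#' Construct a Waveform
#'
#' @param samples numeric vector of acceleration values (m s^-2).
#' @param samplingRate sampling rate in Hz.
#' @param sourceId label identifying the recording.
#' @return a [Waveform-class] object.
#' @examples
#' t <- seq(0, 1, by = 1 / 2000)
#' w <- Waveform(sin(2 * pi * 200 * t), 2000, "example")
#' duration(w)
#' @export
Waveform <- function(samples, samplingRate, sourceId = "waveform") {
  new("Waveform",
    samples = as.numeric(samples),
    samplingRate = as.numeric(samplingRate),
    sourceId = as.character(sourceId)
  )
}

#' @rdname waveform-accessors
#' @aliases samples,Waveform-method
setMethod("samples", "Waveform", function(x, ...) x@samples)

#' @rdname waveform-accessors
#' @aliases samplingRate,Waveform-method
setMethod("samplingRate", "Waveform", function(x, ...) x@samplingRate)

#' @rdname waveform-accessors
#' @aliases sourceId,Waveform-method
setMethod("sourceId", "Waveform", function(x, ...) x@sourceId)

#' @rdname waveform-accessors
#' @aliases nSamples,Waveform-method
setMethod("nSamples", "Waveform", function(x, ...) length(x@samples))

#' @rdname waveform-accessors
#' @aliases duration,Waveform-method
setMethod("duration", "Waveform",
  function(x, ...) length(x@samples) / x@samplingRate)

setMethod("show", "Waveform", function(object) {
  cat("Waveform '", object@sourceId, "': ",
    length(object@samples), " samples @ ", object@samplingRate, " Hz (",
    signif(length(object@samples) / object@samplingRate, 4), " s), ",
    "range [", signif(min(object@samples), 4), ", ",
    signif(max(object@samples), 4), "] m s^-2\n",
    sep = ""
  )
})
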