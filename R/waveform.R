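#' @import methods
NULL

#' Sampled mono audio
#'
#' `Waveform` is the common currency of the package: a vector of
#' dimensionless amplitudes in \[-1, 1\] with a sampling rate in Hz.
#' Call recordings, playback stimuli and synthesized colony sessions are
#' all `Waveform` objects.
#'
#' @slot samples Numeric vector of amplitudes; finite, `|x| <= 1` after
#'   normalization.
#' @slot rate Sampling rate in samples per second (Hz); positive scalar.
#'
#' @seealso [waveform()], [readWav()], [writeWav()], [synthesizeCall()]
#' @export
setClass("Waveform",
  representation(samples = "numeric", rate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
      msg <- c(msg, "rate must be a single positive finite number")
    if (length(object@samples) && !all(is.finite(object@samples)))
      msg <- c(msg, "all samples must be finite")
    else if (length(object@samples) && max(abs(object@samples)) > 1 + 1e-9)
      msg <- c(msg, "samples must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a Waveform
#'
#' @param samples Numeric amplitude vector in \[-1, 1\].
#' @param rate Sampling rate in Hz.
#' @return A [Waveform-class] object.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * (0:999) / 8000), 8000)
#' duration(w)
#' @export
waveform <- function(samples, rate) {
  new("Waveform", samples = as.numeric(samples), rate = as.numeric(rate))
}

#' @describeIn waveform Amplitude vector.
#' @param x A `Waveform`.
#' @export
samples <- function(x) {
  stopifnot(is(x, "Waveform"))
  x@samples
}

#' @describeIn waveform Sampling rate in Hz.
#' @export
sampleRate <- function(x) {
  stopifnot(is(x, "Waveform"))
  x@rate
}

#' @export
setGeneric("duration", function(x, ...) standardGeneric("duration"))

#' @describeIn waveform Duration in seconds.
#' @export
setMethod("duration", "Waveform", function(x, ...) length(x@samples) / x@rate)

setMethod("length", "Waveform", function(x) length(x@samples))

setMethod("show", "Waveform", function(object) {
  cat(sprintf(
    "Waveform: %d samples @ %g Hz (%.3f s), peak %.3f\n",
    length(object@samples), object@rate,
    length(object@samples) / object@rate,
    if (length(object@samples)) max(abs(object@samples)) else 0
  ))
})

#' Peak-normalize a waveform
#'
#' Scales amplitudes so the absolute peak equals `peak` (no-op on silence).
#'
#' @param x A [Waveform-class].
#' @param peak Target absolute peak, in (0, 1].
#' @return A normalized `Waveform`.
#' @export
normalizeWaveform <- function(x, peak = 0.95) {
  stopifnot(is(x, "Waveform"), peak > 0, peak <= 1)
  m <- if (length(x@samples)) max(abs(x@samples)) else 0
  if (m == 0) return(x)
  waveform(x@samples * (peak / m), x@rate)
}

#' Concatenate waveforms with silent padding
#'
#' @param waves List of `Waveform`s sharing one sampling rate.
#' @param gap_s Seconds of silence inserted between consecutive waves.
#' @return A single `Waveform`.
#' @export
concatWaveforms <- function(waves, gap_s = 0) {
  stopifnot(length(waves) >= 1, all(vapply(waves, is, TRUE, "Waveform")))
  rate <- sampleRate(waves[[1L]])
  if (!all(vapply(waves, sampleRate, 0) == rate))
    stop("all waveforms must share one sampling rate")
  gap <- numeric(round(gap_s * rate))
  out <- waves[[1L]]@samples
  for (w in waves[-1L]) out <- c(out, gap, w@samples)
  waveform(out, rate)
}
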