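#' Playback stimulus templates
#'
#' The three playback sequences: a two-call up step (`"a"`), a two-call
#' down step (`"b"`), and a three-call up-then-down step (`"ab"`). Calls
#' alternate between average peak frequencies of 119 and 153 Hz, each call
#' 0.7 s long with a 0.05 s inter-call interval.
#'
#' @slot template_id One of `"a"`, `"b"`, `"ab"`.
#' @slot peak_freqs Ordered per-call average peak frequencies (Hz).
#' @slot call_duration_s Call duration (s).
#' @slot inter_call_s Inter-call interval (s).
#' @slot directions Successive step directions, `"up"`/`"down"`; one fewer
#'   than the number of calls.
#' @export
setClass("StimulusTemplate",
  representation(template_id = "character", peak_freqs = "numeric",
                 call_duration_s = "numeric", inter_call_s = "numeric",
                 directions = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@directions) != length(object@peak_freqs) - 1L)
      msg <- c(msg, "need one direction per successive call pair")
    if (any(diff(object@peak_freqs) == 0))
      msg <- c(msg, "consecutive peak frequencies must differ")
    if (object@call_duration_s <= 0 || object@inter_call_s <= 0)
      msg <- c(msg, "durations and intervals must be positive")
    if (!all(object@directions %in% c("up", "down")))
      msg <- c(msg, "directions must be 'up' or 'down'")
    ok <- ifelse(object@directions == "up", diff(object@peak_freqs) > 0,
                 diff(object@peak_freqs) < 0)
    if (!all(ok)) msg <- c(msg, "directions inconsistent with peak frequencies")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "StimulusTemplate", function(object) {
  cat(sprintf("StimulusTemplate '%s': %s Hz, %g s calls, %g s ICI (%s)\n",
              object@template_id,
              paste(object@peak_freqs, collapse = " -> "),
              object@call_duration_s, object@inter_call_s,
              paste(object@directions, collapse = ", ")))
})

#' Construct a stimulus template
#'
#' @param template_id `"a"` (up), `"b"` (down) or `"ab"` (up-down).
#' @param low_hz,high_hz The two alternating average peak frequencies.
#' @param call_duration_s Per-call duration (s).
#' @param inter_call_s Silence between calls (s).
#' @return A [StimulusTemplate-class].
#' @examples
#' stimulusTemplate("ab")
#' @export
stimulusTemplate <- function(template_id = c("a", "b", "ab"),
                             low_hz = 119, high_hz = 153,
                             call_duration_s = 0.7, inter_call_s = 0.05) {
  if (!is.character(template_id) || !template_id[1] %in% c("a", "b", "ab"))
    stop("unknown template_id: ", template_id[1],
         " (must be 'a', 'b' or 'ab')")
  template_id <- template_id[1]
  freqs <- switch(template_id,
    a = c(low_hz, high_hz),
    b = c(high_hz, low_hz),
    ab = c(low_hz, high_hz, low_hz))
  dirs <- switch(template_id, a = "up", b = "down", ab = c("up", "down"))
  new("StimulusTemplate", template_id = template_id, peak_freqs = freqs,
      call_duration_s = call_duration_s, inter_call_s = inter_call_s,
      directions = dirs)
}

#' @describeIn stimulusTemplate Number of calls in the sequence.
#' @param x A `StimulusTemplate`.
#' @export
templateSize <- function(x) {
  stopifnot(is(x, "StimulusTemplate"))
  length(x@peak_freqs)
}

#' @describeIn stimulusTemplate Per-call target peak frequencies (Hz).
#' @export
peakFreqs <- function(x) {
  stopifnot(is(x, "StimulusTemplate"))
  x@peak_freqs
}

#' @describeIn stimulusTemplate Step directions (`"up"`/`"down"`).
#' @export
directionPattern <- function(x) {
  stopifnot(is(x, "StimulusTemplate"))
  x@directions
}

# Phase-vocoder time stretch by factor `s` (output ~ s * input length).
# Hann analysis/synthesis windows, fixed analysis hop, phase propagation per
# bin, amplitude-normalized overlap-add.
.pvStretch <- function(x, s, win = 2048L, hop_a = 512L) {
  n <- length(x)
  if (n <= win) {  # too short for framing: fall back to linear resample
    return(stats::approx(seq_len(n), x,
                         xout = seq(1, n, length.out = round(n * s)))$y)
  }
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(win) - 1L) / win))
  starts <- seq(1L, n - win + 1L, by = hop_a)
  nf <- length(starts)
  fm <- matrix(0, win, nf)
  for (i in seq_len(nf)) fm[, i] <- x[starts[i] + 0:(win - 1L)] * hann
  S <- stats::mvfft(fm)
  mag <- Mod(S); phs <- Arg(S)

  hop_s <- s * hop_a
  # signed bin frequencies so conjugate bins advance antisymmetrically
  # (keeps the modified spectrum Hermitian for non-integer synthesis hops)
  k0 <- c(0:(win %/% 2L), seq.int(-(win %/% 2L - 1L), -1L))
  omega <- 2 * pi * k0 / win   # rad/sample per bin
  out_len <- ceiling((nf - 1L) * hop_s) + win
  out <- numeric(out_len)
  wsum <- numeric(out_len)
  synth_phase <- phs[, 1L]
  pos <- 1
  for (i in seq_len(nf)) {
    if (i > 1L) {
      dphi <- phs[, i] - phs[, i - 1L] - omega * hop_a
      dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
      inst <- omega + dphi / hop_a
      synth_phase <- synth_phase + inst * hop_s
    }
    frame <- Re(stats::fft(mag[, i] * exp(1i * synth_phase), inverse = TRUE)) / win
    j <- round(pos)
    idx <- j:(j + win - 1L)
    out[idx] <- out[idx] + frame * hann
    wsum[idx] <- wsum[idx] + hann^2
    pos <- pos + hop_s
  }
  # clamp the normalizer so partially-covered edge samples taper instead of
  # being amplified
  out <- out / pmax(wsum, 0.1 * max(wsum))
  out[seq_len(min(out_len, ceiling(n * s)))]
}

#' Duration-preserving pitch shift
#'
#' Scales every frequency component of the call by `ratio` while keeping
#' its duration constant, the same behaviour as the pitch-shifter used to
#' construct the playback stimuli: the harmonic structure moves as a whole,
#' so harmonics remain integer multiples of the shifted fundamental.
#' Implemented as a phase-vocoder time stretch by `ratio` followed by
#' resampling back to the original length.
#'
#' @param x A [Waveform-class].
#' @param ratio Frequency scaling factor (> 0). Shifts that would push the
#'   call's dominant energy past Nyquist are rejected.
#' @param win,hop Phase-vocoder window and analysis hop in samples; the
#'   defaults suit 96 kHz audio, use proportionally smaller values at low
#'   rates.
#' @return A [Waveform-class] with exactly the input length.
#' @examples
#' w <- synthesizeCall(119, 0.2, rate = 48000)
#' up <- pitchShift(w, 153 / 119, win = 1024L, hop = 256L)
#' duration(up) == duration(w)
#' @export
pitchShift <- function(x, ratio, win = 2048L, hop = win %/% 4L) {
  stopifnot(is(x, "Waveform"))
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) ||
      ratio <= 0)
    stop("ratio must be a single positive number")
  n <- length(x@samples)
  if (n == 0) return(x)
  if (ratio > 1) {
    # reject shifts that would alias: demand <1% of spectral energy above
    # Nyquist/ratio before shifting
    P <- Mod(stats::fft(x@samples))^2
    half <- P[seq_len(n %/% 2L + 1L)]
    cut <- ceiling((x@rate / (2 * ratio)) / (x@rate / n))
    if (cut < length(half) &&
        sum(half[(cut + 1L):length(half)]) > 0.01 * sum(half))
      stop("shift would push dominant energy past Nyquist")
  }
  if (ratio == 1) return(x)
  stretched <- .pvStretch(x@samples, ratio, win = as.integer(win),
                          hop_a = as.integer(hop))
  # read the stretched signal at step `ratio`: original duration, freqs x ratio
  pos <- 1 + (seq_len(n) - 1L) * ratio
  pos <- pmin(pos, length(stretched))
  y <- stats::spline(seq_along(stretched), stretched, xout = pos,
                     method = "fmm")$y
  waveform(pmin(1, pmax(-1, y)), x@rate)
}

#' Build a playback stimulus sequence
#'
#' Pitch-shifts a source call to each of the template's per-call target
#' peak frequencies and concatenates the copies with the template's
#' inter-call interval of silence.
#'
#' @param template A [StimulusTemplate-class].
#' @param source A [Waveform-class] source call (synthesized or recorded);
#'   should already have the template call duration.
#' @param source_peak_hz Average peak frequency of `source` in Hz; measured
#'   with [extractFeatures()] when `NULL`.
#' @param params [spectroParams()] used for the measurement.
#' @param win,hop Passed to [pitchShift()].
#' @return A list with `wave` (the stimulus [Waveform-class]) and
#'   `annotation` (data.frame of per-call `onset_s`, `offset_s`,
#'   `target_hz`, `position`).
#' @export
buildStimulus <- function(template, source, source_peak_hz = NULL,
                          params = spectroParams(), win = 2048L,
                          hop = win %/% 4L) {
  stopifnot(is(template, "StimulusTemplate"), is(source, "Waveform"))
  if (is.null(source_peak_hz))
    source_peak_hz <- extractFeatures(source, params)$mean_peak
  if (!is.finite(source_peak_hz) || source_peak_hz <= 0)
    stop("could not determine the source call's peak frequency")
  rate <- sampleRate(source)
  calls <- lapply(template@peak_freqs, function(f) {
    r <- f / source_peak_hz
    if (abs(r - 1) < 1e-9) source else pitchShift(source, r, win, hop)
  })
  wave <- concatWaveforms(calls, gap_s = template@inter_call_s)
  durs <- vapply(calls, duration, 0)
  onsets <- cumsum(c(0, head(durs, -1) + template@inter_call_s))
  ann <- data.frame(onset_s = onsets, offset_s = onsets + durs,
                    target_hz = template@peak_freqs,
                    position = seq_along(durs))
  list(wave = normalizeWaveform(wave), annotation = ann)
}

#' Repeat a stimulus into a playback block
#'
#' @param x A [Waveform-class] stimulus sequence.
#' @param repetitions Number of repeats (>= 1); playbacks use blocks of 50.
#' @param inter_sequence_s Silence between repeats in seconds (>= 0).
#' @return A [Waveform-class].
#' @export
buildBlock <- function(x, repetitions = 50L, inter_sequence_s = 1.0) {
  stopifnot(is(x, "Waveform"))
  repetitions <- as.integer(repetitions)
  if (is.na(repetitions) || repetitions < 1L)
    stop("repetitions must be >= 1")
  if (inter_sequence_s < 0) stop("inter_sequence_s must be >= 0")
  if (length(x@samples) == 0) stop("stimulus is empty")
  if (repetitions == 1L) return(x)
  concatWaveforms(rep(list(x), repetitions), gap_s = inter_sequence_s)
}
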