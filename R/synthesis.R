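#' Synthesize a tonal harmonic pup call
#'
#' Additive-harmonic synthesis of the kind of short tonal call grey seal
#' pups produce: a fundamental-frequency contour plus integer-multiple
#' harmonics with a 1/h^`rolloff` amplitude taper, shaped by a raised-cosine
#' attack/decay envelope that avoids spectral splatter at the call edges.
#'
#' @param f0 Fundamental-frequency contour in Hz: either a single value
#'   (constant F0) or a vector that is linearly interpolated across the call.
#' @param duration_s Call duration in seconds (> 0).
#' @param n_harmonics Number of harmonics including the fundamental (>= 1).
#' @param rate Sampling rate in Hz.
#' @param rolloff Spectral taper exponent: harmonic h has amplitude
#'   `h^-rolloff`. The default 1 (-6 dB/octave) keeps the fundamental the
#'   peak-frequency band, as in natural pup calls.
#' @param edge_s Raised-cosine attack and decay length in seconds (>= 20 ms
#'   by default).
#' @param peak Normalization peak amplitude.
#' @return A [Waveform-class] with `round(duration_s * rate)` samples.
#' @examples
#' w <- synthesizeCall(119, 0.7, rate = 96000)
#' length(samples(w))  # 67200
#' @export
synthesizeCall <- function(f0, duration_s, n_harmonics = 3L, rate = 96000,
                           rolloff = 1, edge_s = 0.02, peak = 0.95) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L ||
      !is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be a single positive number")
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1")
  if (any(!is.finite(f0)) || any(f0 <= 0))
    stop("f0 contour must be positive and finite")
  if (max(f0) * n_harmonics >= rate / 2)
    stop(sprintf(
      "contour exceeds Nyquist after harmonics: %g Hz x %d harmonics >= %g Hz",
      max(f0), as.integer(n_harmonics), rate / 2))

  n <- round(duration_s * rate)
  f0_t <- if (length(f0) == 1L) rep(f0, n) else
    stats::approx(seq(0, 1, length.out = length(f0)),
                  f0, xout = seq(0, 1, length.out = n))$y
  phase <- 2 * pi * cumsum(f0_t) / rate
  x <- numeric(n)
  for (h in seq_len(n_harmonics)) x <- x + h^(-rolloff) * sin(h * phase)

  edge_n <- min(round(edge_s * rate), floor(n / 2))
  env <- rep(1, n)
  if (edge_n > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(edge_n) / edge_n))
    env[seq_len(edge_n)] <- ramp
    env[n - edge_n + seq_len(edge_n)] <- rev(ramp)
  }
  y <- x * env
  m <- max(abs(y))
  if (m > 0) y <- y * (peak / m)
  waveform(y, rate)
}
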