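#' Spectrographic analysis settings
#'
#' Bundle of the spectrogram/feature settings used throughout the pipeline.
#' The defaults reproduce the field analysis settings at 96 kHz:
#' FFT 2048 (46.875 Hz bins), Hamming taper, hop of half a window
#' (10.66 ms), 100 Hz high-pass. For low-rate synthetic audio pass a
#' proportionally smaller `fft` so the analysis window stays near 20-30 ms.
#'
#' @param fft FFT size in samples (power of two).
#' @param hop Hop between frames in samples; defaults to `fft / 2`.
#' @param window Taper name; only `"hamming"` is implemented.
#' @param highpass High-pass cutoff in Hz applied before analysis.
#' @param f0_range Length-2 autocorrelation F0 search band in Hz.
#' @param frame_step_ms Feature-contour step in ms (F0/peak measured every
#'   `frame_step_ms`).
#' @param voicing_min Minimum normalized autocorrelation peak for a frame
#'   to count as voiced.
#' @param threshold_db Segmentation energy threshold in dB relative to the
#'   95th-percentile frame RMS.
#' @param max_gap_ms Silent gaps up to this length are bridged within one
#'   call; longer gaps split calls.
#' @param min_call_ms Segments shorter than this are discarded.
#' @return A list of class `"spectroParams"`.
#' @export
spectroParams <- function(fft = 2048L, hop = NULL, window = "hamming",
                          highpass = 100, f0_range = c(60, 800),
                          frame_step_ms = 5, voicing_min = 0.5,
                          threshold_db = -30, max_gap_ms = 5,
                          min_call_ms = 50) {
  fft <- as.integer(fft)
  if (fft <= 0 || bitwAnd(fft, fft - 1L) != 0L)
    stop("fft must be a positive power of two")
  if (is.null(hop)) hop <- fft %/% 2L
  hop <- as.integer(hop)
  if (hop <= 0 || hop > fft) stop("hop must be in (0, fft]")
  if (!identical(window, "hamming")) stop("only the hamming window is supported")
  stopifnot(length(f0_range) == 2L, f0_range[1] > 0, f0_range[2] > f0_range[1])
  structure(list(fft = fft, hop = hop, window = window, highpass = highpass,
                 f0_range = f0_range, frame_step_ms = frame_step_ms,
                 voicing_min = voicing_min, threshold_db = threshold_db,
                 max_gap_ms = max_gap_ms, min_call_ms = min_call_ms),
            class = "spectroParams")
}

#' Zero-phase high-pass filter
#'
#' 4th-order Butterworth applied forward and backward, so the passband is
#' ripple-free, the stopband roll-off is doubled to 48 dB/octave, and call
#' onsets are not delayed (zero phase).
#'
#' @param x A [Waveform-class].
#' @param cutoff Cutoff frequency in Hz; must be below Nyquist.
#' @param order Butterworth order of the one-way prototype.
#' @return Filtered [Waveform-class].
#' @export
highpassFilter <- function(x, cutoff = 100, order = 4L) {
  stopifnot(is(x, "Waveform"))
  nyq <- x@rate / 2
  if (cutoff <= 0 || cutoff >= nyq)
    stop(sprintf("cutoff must lie in (0, %g) Hz", nyq))
  if (length(x@samples) == 0) return(x)
  # forward-backward (zero-phase) application in the frequency domain.
  # A bilinear-transform Butterworth high-pass of order m has
  # |H(w)|^2 = 1 / (1 + (tan(wc/2)/tan(w/2))^(2m)); applying the squared
  # magnitude doubles the roll-off exactly as filtfilt does, without the
  # recursion cost on long sessions.
  n0 <- length(x@samples)
  n <- stats::nextn(n0)
  X <- stats::fft(c(x@samples, numeric(n - n0)))
  w <- 2 * pi * (seq_len(n) - 1L) / n
  w <- pmin(w, 2 * pi - w)                 # fold to [0, pi]
  wc <- pi * cutoff / nyq
  ratio <- tan(wc / 2) / tan(pmax(w, 1e-12) / 2)
  H2 <- 1 / (1 + ratio^(2 * order))
  H2[1L] <- 0
  y <- Re(stats::fft(X * H2, inverse = TRUE))[seq_len(n0)] / n
  waveform(pmin(1, pmax(-1, y)), x@rate)
}

# Hamming-tapered frame matrix centred on `centers` (sample indices, 1-based).
# Frames reaching past the signal are zero-padded.
.frameMatrix <- function(x, centers, width) {
  offs <- seq_len(width) - 1L - (width %/% 2L)
  idx <- outer(offs, as.integer(round(centers)), `+`)
  bad <- idx < 1L | idx > length(x)
  idx[bad] <- 1L
  fm <- matrix(x[idx], nrow = width)
  fm[bad] <- 0
  fm
}

#' Spectrogram magnitude matrix
#'
#' Short-time Fourier magnitude with Hamming taper. The frequency bin width
#' is exactly `rate / fft`; at 96 kHz and FFT 2048 that is 46.875 Hz
#' (46.87 Hz when truncated to two decimals, as spectrogram software
#' commonly displays it).
#'
#' @param x A [Waveform-class], at least `fft` samples long.
#' @param params A [spectroParams()] list.
#' @return A list with `mag` (bins x frames magnitude matrix), `freq` (Hz
#'   per bin), `time` (s per frame centre), and `bin_width` (Hz).
#' @export
spectrogramMatrix <- function(x, params = spectroParams()) {
  stopifnot(is(x, "Waveform"))
  n <- length(x@samples)
  if (n < params$fft) stop("signal shorter than one analysis frame")
  win <- .hammingWin(params$fft)
  starts <- seq(1L, n - params$fft + 1L, by = params$hop)
  centers <- starts + params$fft %/% 2L
  fm <- .frameMatrix(x@samples, centers, params$fft) * win
  sp <- stats::mvfft(fm)
  nb <- params$fft %/% 2L + 1L
  list(mag = Mod(sp[seq_len(nb), , drop = FALSE]),
       freq = (seq_len(nb) - 1L) * x@rate / params$fft,
       time = (centers - 1L) / x@rate,
       bin_width = x@rate / params$fft)
}

.hammingWin <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))

#' Segment a recording into calls
#'
#' Energy-based segmentation with the 5 ms gap rule: maximal runs of
#' supra-threshold short-frame energy are calls; silent breaks of up to
#' `max_gap_ms` are bridged inside one call, longer breaks split calls.
#' The threshold is `threshold_db` relative to the session's
#' 95th-percentile frame RMS, and segments shorter than `min_call_ms`
#' are dropped.
#'
#' @param x A high-pass-filtered [Waveform-class].
#' @param params A [spectroParams()]; uses `threshold_db`, `max_gap_ms`,
#'   `min_call_ms`.
#' @return A data.frame with columns `onset_s`, `offset_s`, `duration_s`;
#'   zero rows for silence.
#' @export
segmentCalls <- function(x, params = spectroParams()) {
  stopifnot(is(x, "Waveform"))
  empty <- data.frame(onset_s = numeric(), offset_s = numeric(),
                      duration_s = numeric())
  n <- length(x@samples)
  win <- max(2L, round(0.005 * x@rate))      # 5 ms energy frames
  hop <- max(1L, round(0.001 * x@rate))      # 1 ms hop
  if (n < win) return(empty)
  cs <- cumsum(c(0, x@samples^2))
  starts <- seq(1L, n - win + 1L, by = hop)
  rms <- sqrt((cs[starts + win] - cs[starts]) / win)
  ref <- stats::quantile(rms, 0.95, names = FALSE)
  if (ref <= 0) return(empty)
  active <- rms > ref * 10^(params$threshold_db / 20)
  if (!any(active)) return(empty)

  r <- rle(active)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  seg <- cbind(begs[r$values], ends[r$values])   # active runs, frame indices
  # merge runs separated by <= max_gap_ms
  if (nrow(seg) > 1L) {
    max_gap_frames <- params$max_gap_ms / 1000 * x@rate / hop
    merged <- seg[1L, , drop = FALSE]
    for (i in 2L:nrow(seg)) {
      gap <- seg[i, 1L] - merged[nrow(merged), 2L] - 1L
      if (gap <= max_gap_frames) merged[nrow(merged), 2L] <- seg[i, 2L]
      else merged <- rbind(merged, seg[i, ])
    }
    seg <- merged
  }
  onset <- (starts[seg[, 1L]] - 1L) / x@rate
  offset <- (starts[seg[, 2L]] - 1L + win) / x@rate
  keep <- (offset - onset) >= params$min_call_ms / 1000
  data.frame(onset_s = onset[keep], offset_s = offset[keep],
             duration_s = offset[keep] - onset[keep])
}

# Parabolic interpolation of a discrete peak: returns fractional offset in
# (-0.5, 0.5) and interpolated height, given heights (left, centre, right).
.parabolic <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  d <- ifelse(abs(denom) > .Machine$double.eps,
              0.5 * (ym1 - yp1) / denom, 0)
  d <- pmin(0.5, pmax(-0.5, d))
  list(offset = d, height = y0 - 0.25 * (ym1 - yp1) * d)
}

# Core frame analysis: F0 by normalized autocorrelation with parabolic
# interpolation (smallest-lag rule among near-maximal peaks to avoid octave
# errors) and peak frequency as the parabolic-interpolated argmax of the
# Hamming power spectrum. Vectorized across frames via mvfft/max.col.
.analyzeFrames <- function(x, rate, centers, params) {
  nfr <- length(centers)
  f0 <- rep(NA_real_, nfr)
  pk <- rep(NA_real_, nfr)
  q <- rep(NA_real_, nfr)
  if (nfr == 0) return(list(f0 = f0, peak = pk, quality = q))

  ## --- F0: autocorrelation over a window long enough for the search band
  lag_max <- ceiling(rate / params$f0_range[1])
  w <- as.integer(2^ceiling(log2(1.6 * lag_max)))   # covers fmin's period
  w <- min(w, as.integer(2^floor(log2(max(length(x), 2)))))
  nfft <- 2L * w
  fm <- .frameMatrix(x, centers, w)
  fm <- sweep(fm, 2, colMeans(fm))
  sp <- stats::mvfft(rbind(fm, matrix(0, w, nfr)))
  ac <- Re(stats::mvfft(Re(sp)^2 + Im(sp)^2, inverse = TRUE)) / nfft
  r0 <- ac[1L, ]
  lag_lo <- max(2L, floor(rate / params$f0_range[2]))
  lag_hi <- min(w - 2L, ceiling(rate / params$f0_range[1]))
  if (lag_hi > lag_lo + 2L) {
    R <- ac[(lag_lo:lag_hi) + 1L, , drop = FALSE]
    R <- sweep(R, 2, pmax(r0, .Machine$double.eps), `/`)
    m <- nrow(R)
    locmax <- rbind(FALSE,
                    R[2:(m - 1L), , drop = FALSE] > R[1:(m - 2L), , drop = FALSE] &
                    R[2:(m - 1L), , drop = FALSE] >= R[3:m, , drop = FALSE],
                    FALSE)
    colmax <- R[cbind(max.col(t(R), ties.method = "first"), seq_len(nfr))]
    cand <- locmax & sweep(R, 2, 0.9 * colmax, `>=`)
    has <- colSums(cand) > 0L
    pick <- max.col(t(cand), ties.method = "first")   # smallest qualifying lag
    ok <- which(has & r0 > 0)
    if (length(ok)) {
      ii <- cbind(pick[ok], ok)
      qv <- R[ii]
      par <- .parabolic(R[cbind(pick[ok] - 1L, ok)], qv, R[cbind(pick[ok] + 1L, ok)])
      lag <- (lag_lo + pick[ok] - 1L) + par$offset
      f0v <- rate / lag
      voiced <- qv >= params$voicing_min & f0v >= params$f0_range[1] &
        f0v <= params$f0_range[2]
      f0[ok[voiced]] <- f0v[voiced]
      q[ok] <- qv
    }
  }

  ## --- peak frequency: Hamming power spectrum per frame
  wp <- min(params$fft, as.integer(2^floor(log2(max(length(x), 2)))))
  fmp <- .frameMatrix(x, centers, wp) * .hammingWin(wp)
  pad <- params$fft - wp
  if (pad > 0) fmp <- rbind(fmp, matrix(0, pad, nfr))
  spp <- stats::mvfft(fmp)[seq_len(params$fft %/% 2L + 1L), , drop = FALSE]
  P <- Re(spp)^2 + Im(spp)^2
  bw <- rate / params$fft
  b_lo <- max(1L, floor(params$f0_range[1] / bw))    # skip DC/envelope bins
  if (nrow(P) > b_lo + 2L) {
    Pb <- P[(b_lo + 1L):nrow(P), , drop = FALSE]
    amax <- max.col(t(Pb), ties.method = "first")
    inner <- amax > 1L & amax < nrow(Pb)
    off <- numeric(nfr)
    lp <- log(Pb + .Machine$double.xmin)
    if (any(inner)) {
      j <- which(inner)
      par <- .parabolic(lp[cbind(amax[j] - 1L, j)], lp[cbind(amax[j], j)],
                        lp[cbind(amax[j] + 1L, j)])
      off[j] <- par$offset
    }
    pk <- (b_lo + amax - 1L + off) * bw
    pk[colSums(Pb) == 0] <- NA_real_
  }
  list(f0 = f0, peak = pk, quality = q)
}

#' Measure acoustic features of one call segment
#'
#' Fundamental and peak frequency are measured every `frame_step_ms`
#' (5 ms by default) across the segment and averaged over voiced frames:
#' F0 by normalized autocorrelation with parabolic interpolation over the
#' `f0_range` search band, peak frequency as the interpolated argmax of
#' the Hamming power spectrum. Frames whose autocorrelation peak quality
#' falls below `voicing_min` are flagged unvoiced (`NA` in the contour)
#' and excluded from the averages.
#'
#' @param x A [Waveform-class] holding the segment samples (or a longer
#'   signal, with `onset_s`/`offset_s` delimiting the segment).
#' @param params A [spectroParams()].
#' @param onset_s,offset_s Segment boundaries in seconds within `x`;
#'   default to the whole waveform.
#' @return A list of class `"callFeatures"`: `duration_s`, `f0_contour`,
#'   `peak_contour` (Hz every frame step, `NA` = unvoiced), `mean_f0`,
#'   `min_f0`, `max_f0`, `mean_peak`, `n_frames`, `n_voiced`.
#' @export
extractFeatures <- function(x, params = spectroParams(), onset_s = 0,
                            offset_s = duration(x)) {
  stopifnot(is(x, "Waveform"))
  step <- params$frame_step_ms / 1000
  dur <- offset_s - onset_s
  if (dur < 2 * step)
    stop("segment too short: need at least two analysis frames")
  centers_s <- seq(onset_s + step / 2, offset_s - step / 2, by = step)
  centers <- centers_s * x@rate + 1
  fr <- .analyzeFrames(x@samples, x@rate, centers, params)
  voiced <- !is.na(fr$f0)
  structure(list(
    duration_s = dur,
    f0_contour = fr$f0,
    peak_contour = fr$peak,
    mean_f0 = if (any(voiced)) mean(fr$f0[voiced]) else NA_real_,
    min_f0 = if (any(voiced)) min(fr$f0[voiced]) else NA_real_,
    max_f0 = if (any(voiced)) max(fr$f0[voiced]) else NA_real_,
    mean_peak = if (any(voiced)) mean(fr$peak[voiced], na.rm = TRUE) else NA_real_,
    n_frames = length(centers),
    n_voiced = sum(voiced)
  ), class = "callFeatures")
}

#' @export
print.callFeatures <- function(x, ...) {
  cat(sprintf(
    "Call features: %.3f s, mean F0 %.1f Hz [%.1f-%.1f], mean peak %.1f Hz (%d/%d voiced frames)\n",
    x$duration_s, x$mean_f0, x$min_f0, x$max_f0, x$mean_peak,
    x$n_voiced, x$n_frames))
  invisible(x)
}

#' Segment a session and measure every call
#'
#' Convenience wrapper: high-pass filter, segment, and extract per-call
#' features, returning one row per call.
#'
#' @param x A [Waveform-class] session recording.
#' @param params A [spectroParams()].
#' @param filter Apply the high-pass filter first (set `FALSE` if `x` is
#'   already filtered).
#' @return A data.frame with columns `onset_s`, `offset_s`, `duration_s`,
#'   `mean_f0`, `min_f0`, `max_f0`, `mean_peak`, `n_frames`, `n_voiced`.
#' @export
measureSession <- function(x, params = spectroParams(), filter = TRUE) {
  if (filter) x <- highpassFilter(x, params$highpass)
  seg <- segmentCalls(x, params)
  n <- nrow(seg)
  cols <- list(mean_f0 = rep(NA_real_, n), min_f0 = rep(NA_real_, n),
               max_f0 = rep(NA_real_, n), mean_peak = rep(NA_real_, n),
               n_frames = integer(n), n_voiced = integer(n))
  for (i in seq_len(n)) {
    f <- extractFeatures(x, params, seg$onset_s[i], seg$offset_s[i])
    cols$mean_f0[i] <- f$mean_f0; cols$min_f0[i] <- f$min_f0
    cols$max_f0[i] <- f$max_f0; cols$mean_peak[i] <- f$mean_peak
    cols$n_frames[i] <- f$n_frames; cols$n_voiced[i] <- f$n_voiced
  }
  cbind(seg, as.data.frame(cols))
}

#' Estimate formant frequencies by linear prediction
#'
#' Optional feature. Fits LPC coefficients (autocorrelation/Yule-Walker
#' method) to the segment and reports the angles of complex roots with
#' bandwidth under 400 Hz as formants, sorted ascending.
#'
#' @param x A [Waveform-class] segment.
#' @param lpc_order LPC model order, in \[8, 16\].
#' @param max_bandwidth_hz Roots with larger bandwidth are discarded.
#' @return Numeric vector of formant frequencies in Hz (possibly empty).
#' @export
estimateFormants <- function(x, lpc_order = 12L, max_bandwidth_hz = 400) {
  stopifnot(is(x, "Waveform"))
  lpc_order <- as.integer(lpc_order)
  if (lpc_order < 8L || lpc_order > 16L) stop("lpc_order must be in [8, 16]")
  s <- x@samples
  if (length(s) <= lpc_order) stop("segment shorter than LPC order")
  s <- s - mean(s)
  # mild pre-emphasis flattens the harmonic rolloff before pole fitting
  s <- c(s[1], s[-1] - 0.95 * s[-length(s)])
  fit <- stats::ar.yw(s, aic = FALSE, order.max = lpc_order, demean = FALSE)
  a <- fit$ar
  if (!length(a)) return(numeric())
  rts <- polyroot(c(1, -a))
  rts <- rts[Im(rts) > 1e-9]
  if (!length(rts)) return(numeric())
  freq <- Arg(rts) * x@rate / (2 * pi)
  bw <- -x@rate / pi * log(pmin(Mod(rts), 1 - 1e-12))
  keep <- bw < max_bandwidth_hz & freq > 0 & freq < x@rate / 2
  sort(freq[keep])
}
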