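# Shared fixtures and independent oracles for the test suite.

# Independent pitch oracle: whole-signal autocorrelation peak in a search
# band, no parabolic interpolation, separate code path from the package's
# frame-based estimator.
acfPitchOracle <- function(w, fmin = 60, fmax = 800) {
  x <- samples(w) - mean(samples(w))
  rate <- sampleRate(w)
  lag_max <- floor(rate / fmin)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lags <- seq.int(max(2L, floor(rate / fmax)), lag_max)
  rate / lags[which.max(ac[lags + 1L])]
}

# Brute-force window enumeration: every window of every template, no
# greedy assignment, call reuse allowed. Returns a data.frame of all
# matching windows (start, k, template_id).
bruteForceWindows <- function(calls, templates, threshold_hz = 100,
                              max_gap_s = 1) {
  out <- list()
  for (tpl in templates) {
    k <- templateSize(tpl)
    sgn <- ifelse(directionPattern(tpl) == "up", 1, -1)
    for (i in seq_len(max(nrow(calls) - k + 1L, 0L))) {
      idx <- i:(i + k - 1L)
      if (any(diff(calls$onset_s[idx]) > max_gap_s)) next
      d <- diff(calls$mean_f0[idx])
      if (all(is.finite(d)) && all(abs(d) >= threshold_hz) &&
          all(sign(d) == sgn))
        out[[length(out) + 1L]] <- data.frame(start = i, k = k,
                                              template_id = tpl@template_id)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start = integer(), k = integer(), template_id = character())
}

# Per-pair loop Gower oracle (numeric columns and ordered factors).
gowerLoopOracle <- function(x, ranges = NULL) {
  num <- as.data.frame(lapply(x, function(col) {
    if (is.ordered(col)) as.numeric(rank(col, na.last = "keep")) else
      as.numeric(col)
  }))
  rng <- vapply(names(num), function(v) {
    if (!is.null(ranges) && v %in% names(ranges)) ranges[[v]]
    else diff(range(num[[v]], na.rm = TRUE))
  }, 0)
  n <- nrow(num)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0; m <- 0
    for (v in seq_along(num)) {
      if (rng[v] <= 0) next
      xi <- num[i, v]; xj <- num[j, v]
      if (is.na(xi) || is.na(xj)) next
      s <- s + abs(xi - xj) / rng[v]; m <- m + 1
    }
    d[i, j] <- if (m > 0) s / m else NA
  }
  d
}

# Random call list for match-rule property tests.
randomCallList <- function(n, seed) {
  set.seed(seed)
  data.frame(
    onset_s = cumsum(runif(n, 0.3, 1.4)),
    mean_f0 = runif(n, 100, 450)
  )
}

allTemplates <- function() list(stimulusTemplate("a"), stimulusTemplate("b"),
                                stimulusTemplate("ab"))

# Small low-rate parameter set used for synthetic-colony audio checks.
lowRateParams <- function() spectroParams(fft = 256)
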