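rate96 <- 96000
tone <- function(f, rate = rate96, dur = 1, amp = 0.5)
  waveform(amp * sin(2 * pi * f * (0:(dur * rate - 1)) / rate), rate)
rmsOf <- function(w) sqrt(mean(samples(w)^2))

test_that("high-pass filter meets its stopband/passband contract", {
  lo <- highpassFilter(tone(50), 100)
  expect_lt(20 * log10(rmsOf(lo) / rmsOf(tone(50))), -24)
  hi <- highpassFilter(tone(1000), 100)
  expect_lt(abs(20 * log10(rmsOf(hi) / rmsOf(tone(1000)))), 1)
  expect_error(highpassFilter(tone(1000), 60000), "cutoff")
  # zero phase: the energy envelope of a gated tone is not delayed
  w <- synthesizeCall(300, 0.2, rate = 16000)
  padded <- waveform(c(numeric(1600), samples(w) * 0.9, numeric(1600)), 16000)
  flt <- highpassFilter(padded, 100)
  on_raw <- which(abs(samples(padded)) > 0.1)[1]
  on_flt <- which(abs(samples(flt)) > 0.1)[1]
  expect_lt(abs(on_raw - on_flt) / 16000, 0.001)
})

test_that("spectrogram bin width is exactly rate/fft and peaks land correctly", {
  for (fft in c(256L, 1024L, 2048L)) {
    p <- spectroParams(fft = fft)
    s <- spectrogramMatrix(tone(468.75, dur = 0.2), p)
    expect_identical(s$bin_width, rate96 / fft)
  }
  s <- spectrogramMatrix(tone(468.75, dur = 0.2), spectroParams(fft = 2048L))
  expect_equal(s$bin_width, 46.875)
  # 468.75 Hz = 10 x 46.875: argmax lands on bin index 10 (0-based)
  expect_equal(unname(which.max(rowMeans(s$mag))) - 1L, 10L)
  set.seed(1)
  noise <- waveform(runif(8192, -0.5, 0.5), rate96)
  sn <- spectrogramMatrix(noise, spectroParams(fft = 2048L))
  expect_true(all(is.finite(sn$mag)))
  expect_error(spectrogramMatrix(tone(100, dur = 0.01), spectroParams()),
               "shorter")
})

test_that("segmentation applies the 5 ms gap rule", {
  p <- spectroParams(fft = 512)
  r <- 16000
  # short 2 ms fades so the acoustic gap equals the annotated gap
  call1 <- synthesizeCall(200, 0.3, rate = r, edge_s = 0.002)
  # two calls separated by 50 ms -> two segments
  two <- waveform(c(numeric(r %/% 2), samples(call1), numeric(0.05 * r),
                    samples(call1), numeric(r %/% 2)), r)
  seg2 <- segmentCalls(highpassFilter(two, 100), p)
  expect_equal(nrow(seg2), 2L)
  # a 3 ms internal break stays one call
  one <- waveform(c(numeric(r %/% 2), samples(call1), numeric(0.003 * r),
                    samples(call1), numeric(r %/% 2)), r)
  seg1 <- segmentCalls(highpassFilter(one, 100), p)
  expect_equal(nrow(seg1), 1L)
  expect_gt(seg1$duration_s, 0.55)
  # silence -> no segments, not an error
  expect_equal(nrow(segmentCalls(waveform(numeric(r), r), p)), 0L)
  # sub-minimum blips are discarded
  blip <- synthesizeCall(200, 0.02, rate = r, edge_s = 0.005)
  wb <- waveform(c(numeric(r %/% 2), samples(call1), numeric(r %/% 4),
                   samples(blip) * 0.9, numeric(r %/% 2)), r)
  expect_equal(nrow(segmentCalls(highpassFilter(wb, 100), p)), 1L)
})

test_that("per-frame features recover F0 and peak frequency", {
  p <- spectroParams(fft = 512)
  w <- synthesizeCall(176, 0.7, rate = 16000)
  f <- extractFeatures(w, p)
  expect_lt(abs(f$mean_f0 - 176), 5)
  expect_true(f$min_f0 <= f$mean_f0 && f$mean_f0 <= f$max_f0)
  # contour step rule: floor(duration / 5 ms) +/- 1 entries
  expect_lte(abs(f$n_frames - floor(0.7 / 0.005)), 1)
  # amplify the 2nd harmonic: peak moves there, F0 stays put
  r <- 16000; n <- 0.7 * r; t <- (0:(n - 1)) / r
  x <- 0.3 * sin(2 * pi * 176 * t) + 0.6 * sin(2 * pi * 352 * t)
  env <- pupcall:::.hammingWin(n)
  w2 <- waveform(x * env / max(abs(x)), r)
  f2 <- extractFeatures(w2, p)
  expect_lt(abs(f2$mean_peak - 2 * f2$mean_f0), r / 512)
  expect_lt(abs(f2$mean_f0 - 176), 5)
  expect_error(extractFeatures(w, p, 0, 0.004), "short")
})

test_that("segmentation and features round-trip generator calls", {
  cfg <- devConfig(calls_per_day = 100, rate = 16000, seed = 421L)
  col <- simulateColony(pupRoster(1L, 0L, 0L), cfg, days = 0L)
  w <- renderSession(col, "P01", 0L)
  feats <- measureSession(w, spectroParams(fft = 512))
  truth <- col$annotations[order(col$annotations$onset_s), ]
  expect_equal(nrow(feats), nrow(truth))        # call count exact
  expect_lt(max(abs(feats$onset_s - truth$onset_s)), 0.005)
  expect_lt(max(abs(feats$mean_f0 - truth$f0_hz)), 5)
})

test_that("extracted mean F0 scales linearly under pitch shifting", {
  p <- spectroParams(fft = 1024)
  w <- synthesizeCall(180, 0.5, rate = 48000)
  base <- extractFeatures(w, p)$mean_f0
  for (ratio in c(0.75, 1.25, 1.5)) {
    sh <- pitchShift(w, ratio, win = 1024L)
    got <- extractFeatures(sh, p)$mean_f0
    expect_lt(abs(got - ratio * base), 48000 / 1024,
              label = sprintf("ratio %g", ratio))
  }
})

test_that("formants are recovered from known resonators", {
  r <- 16000
  set.seed(7)
  x <- rnorm(r)  # 1 s excitation
  for (f in c(800, 1500)) {
    bw <- 120
    rr <- exp(-pi * bw / r)
    a <- c(1, -2 * rr * cos(2 * pi * f / r), rr^2)
    x <- stats::filter(x, filter = -a[-1], method = "recursive")
  }
  x <- as.numeric(x); x <- x / max(abs(x))
  fm <- estimateFormants(waveform(x, r), lpc_order = 12L)
  expect_gte(length(fm), 2L)
  expect_lt(abs(fm[1] - 800) / 800, 0.10)
  expect_lt(abs(fm[2] - 1500) / 1500, 0.10)
  # robustness: white noise returns without error
  set.seed(8)
  expect_silent(estimateFormants(waveform(runif(4000, -1, 1), r), 12L))
  expect_error(estimateFormants(waveform(x, r), 0), "lpc_order")
})
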