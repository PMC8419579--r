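test_that("configuration and roster validation reject bad inputs", {
  expect_error(devConfig(p_match_control_start = 1.2), "probabilities")
  expect_error(devConfig(feedVsVariedRatio = 0), "ratios")
  expect_error(devConfig(calls_per_day = 0), "calls_per_day")
  pups <- pupRoster()
  bad <- pups; bad$stimulus_id[1] <- "a"          # control with a stimulus
  expect_error(simulateColony(bad, devConfig()), "control pups")
  bad2 <- pups; bad2$wean_day <- 25L
  expect_error(simulateColony(bad2, devConfig()), "wean_day")
  expect_error(simulateColony(pups[0, ], devConfig()), "at least one pup")
})

test_that("the match trajectory reproduces the configured anchor fractions", {
  cfg <- devConfig()
  ctl <- matchTrajectory("control", cfg)
  expect_equal(mean(ctl(0:4)), 0.20, tolerance = 1e-8)
  expect_equal(mean(ctl(15:19)), 0.02, tolerance = 1e-8)
  vr <- matchTrajectory("varied", cfg)
  expect_equal(mean(vr(15:19)), 0.35, tolerance = 1e-8)
  expect_equal(mean(vr(15:19)) / mean(vr(0:4)), 2.0, tolerance = 1e-8)
  fd <- matchTrajectory("feeding", cfg)
  expect_equal(mean(vr(15:19)) / mean(fd(15:19)), 1.5, tolerance = 1e-8)
  # monotone: control declines, playback rises
  expect_true(all(diff(ctl(0:19)) < 0))
  expect_true(all(diff(vr(0:19)) > 0))
})

test_that("identical seeds give identical colonies and waveforms", {
  pups <- pupRoster(1L, 1L, 1L)
  cfg <- devConfig(calls_per_day = 12, rate = 8000, seed = 55L)
  c1 <- simulateColony(pups, cfg, days = c(0L, 10L))
  c2 <- simulateColony(pups, cfg, days = c(0L, 10L))
  expect_identical(c1$annotations, c2$annotations)
  w1 <- renderSession(c1, "P02", 10L)
  w2 <- renderSession(c2, "P02", 10L)
  expect_identical(samples(w1), samples(w2))
  c3 <- simulateColony(pups, devConfig(calls_per_day = 12, rate = 8000,
                                       seed = 56L), days = c(0L, 10L))
  expect_false(identical(c1$annotations, c3$annotations))
})

test_that("planted fractions converge to the configured bin anchors", {
  # 5000 calls per evaluated bin, tolerance 3 binomial SDs
  cfg <- devConfig(calls_per_day = 250, seed = 77L)
  col <- simulateColony(pupRoster(4L, 0L, 0L), cfg, days = c(0:4, 15:19))
  ann <- col$annotations
  early <- ann$is_planted_match[ann$age_days <= 4]
  late <- ann$is_planted_match[ann$age_days >= 15]
  expect_gte(length(early), 5000)
  expect_lt(abs(mean(early) - 0.20), 3 * sqrt(0.2 * 0.8 / length(early)))
  expect_lt(abs(mean(late) - 0.02), 3 * sqrt(0.02 * 0.98 / length(late)))
  colv <- simulateColony(pupRoster(0L, 0L, 4L),
                         devConfig(calls_per_day = 252, seed = 78L),
                         days = 15:19)
  lv <- colv$annotations$is_planted_match
  expect_gte(length(lv), 5000)
  expect_lt(abs(mean(lv) - 0.35), 3 * sqrt(0.35 * 0.65 / length(lv)))
})

test_that("the classifier detects planted matches and rejects non-matches", {
  cfg <- devConfig(calls_per_day = 60, rate = 8000, seed = 91L)
  pups <- pupRoster(1L, 1L, 1L)
  col <- simulateColony(pups, cfg, days = c(2L, 17L))
  feats <- analyzeColony(col, params = lowRateParams())
  mt <- buildMatchTable(feats, pups)
  ann <- col$annotations
  key_a <- paste(ann$pup_id, ann$age_days, round(ann$onset_s, 3))
  key_m <- paste(mt$pup_id, mt$age_days, round(mt$onset_s, 3))
  det <- mt$is_match[match(key_a, key_m)]
  # onsets measured from audio differ by <5 ms; match on nearest onset
  if (anyNA(det)) {
    det <- vapply(seq_len(nrow(ann)), function(i) {
      j <- which(mt$pup_id == ann$pup_id[i] & mt$age_days == ann$age_days[i])
      jj <- j[which.min(abs(mt$onset_s[j] - ann$onset_s[i]))]
      mt$is_match[jj]
    }, TRUE)
  }
  expect_gte(mean(det[ann$is_planted_match]), 0.95)
  expect_lt(mean(det[!ann$is_planted_match]), 0.10)
})

test_that("colony sessions and annotations round-trip through disk", {
  cfg <- devConfig(calls_per_day = 8, rate = 8000, seed = 12L)
  col <- simulateColony(pupRoster(1L, 0L, 0L), cfg, days = 0:1)
  dir <- withr::local_tempdir()
  csv <- writeColony(col, dir)
  expect_true(file.exists(file.path(dir, "P01_day00.wav")))
  expect_true(file.exists(file.path(dir, "P01_day01.wav")))
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(col$annotations))
  expect_equal(back$f0_hz, col$annotations$f0_hz, tolerance = 1e-12)
  w <- readWav(file.path(dir, "P01_day00.wav"))
  expect_equal(sampleRate(w), 8000)
})
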