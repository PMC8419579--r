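test_that("null data recover odds ratios of 1 with nominal coverage", {
  null_coefs <- matchModelDefaults() * 0
  terms_cover <- vapply(1:50, function(i) {
    d <- simulateMatchTable(null_coefs, n_per_condition = 3L,
                            calls_per_pup = 150L, ranef_sd = 0.3,
                            seed = 7000L + i)
    fit <- suppressWarnings(suppressMessages(fitMatchGlmm(d)))
    ct <- fit$coefficients
    ct$ci_lower <= 1 & ct$ci_upper >= 1
  }, logical(6))
  # per-term coverage of the true OR = 1 at the 95% Wald interval
  cover <- rowMeans(terms_cover)
  expect_true(all(cover >= 0.88))
  expect_true(all(cover <= 1.00))
})

test_that("the matching model recovers its generating coefficients", {
  set.seed(2024)
  d <- simulateMatchTable(seed = 171L)
  fit <- fitMatchGlmm(d)
  ct <- fit$coefficients
  av <- ct[ct$term == "age_days:conditionvaried", ]
  expect_lt(abs(av$estimate - log(1.981)), 3 * av$se)
  # exponentiation consistency to machine precision
  expect_equal(ct$exp_estimate, exp(ct$estimate), tolerance = 1e-15)
})

test_that("degenerate match tables are rejected with diagnostics", {
  d <- simulateMatchTable(seed = 5L)
  expect_error(fitMatchGlmm(d[d$pup_id == "S01", ]), "single pup")
  d1 <- d; d1$is_match <- TRUE
  expect_error(fitMatchGlmm(d1), "outcome classes")
  # outcome fully determined by condition: complete separation is flagged
  d2 <- d; d2$is_match <- d2$condition == "varied"
  expect_error(suppressWarnings(suppressMessages(fitMatchGlmm(d2))),
               "separation")
})

test_that("refitting identical data reproduces estimates", {
  d <- simulateMatchTable(seed = 88L)
  f1 <- fitMatchGlmm(d)
  f2 <- fitMatchGlmm(d)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-10)
})

test_that("a flat similarity table yields age slopes of ~1 after exponentiation", {
  set.seed(61)
  d <- data.frame(pup_id = rep(sprintf("P%02d", 1:6), each = 4),
                  sex = rep(c("F", "M"), each = 12),
                  condition = rep(c("control", "feeding", "varied"), each = 8),
                  age_bin = rep(0:3, 6),
                  r = 0.7 + rnorm(24, 0, 1e-4))
  fit <- suppressWarnings(suppressMessages(fitSimilarityLmm(d)))
  ct <- fit$coefficients
  for (term in c("age_bin", "age_bin:conditionfeeding",
                 "age_bin:conditionvaried"))
    expect_equal(ct$exp_estimate[ct$term == term], 1, tolerance = 1e-2)
  expect_error(fitSimilarityLmm(d[1:2, ]), "3 observations")
  dc <- d; dc$r <- 0.5
  expect_error(fitSimilarityLmm(dc), "constant")
})

test_that("the similarity model detects the varied-condition age trend", {
  res <- vapply(1:50, function(i) {
    cfg <- devConfig(calls_per_day = 120, rate = 8000, seed = 600L + i)
    pups <- pupRoster(4L, 4L, 4L)
    col <- simulateColony(pups, cfg)
    feats <- analyzeColony(col, from_annotations = TRUE)
    mt <- buildMatchTable(feats, pups)
    sim <- suppressMessages(sessionSimilarity(feats, mt, pups, n_perm = 0))
    fit <- suppressWarnings(suppressMessages(fitSimilarityLmm(sim)))
    ct <- fit$coefficients
    av <- ct[ct$term == "age_bin:conditionvaried", ]
    af <- ct[ct$term == "age_bin:conditionfeeding", ]
    c(av$ci_lower > 1, af$ci_lower <= 1 & af$ci_upper >= 1)
  }, logical(2))
  expect_gte(mean(res[1, ]), 0.80)   # age x varied credibly above 1
  expect_gte(mean(res[2, ]), 0.80)   # age x feeding interval covers 1
})

test_that("fit summaries have the report shape and round-trip via CSV", {
  d <- simulateMatchTable(seed = 9L)
  glmm <- fitMatchGlmm(d)
  set.seed(10)
  sm <- data.frame(pup_id = rep(sprintf("P%02d", 1:6), each = 4),
                   sex = rep(c("F", "M"), 12),
                   condition = rep(c("control", "feeding", "varied"), each = 8),
                   age_bin = rep(0:3, 6),
                   r = runif(24, 0.4, 0.9))
  lmm <- suppressWarnings(fitSimilarityLmm(sm))
  dir <- withr::local_tempdir()
  rep_tables <- summarizeFits(glmm, lmm, dir = dir)
  expect_equal(nrow(rep_tables$match_model), 6L)
  expect_equal(nrow(rep_tables$similarity_model), 7L)  # + sex term
  back <- utils::read.csv(file.path(dir, "match_model.csv"))
  expect_equal(back$estimate, rep_tables$match_model$estimate,
               tolerance = 1e-12)
  expect_warning(summarizeFits(glmm, NULL), "partial")
  expect_error(summarizeFits(), "nothing")
})
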