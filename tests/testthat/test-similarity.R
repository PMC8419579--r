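test_that("Gower dissimilarity matches its definition", {
  expect_equal(suppressWarnings(gowerMatrix(data.frame(a = c(1, 1))))[1, 2],
               0)  # identical objects

  d <- gowerMatrix(data.frame(a = c(0, 5)), ranges = c(a = 10))
  expect_equal(d[1, 2], 0.5)
  expect_warning(gowerMatrix(data.frame(a = c(0, 5), b = c(2, 2))),
                 "zero-range")
  expect_error(gowerMatrix(data.frame(a = c(NA_real_, NA_real_))), "missing")
  expect_error(gowerMatrix(data.frame(a = 1)), "two objects")
})

test_that("Gower matrix equals the pairwise-loop oracle and cluster::daisy", {
  set.seed(21)
  x <- data.frame(a = rnorm(6), b = runif(6, 0, 10), c = rnorm(6, 100, 20),
                  o = factor(sample(c("l", "m", "h"), 6, TRUE),
                             levels = c("l", "m", "h"), ordered = TRUE))
  x$a[2] <- NA   # pairwise-available handling
  G <- gowerMatrix(x)
  expect_lt(max(abs(G - gowerLoopOracle(x))), 1e-12)
  # numeric-only table agrees with the daisy implementation exactly
  xn <- x[c("a", "b", "c")]
  expect_lt(max(abs(gowerMatrix(xn) -
                    as.matrix(cluster::daisy(xn, metric = "gower")))), 1e-12)
})

test_that("Gower matrices are bounded, symmetric and zero-diagonal", {
  set.seed(22)
  for (i in 1:100) {
    n <- sample(3:8, 1)
    x <- data.frame(a = rnorm(n), b = runif(n) * sample(1:100, 1),
                    o = factor(sample(letters[1:3], n, TRUE),
                               levels = letters[1:3], ordered = TRUE))
    G <- suppressWarnings(gowerMatrix(x))
    expect_true(all(G >= 0 & G <= 1 + 1e-12))
    expect_equal(G, t(G))
    expect_true(all(diag(G) == 0))
  }
})

test_that("Mantel r is 1 for self- and affine-related matrices", {
  set.seed(31)
  A <- as.matrix(dist(matrix(rnorm(30), 10)))
  expect_equal(mantelR(mantelTest(A, A, n_perm = 0)), 1)
  expect_equal(mantelR(mantelTest(A, 2 * A + 0.3 * (1 - diag(10)),
                                  n_perm = 0)), 1)
  B <- as.matrix(dist(matrix(rnorm(30), 10)))
  expect_error(mantelTest(A, B[1:5, 1:5]), "equal size")
  expect_error(mantelTest(A, matrix(1, 10, 10) - diag(10)), "constant")
  expect_error(mantelTest(A[1:2, 1:2], A[1:2, 1:2]), "3 objects")
})

test_that("Mantel statistic agrees with vegan and is seed-reproducible", {
  set.seed(32)
  A <- as.matrix(dist(matrix(rnorm(36), 12)))
  B <- as.matrix(dist(matrix(rnorm(36), 12)))
  m1 <- mantelTest(A, B, n_perm = 199, seed = 5)
  expect_equal(mantelR(m1),
               unname(vegan::mantel(as.dist(A), as.dist(B),
                                    permutations = 0)$statistic))
  m2 <- mantelTest(A, B, n_perm = 199, seed = 5)
  expect_identical(mantelP(m1), mantelP(m2))
  # r does not depend on the permutation count
  expect_equal(mantelR(mantelTest(A, B, n_perm = 19, seed = 1)), mantelR(m1))
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(33)
  hits <- replicate(400, {
    A <- as.matrix(dist(matrix(rnorm(30), 10)))
    B <- as.matrix(dist(matrix(rnorm(30), 10)))
    mantelP(mantelTest(A, B, n_perm = 199)) <= 0.05
  })
  # ~5% +/- 2 SE of a binomial(400, 0.05)
  expect_lt(abs(mean(hits) - 0.05), 2 * sqrt(0.05 * 0.95 / 400) + 1e-9)
})

test_that("responses copying the template exactly give r = 1", {
  pups <- data.frame(pup_id = "P01", sex = "F", condition = "varied",
                     stimulus_id = "a", birth_day = 0L, wean_day = 19L)
  tplf <- pupcall:::.templateFeatureTable(stimulusTemplate("a"))
  n_win <- 3L
  feats <- do.call(rbind, lapply(seq_len(n_win), function(w) {
    f <- tplf
    f$pup_id <- "P01"; f$age_days <- 2L
    f$onset_s <- (w - 1) * 3 + c(0, 0.75)
    f$offset_s <- f$onset_s + 0.7
    f
  }))
  matches <- data.frame(pup_id = "P01", age_days = 2L,
                        onset_s = feats$onset_s, is_match = TRUE,
                        matched_template = "a",
                        window_position = rep(1:2, n_win),
                        window_id = rep(seq_len(n_win), each = 2))
  sim <- sessionSimilarity(feats, matches, pups, n_perm = 99, seed = 2)
  expect_equal(nrow(sim), 1L)
  expect_equal(sim$r, 1)
})

test_that("position-independent response features give r near zero", {
  set.seed(44)
  pups <- data.frame(pup_id = "P01", sex = "F", condition = "varied",
                     stimulus_id = "a", birth_day = 0L, wean_day = 19L)
  rs <- replicate(20, {
    n_win <- 10L
    f0 <- runif(2 * n_win, 100, 400)
    feats <- data.frame(pup_id = "P01", age_days = 2L,
                        onset_s = as.vector(t(cbind((0:(n_win - 1)) * 3,
                                                    (0:(n_win - 1)) * 3 + 0.75))),
                        duration_s = runif(2 * n_win, 0.4, 0.8),
                        mean_f0 = f0, min_f0 = f0 - 5, max_f0 = f0 + 5,
                        mean_peak = f0)
    feats$offset_s <- feats$onset_s + feats$duration_s
    matches <- data.frame(pup_id = "P01", age_days = 2L,
                          onset_s = feats$onset_s, is_match = TRUE,
                          matched_template = "a",
                          window_position = rep(1:2, n_win),
                          window_id = rep(seq_len(n_win), each = 2))
    # acoustic variables only: the position variable is aligned by
    # construction and would contribute its own structural correlation
    sessionSimilarity(feats, matches, pups, n_perm = 0,
                      vars = c("duration_s", "mean_f0", "min_f0", "max_f0",
                               "mean_peak"))$r
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("varied pups gain ~25% similarity from first to last age bin", {
  cfg <- devConfig(calls_per_day = 60, rate = 8000, seed = 11L)
  pups <- pupRoster(0L, 0L, 8L)
  col <- simulateColony(pups, cfg)
  feats <- analyzeColony(col, from_annotations = TRUE)
  mt <- buildMatchTable(feats, pups)
  sim <- suppressMessages(sessionSimilarity(feats, mt, pups, n_perm = 0))
  agg <- stats::aggregate(r ~ age_bin, sim, mean)
  gain <- agg$r[agg$age_bin == 3] / agg$r[agg$age_bin == 0] - 1
  expect_gt(gain, 0.13)
  expect_lt(gain, 0.37)
})

test_that("bins with too few matched calls are skipped with a message", {
  pups <- data.frame(pup_id = "P01", sex = "F", condition = "feeding",
                     stimulus_id = "a", birth_day = 0L, wean_day = 19L)
  feats <- data.frame(pup_id = "P01", age_days = 1L, onset_s = c(0, 0.75),
                      offset_s = c(0.7, 1.45), duration_s = 0.7,
                      mean_f0 = c(150, 280), min_f0 = c(150, 280),
                      max_f0 = c(150, 280), mean_peak = c(150, 280))
  matches <- data.frame(pup_id = "P01", age_days = 1L, onset_s = c(0, 0.75),
                        is_match = TRUE, matched_template = "a",
                        window_position = 1:2, window_id = 1L)
  expect_message(out <- sessionSimilarity(feats, matches, pups, n_perm = 0),
                 "skipping")
  expect_equal(nrow(out), 0L)
})
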