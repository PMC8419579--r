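#' Gower dissimilarity matrix for mixed-type call features
#'
#' Gower's coefficient: the dissimilarity between two calls is the mean
#' over available variables of the range-normalized absolute difference
#' `|x_i - x_j| / range`. Ordered factors are converted to ranks and then
#' treated as numeric. Missing entries are handled pairwise (a variable
#' missing in either object is skipped for that pair); zero-range variables
#' are dropped with a warning.
#'
#' @param x Data.frame of per-object features (numeric and/or ordered
#'   factors), >= 2 rows.
#' @param ranges Optional named numeric vector of normalization spans per
#'   variable; computed from the pooled table when omitted.
#' @return A symmetric matrix with zero diagonal and entries in \[0, 1\],
#'   with row/column names from `x`.
#' @examples
#' gowerMatrix(data.frame(a = c(0, 5), b = c(1, 1)), ranges = c(a = 10, b = 2))
#' @export
gowerMatrix <- function(x, ranges = NULL) {
  stopifnot(is.data.frame(x))
  n <- nrow(x)
  if (n < 2L) stop("need at least two objects")
  num <- as.data.frame(lapply(x, function(col) {
    if (is.ordered(col)) as.numeric(rank(col, na.last = "keep"))
    else if (is.numeric(col)) as.numeric(col)
    else stop("variables must be numeric or ordered factors")
  }))
  keep <- character()
  for (v in names(num)) {
    col <- num[[v]]
    if (all(is.na(col))) stop("variable '", v, "' is entirely missing")
    r <- if (!is.null(ranges) && v %in% names(ranges)) ranges[[v]]
         else diff(range(col, na.rm = TRUE))
    # a span at rounding-noise level is a constant variable in disguise
    if (is.finite(r) && r <= 1e-9 * max(1, abs(col), na.rm = TRUE)) r <- 0
    if (!is.finite(r) || r <= 0) {
      warning("dropping zero-range variable '", v, "'")
      next
    }
    num[[v]] <- col / r
    keep <- c(keep, v)
  }
  if (!length(keep)) {
    # every variable constant: all objects coincide
    d <- matrix(0, n, n)
    dimnames(d) <- list(rownames(x), rownames(x))
    return(d)
  }
  num <- num[keep]
  d <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  for (v in keep) {
    col <- num[[v]]
    dv <- abs(outer(col, col, `-`))
    ok <- !is.na(dv)
    dv[!ok] <- 0
    d <- d + dv
    cnt <- cnt + ok
  }
  if (any(cnt == 0 & upper.tri(cnt)))
    stop("some object pairs share no observed variables")
  d <- d / pmax(cnt, 1L)
  d <- pmin(d, 1)
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Mantel association between two dissimilarity matrices
#'
#' Pearson correlation over the n(n-1)/2 upper-triangle entries, with a
#' one-sided permutation test: rows and columns of the second matrix are
#' permuted jointly and `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`.
#' The test is one-sided (greater) because the association of interest -
#' response structure following template structure - is directional.
#'
#' @param mA,mB Square symmetric dissimilarity matrices over the same
#'   objects in the same order, n >= 3.
#' @param n_perm Number of permutations (0 skips the test; `p` is `NA`).
#' @param seed Optional seed for the permutation draw.
#' @return A [MantelResult-class].
#' @export
mantelTest <- function(mA, mB, n_perm = 9999L, seed = NULL) {
  stopifnot(is.matrix(mA), is.matrix(mB))
  n <- nrow(mA)
  if (n < 3L) stop("need at least 3 objects")
  if (!all(dim(mA) == n) || !all(dim(mB) == n))
    stop("matrices must be square and of equal size")
  ut <- upper.tri(mA)
  a <- mA[ut]; b <- mB[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant dissimilarity matrix: Mantel r undefined")
  r <- stats::cor(a, b)
  n_perm <- as.integer(n_perm)
  p <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    ge <- 0L
    for (i in seq_len(n_perm)) {
      pp <- sample.int(n)
      rp <- stats::cor(a, mB[pp, pp][ut])
      if (rp >= r) ge <- ge + 1L
    }
    p <- (1 + ge) / (1 + n_perm)
  }
  new("MantelResult", r = r, p_value = p, n_perm = n_perm, n_objects = n)
}

#' Mantel test result
#'
#' @slot r Pearson correlation of the upper-triangle dissimilarities.
#' @slot p_value One-sided permutation tail probability (`NA` if no
#'   permutations were run).
#' @slot n_perm Number of permutations.
#' @slot n_objects Number of objects.
#' @export
setClass("MantelResult",
  representation(r = "numeric", p_value = "numeric", n_perm = "integer",
                 n_objects = "integer"),
  validity = function(object) {
    msg <- character()
    if (!is.na(object@r) && (object@r < -1 - 1e-12 || object@r > 1 + 1e-12))
      msg <- c(msg, "r must lie in [-1, 1]")
    if (!is.na(object@p_value) &&
        (object@p_value <= 0 || object@p_value > 1))
      msg <- c(msg, "p must lie in (0, 1]")
    if (object@n_objects < 3L) msg <- c(msg, "need >= 3 objects")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "MantelResult", function(object) {
  cat(sprintf("Mantel r = %.4f (n = %d objects, %d permutations, p = %s)\n",
              object@r, object@n_objects, object@n_perm,
              format.pval(object@p_value)))
})

#' @describeIn mantelTest Extract the Mantel correlation.
#' @param x A `MantelResult`.
#' @export
mantelR <- function(x) {
  stopifnot(is(x, "MantelResult"))
  x@r
}

#' @describeIn mantelTest Extract the permutation p-value.
#' @export
mantelP <- function(x) {
  stopifnot(is(x, "MantelResult"))
  x@p_value
}

# Feature vectors for the template's calls, on the same variables as the
# response calls.
.templateFeatureTable <- function(template) {
  k <- templateSize(template)
  f <- peakFreqs(template)
  data.frame(duration_s = rep(template@call_duration_s, k),
             mean_f0 = f, min_f0 = f, max_f0 = f, mean_peak = f,
             inter_call_s = c(NA_real_, rep(template@inter_call_s, k - 1L)),
             position = seq_len(k))
}

.similarityVars <- c("duration_s", "mean_f0", "min_f0", "max_f0",
                     "mean_peak", "inter_call_s", "position")

#' Per pup and age bin template similarity (Mantel r)
#'
#' For each pup and age bin, takes the calls that participated in matched
#' windows and quantifies how closely their multi-parameter structure
#' follows the template: matrix A is the Gower dissimilarity among the
#' response calls' feature vectors (duration, mean/min/max F0, mean peak
#' frequency, inter-call interval, sequence position), matrix B the Gower
#' dissimilarity among the template calls each response call is
#' position-aligned to, and the Mantel r between them is the similarity
#' score. Normalization spans are computed over the pooled response +
#' template table so the two matrices are commensurate.
#'
#' @param features Per-call feature table (see [analyzeColony()]).
#' @param matches Call-level match table from [buildMatchTable()].
#' @param pups Pup roster.
#' @param bin_edges Age bin lower edges; default the developmental bins
#'   0-4, 5-9, 10-14, 15-19 days.
#' @param n_perm Permutations per Mantel test.
#' @param seed Seed for the permutation draws.
#' @param min_calls Minimum matched calls per pup-bin (bins with fewer are
#'   skipped, with a message).
#' @param vars Similarity variables to use; defaults to the full set
#'   (duration, mean/min/max F0, mean peak, inter-call interval, position).
#'   Swap in a different list to mirror another parameter choice.
#' @return A data.frame: `pup_id`, `sex`, `condition`, `age_bin` (0-3),
#'   `r`, `p`, `n_objects`, `n_perm`.
#' @export
sessionSimilarity <- function(features, matches, pups,
                              bin_edges = c(0, 5, 10, 15), n_perm = 999L,
                              seed = NULL, min_calls = 3L,
                              vars = c("duration_s", "mean_f0", "min_f0",
                                       "max_f0", "mean_peak", "inter_call_s",
                                       "position")) {
  .validatePups(pups)
  if (!is.null(seed)) set.seed(seed)
  key_f <- paste(features$pup_id, features$age_days, round(features$onset_s, 6))
  key_m <- paste(matches$pup_id, matches$age_days, round(matches$onset_s, 6))
  mi <- match(key_f, key_m)
  features$is_match <- matches$is_match[mi]
  features$matched_template <- matches$matched_template[mi]
  features$window_position <- matches$window_position[mi]
  features$window_id <- matches$window_id[mi]
  matched <- features[!is.na(features$is_match) & features$is_match, ]
  if (!nrow(matched))
    return(data.frame(pup_id = character(), sex = character(),
                      condition = character(), age_bin = integer(),
                      r = numeric(), p = numeric(), n_objects = integer(),
                      n_perm = integer(), stringsAsFactors = FALSE))
  matched$age_bin <- findInterval(matched$age_days, bin_edges) - 1L
  tpl_feats <- lapply(list(a = stimulusTemplate("a"), b = stimulusTemplate("b"),
                           ab = stimulusTemplate("ab")), .templateFeatureTable)
  out <- list()
  for (pid in unique(matched$pup_id)) {
    pup <- pups[pups$pup_id == pid, ]
    for (bin in sort(unique(matched$age_bin[matched$pup_id == pid]))) {
      mm <- matched[matched$pup_id == pid & matched$age_bin == bin, ]
      if (nrow(mm) < min_calls) {
        message(sprintf("skipping %s bin %d: only %d matched calls",
                        pid, bin, nrow(mm)))
        next
      }
      # inter-call interval within the matched window
      mm <- mm[order(mm$age_days, mm$onset_s), ]
      mm$inter_call_s <- NA_real_
      later <- which(mm$window_position > 1L)
      prev <- later - 1L
      ok <- prev >= 1L & mm$window_id[pmax(prev, 1L)] == mm$window_id[later] &
        mm$age_days[pmax(prev, 1L)] == mm$age_days[later]
      mm$inter_call_s[later[ok]] <- mm$onset_s[later[ok]] - mm$offset_s[prev[ok]]
      mm$position <- mm$window_position
      resp <- mm[, vars, drop = FALSE]
      tmat <- do.call(rbind, lapply(seq_len(nrow(mm)), function(i)
        tpl_feats[[mm$matched_template[i]]][mm$window_position[i], ]))
      tmat <- tmat[, vars, drop = FALSE]
      pooled <- rbind(resp, tmat)
      ranges <- vapply(vars, function(v)
        diff(range(pooled[[v]], na.rm = TRUE)), 0)
      scale <- vapply(vars, function(v)
        max(1, abs(pooled[[v]]), na.rm = TRUE), 0)
      ranges[!is.finite(ranges) | ranges <= 1e-9 * scale] <- NA
      ranges <- ranges[!is.na(ranges)]
      mr <- tryCatch({
        A <- suppressWarnings(gowerMatrix(resp, ranges))
        B <- suppressWarnings(gowerMatrix(tmat, ranges))
        mantelTest(A, B, n_perm = n_perm)
      }, error = function(e) {
        message(sprintf("skipping %s bin %d: %s", pid, bin, conditionMessage(e)))
        NULL
      })
      if (is.null(mr)) next
      out[[length(out) + 1L]] <- data.frame(
        pup_id = pid, sex = pup$sex, condition = pup$condition,
        age_bin = bin, r = mantelR(mr), p = mantelP(mr),
        n_objects = mr@n_objects, n_perm = mr@n_perm,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(pup_id = character(), sex = character(),
                      condition = character(), age_bin = integer(),
                      r = numeric(), p = numeric(), n_objects = integer(),
                      n_perm = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
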