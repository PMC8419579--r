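#' Experiment run configuration
#'
#' Assembles the configuration of a full synthetic-colony experiment run.
#' Can be round-tripped through YAML with [readRunConfig()].
#'
#' @param pups Pup roster (see [pupRoster()]).
#' @param dev A [devConfig()].
#' @param threshold_hz Match rule F0 step threshold (Hz).
#' @param max_gap_s Match rule window gap (s).
#' @param n_perm Mantel permutations.
#' @param bin_edges Age bin lower edges.
#' @param days Optional day subset to simulate.
#' @param from_annotations Skip audio rendering and measure from ground
#'   truth (see [analyzeColony()]).
#' @param params Optional [spectroParams()]; chosen from the audio rate
#'   when `NULL`.
#' @return A list of class `"runConfig"`.
#' @export
runConfig <- function(pups = pupRoster(), dev = devConfig(),
                      threshold_hz = 100, max_gap_s = 1, n_perm = 999L,
                      bin_edges = c(0, 5, 10, 15), days = NULL,
                      from_annotations = FALSE, params = NULL) {
  if (threshold_hz <= 0 || max_gap_s <= 0) stop("thresholds must be positive")
  .validatePups(pups)
  structure(list(pups = pups, dev = dev, threshold_hz = threshold_hz,
                 max_gap_s = max_gap_s, n_perm = as.integer(n_perm),
                 bin_edges = bin_edges, days = days,
                 from_annotations = from_annotations, params = params),
            class = "runConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; top-level keys mirror the arguments of
#'   [runConfig()] (`pups` as a list of records, `dev` as a mapping).
#' @return A `"runConfig"`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pups <- if (!is.null(y$pups))
    do.call(rbind, lapply(y$pups, function(p) as.data.frame(p))) else pupRoster()
  dev <- if (!is.null(y$dev)) do.call(devConfig, y$dev) else devConfig()
  runConfig(pups = pups, dev = dev,
            threshold_hz = y$threshold_hz %||% 100,
            max_gap_s = y$max_gap_s %||% 1,
            n_perm = y$n_perm %||% 999L,
            bin_edges = y$bin_edges %||% c(0, 5, 10, 15),
            days = y$days,
            from_annotations = isTRUE(y$from_annotations))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' End-to-end run: simulate the colony, measure every session (segment +
#' features), build the call-level match table, fit the binomial matching
#' model, score per pup x age-bin Mantel similarity, fit the Gaussian
#' similarity model, and write every intermediate table plus a
#' machine-readable summary to `out_dir`. Identical configuration and seed
#' reproduce identical outputs.
#'
#' @param config A [runConfig()].
#' @param out_dir Output directory (created; intermediate CSVs, model
#'   tables and `summary.json` are written there).
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with `features`, `matches`, `mantel`, `glmm`,
#'   `lmm`, `summary`.
#' @export
runExperiment <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    say("stage %-12s %6.1f s", name, as.numeric(Sys.time() - t0, units = "secs"))
    r
  }

  colony <- stage("simulate", simulateColony(config$pups, config$dev,
                                             days = config$days))
  utils::write.csv(colony$annotations, file.path(out_dir, "annotations.csv"),
                   row.names = FALSE)
  features <- stage("features", analyzeColony(colony, params = config$params,
                                              from_annotations = config$from_annotations))
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  matches <- stage("match", buildMatchTable(features, config$pups,
                                            threshold_hz = config$threshold_hz,
                                            max_gap_s = config$max_gap_s))
  utils::write.csv(matches, file.path(out_dir, "matches.csv"),
                   row.names = FALSE)
  glmm <- stage("glmm", tryCatch(fitMatchGlmm(matches), error = function(e) {
    say("matching model not fitted: %s", conditionMessage(e)); NULL
  }))
  mantel <- stage("similarity", suppressMessages(
    sessionSimilarity(features, matches, config$pups,
                      bin_edges = config$bin_edges, n_perm = config$n_perm,
                      seed = config$dev$seed + 1L)))
  utils::write.csv(mantel, file.path(out_dir, "mantel.csv"),
                   row.names = FALSE)
  lmm <- stage("lmm", tryCatch(fitSimilarityLmm(mantel), error = function(e) {
    say("similarity model not fitted: %s", conditionMessage(e)); NULL
  }))
  if (!is.null(glmm) || !is.null(lmm))
    summarizeFits(glmm, lmm, dir = out_dir)

  bins <- config$bin_edges
  matches$age_bin <- findInterval(matches$age_days, bins) - 1L
  mf <- stats::aggregate(is_match ~ condition + age_bin, data = matches,
                         FUN = mean)
  mr <- if (nrow(mantel))
    stats::aggregate(r ~ condition + age_bin, data = mantel, FUN = mean)
  else NULL
  summary <- list(
    seed = config$dev$seed,
    n_pups = nrow(config$pups),
    n_calls = nrow(features),
    match_fraction = mf,
    mean_mantel_r = mr
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list(features = features, matches = matches, mantel = mantel,
                 glmm = glmm, lmm = lmm, summary = summary))
}
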