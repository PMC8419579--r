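#' Find template matches in a time-ordered call sequence
#'
#' Implements the template-match rule: a window of k consecutive calls
#' (k = template size, 2 or 3) counts as a match when every successive
#' onset-to-onset gap is at most `max_gap_s` (1 s) and every successive
#' difference in average fundamental frequency is at least `threshold_hz`
#' (100 Hz) in magnitude, with the sign following the template's
#' direction pattern. Candidate windows are scanned greedily left to right
#' (earliest window wins) and a call belongs to at most one matched window.
#'
#' @param calls Data.frame of per-call features sorted by `onset_s`; needs
#'   columns `onset_s` and `mean_f0`.
#' @param template A [StimulusTemplate-class] (k in \{2, 3\}).
#' @param threshold_hz Minimum absolute F0 step (Hz).
#' @param max_gap_s Maximum successive onset-to-onset gap (s).
#' @return A data.frame of matched windows: `window_id`, `start_index`,
#'   `template_id`, and one row per window; `calls` indices are in
#'   `attr(, "call_windows")`, a list of integer vectors. Zero rows when
#'   nothing matches.
#' @export
findMatches <- function(calls, template, threshold_hz = 100, max_gap_s = 1) {
  stopifnot(is(template, "StimulusTemplate"))
  k <- templateSize(template)
  if (!k %in% c(2L, 3L)) stop("template must have 2 or 3 calls")
  .findMatchesMulti(calls, list(template), threshold_hz, max_gap_s)
}

# Greedy multi-template scan. Templates are tried at each start index in
# the order given (document: a, b, ab for the control rule); the first
# matching, non-overlapping window claims its calls.
.findMatchesMulti <- function(calls, templates, threshold_hz = 100,
                              max_gap_s = 1) {
  need <- c("onset_s", "mean_f0")
  if (!all(need %in% names(calls)))
    stop("calls must have columns onset_s and mean_f0")
  n <- nrow(calls)
  if (n && is.unsorted(calls$onset_s)) stop("calls must be sorted by onset_s")
  onset <- calls$onset_s
  f0 <- calls$mean_f0
  ks <- vapply(templates, templateSize, 0L)
  sgn <- lapply(templates, function(t)
    ifelse(directionPattern(t) == "up", 1, -1))
  ids <- vapply(templates, function(t) t@template_id, "")
  used <- rep(FALSE, n)
  w_start <- integer(); w_tpl <- character()
  win_calls <- list()
  wid <- 0L
  for (i in seq_len(max(n - 1L, 0L))) {
    if (used[i]) next
    for (t in seq_along(templates)) {
      k <- ks[t]
      j <- i + k - 1L
      if (j > n) next
      idx <- i:j
      if (any(used[idx])) next
      if (any(diff(onset[idx]) > max_gap_s)) next
      d <- diff(f0[idx])
      if (any(!is.finite(d))) next
      if (all(abs(d) >= threshold_hz) && all(sign(d) == sgn[[t]])) {
        wid <- wid + 1L
        w_start[wid] <- i
        w_tpl[wid] <- ids[t]
        win_calls[[wid]] <- idx
        used[idx] <- TRUE
        break
      }
    }
  }
  out <- data.frame(window_id = seq_len(wid), start_index = w_start,
                    template_id = w_tpl, stringsAsFactors = FALSE)
  attr(out, "call_windows") <- win_calls
  out
}

#' Chance matches of control pups against any template
#'
#' Control pups received no playbacks; a window counts as a chance match
#' if it matches any of the three stimulus templates. Templates are tried
#' in the order a, b, ab at each window start (deterministic earliest-window
#' greedy rule, as in [findMatches()]).
#'
#' @inheritParams findMatches
#' @param templates List of the candidate [StimulusTemplate-class] objects;
#'   defaults to a, b and ab.
#' @return As [findMatches()], with `template_id` naming the matched
#'   template.
#' @export
controlChanceMatches <- function(calls,
                                 templates = list(stimulusTemplate("a"),
                                                  stimulusTemplate("b"),
                                                  stimulusTemplate("ab")),
                                 threshold_hz = 100, max_gap_s = 1) {
  .findMatchesMulti(calls, templates, threshold_hz, max_gap_s)
}

#' Build the call-level match table
#'
#' Applies the match rule per pup-day session: playback pups are tested
#' against their own assigned template, control pups against all three
#' templates. Every analysed call becomes one row; all k calls of a
#' matched window are flagged as matches, since the statistical unit of
#' the downstream model is whether a call was part of a match.
#'
#' @param features Per-call feature table from [analyzeColony()] or
#'   [measureSession()] (needs `pup_id`, `age_days`, `onset_s`, `mean_f0`).
#' @param pups Pup roster (see [pupRoster()]).
#' @param threshold_hz,max_gap_s Match rule parameters.
#' @return A data.frame with one row per call: `pup_id`, `age_days`,
#'   `condition`, `call_index`, `onset_s`, `is_match`, `window_id` (NA for
#'   unmatched calls), `matched_template`, `window_position`.
#' @export
buildMatchTable <- function(features, pups, threshold_hz = 100,
                            max_gap_s = 1) {
  .validatePups(pups)
  if (!nrow(features))
    return(data.frame(pup_id = character(), age_days = integer(),
                      condition = character(), call_index = integer(),
                      onset_s = numeric(), is_match = logical(),
                      window_id = integer(), matched_template = character(),
                      window_position = integer(), stringsAsFactors = FALSE))
  if (!all(features$pup_id %in% pups$pup_id))
    stop("features contain pups missing from the roster: ",
         paste(setdiff(unique(features$pup_id), pups$pup_id), collapse = ", "))
  out <- list()
  sess_idx <- split(seq_len(nrow(features)),
                    list(factor(features$pup_id), factor(features$age_days)),
                    drop = TRUE)
  for (sel in sess_idx) {
    sess <- features[sel, ]
    sess <- sess[order(sess$onset_s), ]
    pup <- pups[pups$pup_id == sess$pup_id[1L], ]
    wins <- if (pup$condition == "control")
      controlChanceMatches(sess, threshold_hz = threshold_hz,
                           max_gap_s = max_gap_s)
    else
      findMatches(sess, stimulusTemplate(pup$stimulus_id),
                  threshold_hz = threshold_hz, max_gap_s = max_gap_s)
    cw <- attr(wins, "call_windows")
    m <- nrow(sess)
    is_match <- rep(FALSE, m)
    window_id <- rep(NA_integer_, m)
    tpl <- rep(NA_character_, m)
    pos <- rep(NA_integer_, m)
    for (w in seq_len(nrow(wins))) {
      idx <- cw[[w]]
      is_match[idx] <- TRUE
      window_id[idx] <- wins$window_id[w]
      tpl[idx] <- wins$template_id[w]
      pos[idx] <- seq_along(idx)
    }
    out[[length(out) + 1L]] <- data.frame(
      pup_id = sess$pup_id, age_days = sess$age_days,
      condition = pup$condition, call_index = seq_len(m),
      onset_s = sess$onset_s, is_match = is_match, window_id = window_id,
      matched_template = tpl, window_position = pos,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
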