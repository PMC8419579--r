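#' Developmental configuration of the synthetic colony
#'
#' Parameters of the simulated developmental trajectories. Probabilities
#' refer to the fraction of calls that form template matches, evaluated as
#' the mean over the first (0-4 days) and last (15-19 days) age bins of the
#' developmental window; between the two anchor bins the per-day match
#' probability is linear on the log-odds scale (the simplest monotone
#' family consistent with smooth developmental trends).
#'
#' Defaults encode the experiment's developmental conditions: control chance matches
#' decline from 20% to 2%, varied-condition pups reach 35% at weaning,
#' varied pups match 1.5 times as often as feeding pups, and playback pups
#' double their match rate from birth to weaning. Varied-condition planted
#' matches also become more stereotyped with age so that multi-parameter
#' similarity to the template rises by `similarity_gain_varied` (25%) from
#' the first to the last age bin.
#'
#' @param p_match_control_start Control chance-match fraction, ages 0-4.
#' @param p_match_control_end Control chance-match fraction, ages 15-19.
#' @param p_match_playback_end_varied Varied-condition match fraction at
#'   weaning (ages 15-19).
#' @param feedVsVariedRatio Varied/feeding ratio of match fractions.
#' @param birthToWeanRatio Weaning/birth ratio of playback-pup match
#'   fractions.
#' @param similarity_gain_varied Fractional rise in template similarity
#'   (Mantel r) from the first to the last age bin, varied condition.
#' @param calls_per_day Mean calls emitted per pup per day.
#' @param f0_base,f0_sd Mean and SD (Hz) of the truncated-normal F0
#'   distribution of ordinary (non-match) calls.
#' @param rate Audio sampling rate in Hz for rendered sessions.
#' @param n_harmonics Harmonics per synthesized call.
#' @param seed Master seed for colony simulation.
#' @return A list of class `"devConfig"`.
#' @export
devConfig <- function(p_match_control_start = 0.20,
                      p_match_control_end = 0.02,
                      p_match_playback_end_varied = 0.35,
                      feedVsVariedRatio = 1.5,
                      birthToWeanRatio = 2.0,
                      similarity_gain_varied = 0.25,
                      calls_per_day = 25,
                      f0_base = 250, f0_sd = 40,
                      rate = 96000, n_harmonics = 3L,
                      seed = 20211025L) {
  p <- c(p_match_control_start, p_match_control_end,
         p_match_playback_end_varied)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (feedVsVariedRatio <= 0 || birthToWeanRatio <= 0)
    stop("ratios must be positive")
  if (calls_per_day <= 0) stop("calls_per_day must be positive")
  if (f0_base <= 0 || f0_sd < 0) stop("invalid f0 distribution")
  structure(list(
    p_match_control_start = p_match_control_start,
    p_match_control_end = p_match_control_end,
    p_match_playback_end_varied = p_match_playback_end_varied,
    feedVsVariedRatio = feedVsVariedRatio,
    birthToWeanRatio = birthToWeanRatio,
    similarity_gain_varied = similarity_gain_varied,
    calls_per_day = calls_per_day,
    f0_base = f0_base, f0_sd = f0_sd,
    rate = rate, n_harmonics = as.integer(n_harmonics),
    seed = as.integer(seed)
  ), class = "devConfig")
}

# Solve (a, b) of logit p(d) = a + b * d such that the mean match
# probability over `early` days equals p_early and over `late` days equals
# p_late. Bins (rather than single days) are the anchors because binned
# fractions are the quantities the analysis works with.
.trajectoryCoef <- function(p_early, p_late, early = 0:4, late = 15:19) {
  stopifnot(p_early > 0, p_early < 1, p_late > 0, p_late < 1)
  if (p_early == p_late) return(c(a = stats::qlogis(p_early), b = 0))
  a_for_b <- function(b) {
    f <- function(a) mean(stats::plogis(a + b * early)) - p_early
    stats::uniroot(f, c(-30, 30), tol = 1e-12)$root
  }
  g <- function(b) {
    a <- a_for_b(b)
    mean(stats::plogis(a + b * late)) - p_late
  }
  b <- stats::uniroot(g, c(-2, 2), tol = 1e-12)$root
  c(a = a_for_b(b), b = b)
}

#' Per-day match-probability trajectory
#'
#' Returns the simulated probability that a call emitted at a given age is
#' part of a planted template match, for one playback condition.
#'
#' @param condition `"control"`, `"feeding"` or `"varied"`.
#' @param config A [devConfig()].
#' @return A function `f(age_days) -> probability`.
#' @examples
#' f <- matchTrajectory("control", devConfig())
#' mean(f(0:4))   # ~0.20
#' @export
matchTrajectory <- function(condition = c("control", "feeding", "varied"),
                            config = devConfig()) {
  condition <- match.arg(condition)
  pv_end <- config$p_match_playback_end_varied
  ends <- switch(condition,
    control = c(config$p_match_control_start, config$p_match_control_end),
    varied = c(pv_end / config$birthToWeanRatio, pv_end),
    feeding = c(pv_end / config$feedVsVariedRatio / config$birthToWeanRatio,
                pv_end / config$feedVsVariedRatio))
  cf <- .trajectoryCoef(ends[1], ends[2])
  function(age_days) stats::plogis(cf["a"] + cf["b"] * age_days)
}

#' Pup roster of the experimental design
#'
#' Builds the pup metadata table: by default the design's layout of four
#' control pups plus four feeding/varied pairs assigned stimuli a, a, b
#' and ab.
#'
#' @param n_control,n_feeding,n_varied Pups per condition.
#' @param stimuli Stimulus assignment recycled across the playback pairs.
#' @return A data.frame with columns `pup_id`, `sex`, `condition`,
#'   `stimulus_id`, `birth_day`, `wean_day`.
#' @export
pupRoster <- function(n_control = 4L, n_feeding = 4L, n_varied = 4L,
                      stimuli = c("a", "a", "b", "ab")) {
  n <- n_control + n_feeding + n_varied
  if (n < 1L) stop("at least one pup is required")
  cond <- c(rep("control", n_control), rep("feeding", n_feeding),
            rep("varied", n_varied))
  stim <- c(rep("none", n_control),
            rep_len(stimuli, n_feeding), rep_len(stimuli, n_varied))
  data.frame(
    pup_id = sprintf("P%02d", seq_len(n)),
    sex = rep_len(c("F", "M"), n),
    condition = cond,
    stimulus_id = stim,
    birth_day = 0L,
    wean_day = 19L,
    stringsAsFactors = FALSE
  )
}

.validatePups <- function(pups) {
  need <- c("pup_id", "sex", "condition", "stimulus_id", "birth_day", "wean_day")
  if (!all(need %in% names(pups)))
    stop("pup table must have columns: ", paste(need, collapse = ", "))
  if (nrow(pups) == 0L) stop("at least one pup is required")
  if (anyDuplicated(pups$pup_id)) stop("duplicated pup_id")
  if (!all(pups$condition %in% c("control", "feeding", "varied")))
    stop("condition must be control, feeding or varied")
  ctl <- pups$condition == "control"
  if (any(pups$stimulus_id[ctl] != "none") ||
      any(pups$stimulus_id[!ctl] == "none"))
    stop("control pups must have stimulus 'none' and playback pups a/b/ab")
  if (!all(pups$stimulus_id %in% c("none", "a", "b", "ab")))
    stop("stimulus_id must be one of none, a, b, ab")
  if (any(pups$birth_day < 0 | pups$birth_day >= pups$wean_day |
          pups$wean_day > 19))
    stop("need 0 <= birth_day < wean_day <= 19")
  invisible(pups)
}

# Truncated-normal draws by inverse-CDF (exact, no rejection loop).
.rtrunc <- function(n, mean, sd, lo, hi) {
  if (all(sd <= 0)) return(pmin(hi, pmax(lo, rep_len(mean, n))))
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# Draw all call groups of one pup-day at once. Matched groups realize the
# template's direction pattern with >=115 Hz steps from a low anchor, so
# every call stays inside the pup F0 band whatever the pattern; the spread
# of anchor and step shrinks with tau, making matches more stereotyped as
# similarity to the template rises. Non-match groups draw F0 from the
# truncated normal around f0_base with successive steps well under 100 Hz.
# Returns a k*g-row data.frame in group-major order.
.drawDay <- function(is_match, template_id, k, config, tau) {
  g <- length(is_match)
  f0 <- matrix(NA_real_, k, g)
  im <- which(is_match)
  if (length(im)) {
    lo <- .rtrunc(length(im), 200, 130 * tau, 100, 340)
    s1 <- .rtrunc(length(im), 220, 130 * tau, 115, 400)
    f0[1L, im] <- lo
    f0[2L, im] <- lo + s1
    if (k == 3L) {
      s2 <- .rtrunc(length(im), 220, 130 * tau, 115,
                    pmin(400, lo + s1 - 100))
      f0[3L, im] <- lo + s1 - s2
    }
    down <- template_id[im] == "b"     # two-call down step: high then low
    if (any(down)) f0[1:2, im[down]] <- f0[2:1, im[down]]
  }
  un <- which(!is_match)
  if (length(un)) {
    f0[1L, un] <- .rtrunc(length(un), config$f0_base, config$f0_sd, 120, 420)
    for (j in 2:k) {
      step <- .rtrunc(length(un), 0, 30, -70, 70)
      f0[j, un] <- pmin(450, pmax(100, f0[j - 1L, un] + step))
    }
  }
  dur <- matrix(.rtrunc(k * g, 0.62, 0.12 * tau, 0.42, 0.78), k, g)
  gap <- matrix(.rtrunc(k * g, 0.13, 0.06 * tau, 0.05, 0.21), k, g)
  rel <- apply(rbind(0, (dur + gap)[-k, , drop = FALSE]), 2, cumsum)
  data.frame(position = rep(seq_len(k), g),
             f0_hz = as.vector(f0),
             duration_s = as.vector(dur),
             rel_onset_s = as.vector(rel))
}

#' Simulate a synthetic breeding colony
#'
#' Generates per-pup, per-day call annotations with the configured
#' developmental structure. Calls are emitted in groups (sequences) of the
#' size of the pup's template (pairs for controls); with the
#' age-and-condition-dependent probability from [matchTrajectory()] a group
#' is planted as a template match, i.e. its calls step in fundamental
#' frequency by at least 100 Hz (after estimation noise) following the
#' template's direction pattern. Non-match groups draw F0 from a truncated
#' normal around `f0_base` with successive steps well under 100 Hz.
#' Control-pup planted chance matches pick one of templates a/b at random.
#' For varied-condition pups the spread of planted-match features shrinks
#' with age, so similarity to the template rises across development.
#'
#' Identical `(pups, config, days)` and seed give byte-identical output.
#' Audio is not rendered here; see [renderSession()] and [analyzeColony()].
#'
#' @param pups Pup roster data.frame, see [pupRoster()].
#' @param config A [devConfig()].
#' @param days Integer vector of colony days to simulate; default every day
#'   from birth to weaning per pup.
#' @return An object of class `"pupColony"`: list with `annotations` (one
#'   row per call: `pup_id`, `age_days`, `onset_s`, `offset_s`,
#'   `sequence_id`, `is_planted_match`, plus ground-truth `f0_hz`,
#'   `duration_s`, `position`, `planted_template`), `pups`, `config`,
#'   `days`.
#' @export
simulateColony <- function(pups = pupRoster(), config = devConfig(),
                           days = NULL) {
  .validatePups(pups)
  stopifnot(inherits(config, "devConfig"))
  set.seed(config$seed)
  traj <- list(control = matchTrajectory("control", config),
               feeding = matchTrajectory("feeding", config),
               varied = matchTrajectory("varied", config))
  rows <- vector("list", 0L)
  for (p in seq_len(nrow(pups))) {
    pup <- pups[p, ]
    pup_days <- if (is.null(days)) pup$birth_day:pup$wean_day else
      days[days >= pup$birth_day & days <= pup$wean_day]
    for (d in pup_days) {
      age <- d - pup$birth_day
      span <- pup$wean_day - pup$birth_day
      k <- if (pup$stimulus_id == "ab") 3L else 2L
      n_groups <- max(1L, round(config$calls_per_day / k))
      pm <- traj[[pup$condition]](age)
      lambda <- if (pup$condition == "varied") config$similarity_gain_varied else 0
      tau <- 1 - 1.45 * lambda / 0.25 * (age / max(span, 1L))
      tau <- max(tau, 0.05)
      is_match <- stats::runif(n_groups) < pm
      tpl <- if (pup$condition == "control") {
        ifelse(is_match, sample(c("a", "b"), n_groups, replace = TRUE),
               "none")
      } else rep(pup$stimulus_id, n_groups)
      day <- .drawDay(is_match, ifelse(tpl == "none", "a", tpl), k,
                      config, tau)
      # place groups along the session: successive groups separated by
      # enough silence that match windows never span a group boundary
      last_rel <- day$rel_onset_s[seq_len(n_groups) * k] +
        day$duration_s[seq_len(n_groups) * k]
      starts <- 0.5 + cumsum(c(0, (last_rel + stats::runif(n_groups, 0.8, 1.2))[-n_groups]))
      day$onset_s <- starts[rep(seq_len(n_groups), each = k)] + day$rel_onset_s
      day$rel_onset_s <- NULL
      day$offset_s <- day$onset_s + day$duration_s
      day$sequence_id <- rep(seq_len(n_groups), each = k)
      day$is_planted_match <- rep(is_match, each = k)
      day$planted_template <- rep(tpl, each = k)
      day$pup_id <- pup$pup_id
      day$age_days <- age
      rows[[length(rows) + 1L]] <- day
    }
  }
  ann <- do.call(rbind, rows)
  ann <- ann[, c("pup_id", "age_days", "onset_s", "offset_s", "sequence_id",
                 "is_planted_match", "f0_hz", "duration_s", "position",
                 "planted_template")]
  rownames(ann) <- NULL
  structure(list(annotations = ann, pups = pups, config = config,
                 days = days), class = "pupColony")
}

#' @export
print.pupColony <- function(x, ...) {
  cat(sprintf("Synthetic pup colony: %d pups, %d calls, %.1f%% planted matches\n",
              nrow(x$pups), nrow(x$annotations),
              100 * mean(x$annotations$is_planted_match)))
  invisible(x)
}

#' Render one pup-day session to audio
#'
#' Synthesizes the annotated calls of one pup-day at their annotated onsets
#' (deterministic given the annotation table; all randomness lives in
#' [simulateColony()]).
#'
#' @param colony A `"pupColony"` from [simulateColony()].
#' @param pup_id,age_days Session selector.
#' @return A [Waveform-class], or `NULL` if the session has no calls.
#' @export
renderSession <- function(colony, pup_id, age_days) {
  stopifnot(inherits(colony, "pupColony"))
  ann <- colony$annotations
  ann <- ann[ann$pup_id == pup_id & ann$age_days == age_days, ]
  if (!nrow(ann)) return(NULL)
  rate <- colony$config$rate
  n <- round((max(ann$offset_s) + 0.5) * rate)
  x <- numeric(n)
  for (i in seq_len(nrow(ann))) {
    w <- synthesizeCall(ann$f0_hz[i], ann$duration_s[i],
                        n_harmonics = colony$config$n_harmonics,
                        rate = rate, peak = 0.9)
    j <- round(ann$onset_s[i] * rate)
    x[j + seq_along(w@samples)] <- x[j + seq_along(w@samples)] + w@samples
  }
  waveform(pmin(1, pmax(-1, x)), rate)
}

#' Write colony sessions and annotations to disk
#'
#' Renders every pup-day session to a mono PCM WAV file and writes the
#' annotation table as CSV.
#'
#' @param colony A `"pupColony"`.
#' @param dir Output directory (created if needed).
#' @param bits WAV bit depth (16 or 24).
#' @return Invisibly, the annotation CSV path.
#' @export
writeColony <- function(colony, dir, bits = 16L) {
  stopifnot(inherits(colony, "pupColony"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- colony$annotations
  for (key in unique(paste(ann$pup_id, ann$age_days))) {
    parts <- strsplit(key, " ")[[1L]]
    w <- renderSession(colony, parts[1L], as.integer(parts[2L]))
    if (!is.null(w))
      writeWav(w, file.path(dir, sprintf("%s_day%02d.wav", parts[1L],
                                         as.integer(parts[2L]))), bits)
  }
  csv <- file.path(dir, "annotations.csv")
  utils::write.csv(ann, csv, row.names = FALSE)
  invisible(csv)
}

#' Run the measurement pipeline over a synthetic colony
#'
#' For every pup-day session: render audio, high-pass filter, segment with
#' the gap rule, and measure per-call features. With
#' `from_annotations = TRUE` the audio stage is skipped and measured
#' features are taken from the generator's ground truth (useful for large
#' statistical simulations where audio rendering adds nothing but
#' measurement noise).
#'
#' @param colony A `"pupColony"`.
#' @param params A [spectroParams()] (choose `fft` to keep the analysis
#'   window near 20-30 ms at `config$rate`).
#' @param from_annotations Skip audio and use ground-truth features.
#' @return A data.frame with one row per detected call: `pup_id`,
#'   `age_days`, `condition`, `onset_s`, `offset_s`, `duration_s`,
#'   `mean_f0`, `min_f0`, `max_f0`, `mean_peak`, `n_frames`, `n_voiced`.
#' @export
analyzeColony <- function(colony, params = NULL, from_annotations = FALSE) {
  stopifnot(inherits(colony, "pupColony"))
  ann <- colony$annotations
  cond <- stats::setNames(colony$pups$condition, colony$pups$pup_id)
  if (from_annotations) {
    out <- data.frame(
      pup_id = ann$pup_id, age_days = ann$age_days,
      condition = unname(cond[ann$pup_id]),
      onset_s = ann$onset_s, offset_s = ann$offset_s,
      duration_s = ann$duration_s,
      mean_f0 = ann$f0_hz, min_f0 = ann$f0_hz, max_f0 = ann$f0_hz,
      mean_peak = ann$f0_hz,
      n_frames = as.integer(round(ann$duration_s / 0.005)),
      n_voiced = as.integer(round(ann$duration_s / 0.005)),
      stringsAsFactors = FALSE)
    return(out[order(out$pup_id, out$age_days, out$onset_s), ])
  }
  if (is.null(params)) {
    fft <- 2^round(log2(0.021 * colony$config$rate))
    params <- spectroParams(fft = as.integer(fft))
  }
  res <- list()
  for (key in unique(paste(ann$pup_id, ann$age_days))) {
    parts <- strsplit(key, " ")[[1L]]
    pid <- parts[1L]; day <- as.integer(parts[2L])
    w <- renderSession(colony, pid, day)
    if (is.null(w)) next
    feats <- measureSession(w, params)
    if (!nrow(feats)) next
    feats$pup_id <- pid
    feats$age_days <- day
    feats$condition <- unname(cond[pid])
    res[[length(res) + 1L]] <- feats
  }
  out <- do.call(rbind, res)
  out <- out[, c("pup_id", "age_days", "condition", "onset_s", "offset_s",
                 "duration_s", "mean_f0", "min_f0", "max_f0", "mean_peak",
                 "n_frames", "n_voiced")]
  out[order(out$pup_id, out$age_days, out$onset_s), ]
}
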