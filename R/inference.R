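# Wald summary of an lme4 fit: estimates on the link/response scale,
# exponentiated estimates, 95% CIs and normal-approximation p-values.
.waldTable <- function(fit) {
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    exp_estimate = exp(unname(est)),
    ci_lower = exp(unname(est - 1.959964 * se)),
    ci_upper = exp(unname(est + 1.959964 * se)),
    p_value = 2 * stats::pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE
  )
}

#' Fit the binomial mixed model of call matching
#'
#' Logistic mixed-effects regression of whether a call was a match, with
#' age in days (continuous) interacting with playback condition
#' (reference level control) as fixed effects and a random intercept per
#' pup to account for repeated sampling. Estimated by maximum likelihood
#' with the Laplace approximation (`lme4::glmer`). Estimates are
#' exponentiated to odds ratios with Wald 95% CIs.
#'
#' @param matches Call-level match table (see [buildMatchTable()] or
#'   [simulateMatchTable()]): needs `pup_id`, `age_days`, `condition`,
#'   `is_match`.
#' @return A list of class `"glmmFit"`: `coefficients` (data.frame with
#'   `term`, `estimate` (log-odds), `exp_estimate` (odds ratio),
#'   `ci_lower`, `ci_upper`, `p_value`), `ranef_var` (pup intercept
#'   variance), `n_obs`, `n_pups`, `model` (the `merMod`).
#' @export
fitMatchGlmm <- function(matches) {
  need <- c("pup_id", "age_days", "condition", "is_match")
  if (!all(need %in% names(matches)))
    stop("match table needs columns: ", paste(need, collapse = ", "))
  d <- matches
  d$condition <- factor(d$condition,
                        levels = intersect(c("control", "feeding", "varied"),
                                           unique(d$condition)))
  if (length(unique(d$pup_id)) < 2L)
    stop("random intercept inestimable with a single pup")
  tab <- table(d$pup_id, d$condition)
  if (any(colSums(tab > 0) < 2L))
    stop("need at least 2 pups per condition")
  if (length(unique(d$is_match)) < 2L)
    stop("both outcome classes must be present")
  d$is_match <- as.logical(d$is_match)
  fit <- lme4::glmer(is_match ~ age_days * condition + (1 | pup_id),
                     data = d, family = stats::binomial(),
                     control = lme4::glmerControl(calc.derivs = FALSE))
  ct <- .waldTable(fit)
  if (any(!is.finite(ct$se)) || any(ct$se > 50) || any(abs(ct$estimate) > 20))
    stop("apparent complete separation: |estimate| or SE diverged; ",
         "check that both outcomes occur in every condition-age range")
  structure(list(
    coefficients = ct,
    ranef_var = unname(lme4::VarCorr(fit)$pup_id[1, 1]),
    n_obs = nrow(d),
    n_pups = length(unique(d$pup_id)),
    model = fit
  ), class = "glmmFit")
}

#' @export
print.glmmFit <- function(x, ...) {
  cat(sprintf("Binomial GLMM of call matching: %d calls, %d pups, pup variance %.3f\n",
              x$n_obs, x$n_pups, x$ranef_var))
  print(x$coefficients[, c("term", "exp_estimate", "ci_lower", "ci_upper",
                           "p_value")], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Fit the linear mixed model of match quality (Mantel r)
#'
#' Gaussian mixed model of the per pup x age-bin Mantel similarity score,
#' with binned age (entered as ordered numeric 0-3), condition, sex and
#' the age x condition interaction as fixed effects and a random intercept
#' per pup. Fitted by REML. Estimates are exponentiated in the report for
#' parity with the matching model's odds-ratio presentation (documented
#' choice; the response is a correlation, not a log-odds).
#'
#' @param mantel_rows Data.frame from [sessionSimilarity()]: `pup_id`,
#'   `sex`, `condition`, `age_bin`, `r`.
#' @return A list of class `"lmmFit"` mirroring [fitMatchGlmm()]'s shape,
#'   plus `residual_var`.
#' @export
fitSimilarityLmm <- function(mantel_rows) {
  need <- c("pup_id", "sex", "condition", "age_bin", "r")
  if (!all(need %in% names(mantel_rows)))
    stop("need columns: ", paste(need, collapse = ", "))
  d <- mantel_rows
  if (nrow(d) < 3L) stop("need at least 3 observations")
  if (length(unique(d$pup_id)) < 2L) stop("need at least 2 pups")
  if (length(unique(d$age_bin)) < 2L) stop("need at least 2 age bins")
  if (stats::sd(d$r) == 0) stop("similarity scores are constant")
  d$condition <- factor(d$condition,
                        levels = intersect(c("control", "feeding", "varied"),
                                           unique(d$condition)))
  d$age_bin <- as.numeric(d$age_bin)
  d$sex <- factor(d$sex)
  form <- if (nlevels(d$sex) > 1L)
    r ~ age_bin * condition + sex + (1 | pup_id)
  else r ~ age_bin * condition + (1 | pup_id)
  fit <- lme4::lmer(form, data = d, REML = TRUE)
  structure(list(
    coefficients = .waldTable(fit),
    ranef_var = unname(lme4::VarCorr(fit)$pup_id[1, 1]),
    residual_var = stats::sigma(fit)^2,
    n_obs = nrow(d),
    n_pups = length(unique(d$pup_id)),
    model = fit
  ), class = "lmmFit")
}

#' @export
print.lmmFit <- function(x, ...) {
  cat(sprintf("Gaussian LMM of Mantel r: %d pup-bins, %d pups\n",
              x$n_obs, x$n_pups))
  print(x$coefficients[, c("term", "exp_estimate", "ci_lower", "ci_upper",
                           "p_value")], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Default generating coefficients for match-model simulations
#'
#' Odds ratios of the matching model used as generator defaults for
#' parameter-recovery simulations: intercept 1.116, age 1.031, feeding
#' 1.243, varied 1.651, age x feeding 1.544, age x varied 1.981.
#'
#' @return Named numeric vector of log-odds coefficients.
#' @export
matchModelDefaults <- function() {
  log(c(intercept = 1.116, age = 1.031, feeding = 1.243, varied = 1.651,
        age_feeding = 1.544, age_varied = 1.981))
}

#' Simulate a call-level match table from the logistic model
#'
#' Direct simulation from the binomial random-intercept model: each pup
#' gets a normal random intercept, each call an age drawn uniformly over
#' 0-19 days, and the match outcome is Bernoulli with log-odds
#' `intercept + age*b_age + condition + age x condition + pup effect`.
#' Used for parameter-recovery checks of [fitMatchGlmm()].
#'
#' @param coefs Named log-odds coefficients as from [matchModelDefaults()].
#' @param n_per_condition Pups per condition.
#' @param calls_per_pup Calls per pup.
#' @param ranef_sd SD of the pup random intercept (log-odds scale).
#' @param seed Optional seed.
#' @return A match-table data.frame (`pup_id`, `age_days`, `condition`,
#'   `is_match`).
#' @export
simulateMatchTable <- function(coefs = matchModelDefaults(),
                               n_per_condition = 4L, calls_per_pup = 430L,
                               ranef_sd = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conds <- c("control", "feeding", "varied")
  pups <- data.frame(
    pup_id = sprintf("S%02d", seq_len(3L * n_per_condition)),
    condition = rep(conds, each = n_per_condition),
    u = stats::rnorm(3L * n_per_condition, 0, ranef_sd),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(pups)), function(i) {
    age <- stats::runif(calls_per_pup, 0, 19)
    eta <- coefs[["intercept"]] + coefs[["age"]] * age + pups$u[i] +
      switch(pups$condition[i],
             control = 0,
             feeding = coefs[["feeding"]] + coefs[["age_feeding"]] * age,
             varied = coefs[["varied"]] + coefs[["age_varied"]] * age)
    data.frame(pup_id = pups$pup_id[i], age_days = age,
               condition = pups$condition[i],
               is_match = stats::runif(calls_per_pup) < stats::plogis(eta),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Report tables for the fitted models
#'
#' Formats one or both fitted models as report tables (variable,
#' exponentiated estimate, CI bounds, p), optionally writing CSVs.
#'
#' @param glmm A `"glmmFit"` or `NULL`.
#' @param lmm A `"lmmFit"` or `NULL`.
#' @param dir Optional output directory for `match_model.csv` /
#'   `similarity_model.csv`.
#' @return A named list of data.frames (`match_model`, `similarity_model`)
#'   with columns `variable`, `estimate`, `ci_2.5`, `ci_97.5`, `p`.
#' @export
summarizeFits <- function(glmm = NULL, lmm = NULL, dir = NULL) {
  if (is.null(glmm) && is.null(lmm)) stop("nothing to summarize")
  shape <- function(fit) {
    ct <- fit$coefficients
    data.frame(variable = ct$term, estimate = ct$exp_estimate,
               ci_2.5 = ct$ci_lower, ci_97.5 = ct$ci_upper, p = ct$p_value,
               stringsAsFactors = FALSE)
  }
  out <- list()
  if (!is.null(glmm)) out$match_model <- shape(glmm)
  if (!is.null(lmm)) out$similarity_model <- shape(lmm)
  if (length(out) == 1L)
    warning("only one model supplied; partial report")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      utils::write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  out
}
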