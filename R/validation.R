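# Robustness and validity machinery: bootstrap and repeated stratified
# k-fold re-estimation of the event sequence, longitudinal staging
# consistency, stage-outcome association, and end-to-end orchestration.

# Shared reduced-cost EBM refit used inside resampling loops.
refit_ebm <- function(cases, controls, events, seed,
                      n_init = 5, n_samples = 500, burn_in = 500) {
  fits <- fit_all_mixtures(cases, controls, events = events)
  L <- event_likelihood_matrix(fits, cases)
  fit <- fit_ebm(L, n_init = n_init, n_samples = n_samples,
                 burn_in = burn_in, seed = seed)
  list(fits = fits, ebm = fit)
}

#' Bootstrap re-estimation of the event sequence
#'
#' Re-estimates the full model (mixtures and sequence) on bootstrap samples
#' of the cases, drawn with replacement; the control set is kept fixed for
#' mixture fitting so the normal component stays anchored. The aggregated
#' matrix records, per event and position, the proportion of bootstrap
#' samples whose maximum-likelihood sequence places that event at that
#' position — a resampling analogue of the positional variance diagram that
#' gives a more liberal view of ordering uncertainty than MCMC.
#'
#' @param cases,controls Covariate-adjusted biomarker tables.
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param seed Integer master seed.
#' @param n_init,n_samples,burn_in Per-resample EBM fit controls (kept small:
#'   only the ML sequence of each resample is used).
#' @return An object of class `ebm_cv_report`: `sequences` (n_boot x Z),
#'   `positional_variance`, `method = "bootstrap"`, `n_resamples`.
#' @export
bootstrap_sequences <- function(cases, controls, n_boot = 100, seed = 1L,
                                n_init = 5, n_samples = 500, burn_in = 500) {
  if (n_boot < 1) stop("`n_boot` must be at least 1")
  events <- event_columns(cases)
  seqs <- matrix(NA_integer_, n_boot, length(events))
  kept <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(seed, 100L + b))
    idx <- sample.int(nrow(cases), nrow(cases), replace = TRUE)
    res <- tryCatch(
      refit_ebm(cases[idx, , drop = FALSE], controls, events,
                seed = derive_seed(seed, 200L + b),
                n_init = n_init, n_samples = n_samples, burn_in = burn_in),
      error = function(e) {
        message("bootstrap resample ", b, " skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) {
      seqs[b, ] <- res$ebm$ml_sequence
      kept[b] <- TRUE
    }
  }
  seqs <- seqs[kept, , drop = FALSE]
  structure(list(
    sequences = seqs,
    positional_variance = positional_variance(seqs, events),
    method = "bootstrap", n_resamples = nrow(seqs), events = events
  ), class = "ebm_cv_report")
}

# Stratified fold assignment: within each group, a random permutation is
# dealt round-robin into k folds, so fold case/control ratios match the
# cohort's within one subject.
stratified_folds <- function(group, k) {
  fold <- integer(length(group))
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) < k) stop("fold too small: group `", g,
                              "` has fewer rows than folds")
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the event sequence
#'
#' For each of `repeats` random partitions into `k` group-stratified folds,
#' the model (mixtures and sequence) is refit on the training fraction and
#' the held-out subjects are staged under the fold's sequence; held-out
#' performance is summarized as stage-threshold classification accuracy. The
#' default 10 repeats of 5 folds give 50 fold models, averaged into a single
#' positional-variance matrix; the modal fold sequence is reported alongside.
#'
#' @param cases,controls Covariate-adjusted biomarker tables.
#' @param k Folds per repeat (default 5).
#' @param repeats Number of random partitions (default 10).
#' @param seed Integer master seed.
#' @param threshold_stage Stage cut-off for held-out classification
#'   (default 2).
#' @param n_init,n_samples,burn_in Per-fold EBM fit controls.
#' @return An `ebm_cv_report` with `sequences` (one per fold model),
#'   `positional_variance` (average over folds), `modal_sequence`,
#'   `holdout_accuracy` per fold, `method = "repeated_stratified_kfold"`.
#' @export
repeated_stratified_kfold <- function(cases, controls, k = 5, repeats = 10,
                                      seed = 1L, threshold_stage = 2,
                                      n_init = 5, n_samples = 500,
                                      burn_in = 500) {
  if (k < 2) stop("`k` must be at least 2")
  events <- event_columns(cases)
  n_models <- k * repeats
  seqs <- matrix(NA_integer_, n_models, length(events))
  acc <- numeric(n_models)
  m <- 0L
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, 300L + r))
    fold_case <- stratified_folds(rep("case", nrow(cases)), k)
    fold_ctrl <- stratified_folds(rep("control", nrow(controls)), k)
    for (f in seq_len(k)) {
      m <- m + 1L
      tr_cases <- cases[fold_case != f, , drop = FALSE]
      tr_ctrl <- controls[fold_ctrl != f, , drop = FALSE]
      te <- rbind(cases[fold_case == f, , drop = FALSE],
                  controls[fold_ctrl == f, , drop = FALSE])
      res <- refit_ebm(tr_cases, tr_ctrl, events,
                       seed = derive_seed(seed, 400L + m),
                       n_init = n_init, n_samples = n_samples,
                       burn_in = burn_in)
      seqs[m, ] <- res$ebm$ml_sequence
      L_te <- event_likelihood_matrix(res$fits, te)
      st <- stage_cohort(L_te, res$ebm$ml_sequence)
      acc[m] <- classify_by_stage(st, threshold_stage)$accuracy
    }
  }
  key <- apply(seqs, 1, paste, collapse = ",")
  modal <- as.integer(strsplit(names(which.max(table(key))), ",")[[1]])
  structure(list(
    sequences = seqs,
    positional_variance = positional_variance(seqs, events),
    modal_sequence = modal, holdout_accuracy = acc,
    method = "repeated_stratified_kfold", n_resamples = n_models,
    k = k, repeats = repeats, events = events
  ), class = "ebm_cv_report")
}

#' Longitudinal consistency of staging
#'
#' A valid staging system should not move subjects to earlier stages over
#' time in a progressive disease. Matches baseline and follow-up staging on
#' `subject_id` and reports the fraction of subjects whose follow-up stage is
#' at or beyond their baseline stage, and the mean stage change.
#'
#' @param baseline,followup `ebm_staging` data frames (both staged under the
#'   baseline-fitted model).
#' @param cases_only Restrict to case rows (default TRUE).
#' @return List with `n_pairs`, `fraction_non_decreasing`,
#'   `mean_stage_change`, and a per-subject `pairs` data frame.
#' @export
longitudinal_consistency <- function(baseline, followup, cases_only = TRUE) {
  stopifnot(inherits(baseline, "ebm_staging"), inherits(followup, "ebm_staging"))
  b <- as.data.frame(baseline)
  f <- as.data.frame(followup)
  if (cases_only) {
    b <- b[b$group == "case", ]
    f <- f[f$group == "case", ]
  }
  m <- merge(b[, c("subject_id", "stage")], f[, c("subject_id", "stage")],
             by = "subject_id", suffixes = c("_baseline", "_followup"))
  if (nrow(m) == 0) stop("no matched subject pairs between visits")
  change <- m$stage_followup - m$stage_baseline
  list(n_pairs = nrow(m),
       fraction_non_decreasing = mean(change >= 0),
       mean_stage_change = mean(change),
       pairs = m)
}

#' Association between model stage and an external outcome
#'
#' Ordinary least-squares regression of a per-visit outcome (e.g. a clinical
#' severity score or disease duration) on the assigned stage, with
#' normal-theory 95% confidence interval for the slope. One observation per
#' row; repeated-measures structure is deliberately not modelled here.
#'
#' @param staging An `ebm_staging` data frame.
#' @param outcome Numeric vector, one value per staging row (NA allowed;
#'   such rows are dropped).
#' @return List with `beta`, `ci` (length 2), `intercept`, `r_squared`, `p`,
#'   and `n`.
#' @export
stage_association <- function(staging, outcome) {
  stopifnot(inherits(staging, "ebm_staging"))
  if (length(outcome) != nrow(staging)) {
    stop("`outcome` must have one value per staging row")
  }
  keep <- is.finite(staging$stage) & is.finite(outcome)
  stage <- staging$stage[keep]
  y <- outcome[keep]
  if (length(y) < 3) stop("need at least 3 paired observations")
  if (stats::var(stage) == 0) stop("zero variance in stage")
  fit <- stats::lm(y ~ stage)
  sm <- summary(fit)
  ci <- stats::confint(fit, "stage", level = 0.95)
  list(beta = unname(stats::coef(fit)["stage"]),
       ci = as.numeric(ci),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared,
       p = sm$coefficients["stage", "Pr(>|t|)"],
       n = length(y))
}

#' Run the full event-based model pipeline on a cohort
#'
#' Orchestrates the standard analysis: fit covariate models on baseline
#' controls, adjust all rows, select biomarkers, fit per-event KDE mixtures
#' (baseline data), fit the EBM on baseline cases only, stage every
#' subject-visit (including follow-up rows, staged under the baseline model),
#' and, when a follow-up table is supplied, compute the longitudinal
#' consistency report.
#'
#' @param baseline Baseline biomarker table (cases and controls).
#' @param followup Optional follow-up biomarker table.
#' @param family_alpha Family-wise level for biomarker selection
#'   (default 0.05).
#' @param select Drop events failing the Bonferroni test before model fitting
#'   (default TRUE).
#' @param threshold_stage Stage cut-off for the case/control classifier
#'   (default 2).
#' @param n_init,n_samples,burn_in,thin EBM fit controls (see [fit_ebm()]).
#' @param seed Integer master seed; reruns with the same seed reproduce the
#'   ML sequence and stages exactly.
#' @return A list of class `ebm_pipeline`: `covariate_model`, `selection`,
#'   `events_used`, `mixtures`, `ebm`, `staging` (baseline),
#'   `staging_followup`, `classification`, `longitudinal`, and a `manifest`
#'   (seed, sizes, package version).
#' @export
run_ebm_pipeline <- function(baseline, followup = NULL, family_alpha = 0.05,
                             select = TRUE, threshold_stage = 2,
                             n_init = 10, n_samples = 40000,
                             burn_in = 10000, thin = 1, seed = 1L) {
  stopifnot(is.data.frame(baseline))
  controls <- baseline[baseline$group == "control", , drop = FALSE]
  cases <- baseline[baseline$group == "case", , drop = FALSE]
  if (nrow(controls) == 0 || nrow(cases) == 0) {
    stop("pipeline failed at preprocess: need both cases and controls")
  }
  cov_model <- fit_covariate_model(controls)
  adj_cases <- adjust_covariates(cases, cov_model)
  adj_controls <- adjust_covariates(controls, cov_model)
  selection <- select_biomarkers(adj_cases, adj_controls, family_alpha)
  events <- if (select) selection$event[selection$pass] else selection$event
  if (length(events) < 2) {
    stop("pipeline failed at selection: fewer than 2 events selected")
  }
  mixtures <- fit_all_mixtures(adj_cases, adj_controls, events = events)
  L_cases <- event_likelihood_matrix(mixtures, adj_cases)
  ebm <- fit_ebm(L_cases, n_init = n_init, n_samples = n_samples,
                 burn_in = burn_in, thin = thin, seed = seed)
  L_all <- event_likelihood_matrix(mixtures,
                                   rbind(adj_cases, adj_controls))
  staging <- stage_cohort(L_all, ebm$ml_sequence)
  classification <- classify_by_stage(staging, threshold_stage)
  staging_fu <- NULL
  longitudinal <- NULL
  if (!is.null(followup)) {
    adj_fu <- adjust_covariates(followup, cov_model)
    L_fu <- event_likelihood_matrix(mixtures, adj_fu)
    staging_fu <- stage_cohort(L_fu, ebm$ml_sequence)
    longitudinal <- longitudinal_consistency(staging, staging_fu)
  }
  structure(list(
    covariate_model = cov_model, selection = selection, events_used = events,
    mixtures = mixtures, ebm = ebm, staging = staging,
    staging_followup = staging_fu, classification = classification,
    longitudinal = longitudinal,
    manifest = list(seed = seed, n_cases = nrow(cases),
                    n_controls = nrow(controls),
                    n_events = length(events),
                    package_version = as.character(utils::packageVersion("ebmseq")),
                    timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "ebm_pipeline")
}
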