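# Maximum-likelihood patient staging under a fitted event sequence, the
# staging histogram, and the stage-threshold classifier.

#' Stage one subject under a fitted sequence
#'
#' Evaluates the stage log-likelihoods `k = 0..Z` (uniform stage prior; at
#' stage `k` the first `k` events of the sequence are abnormal, the rest
#' normal) and returns the maximizing stage. Ties are broken toward the
#' lowest stage — the conservative choice of fewest events.
#'
#' @param p_event,p_not_event Length-Z vectors of event likelihoods for the
#'   subject (natural scale, entries > 0).
#' @param s Integer permutation of `1..Z`.
#' @return List with `stage` (integer in `0..Z`) and `log_liks`
#'   (length `Z + 1`, stage 0 first).
#' @export
stage_subject <- function(p_event, p_not_event, s) {
  z <- length(p_event)
  s <- check_sequence(s, z)
  if (any(!is.finite(p_event)) || any(!is.finite(p_not_event)) ||
      any(p_event <= 0) || any(p_not_event <= 0)) {
    stop("event likelihoods must be finite and positive")
  }
  a <- log(p_event)[s]
  b <- log(p_not_event)[s]
  ll <- cumsum(c(0, a - b)) + sum(b) - log(z + 1)
  k <- which.max(ll) - 1L   # which.max takes the first (lowest) on ties
  list(stage = k, log_liks = ll)
}

#' Stage every subject-visit in an event-likelihood matrix
#'
#' Assigns each row its maximum-likelihood stage under the given sequence.
#' Cases and controls, baseline and follow-up rows are all staged against
#' the same (baseline-fitted) mixtures and sequence.
#'
#' @param L An `event_likelihood_matrix`.
#' @param s Integer permutation of `1..Z`.
#' @return A data frame of class `ebm_staging` with columns `subject_id`,
#'   `visit`, `group`, `stage`, `stage_log_lik` (the maximized value);
#'   attribute `log_liks` holds the full N x (Z+1) stage log-likelihood
#'   matrix and attribute `sequence` the sequence used.
#' @export
stage_cohort <- function(L, s) {
  check_elm(L)
  s <- check_sequence(s, length(L$events))
  n <- nrow(L$log_p_e)
  if (n == 0) {
    out <- data.frame(subject_id = character(0), visit = character(0),
                      group = character(0), stage = integer(0),
                      stage_log_lik = numeric(0))
    attr(out, "log_liks") <- matrix(numeric(0), 0, length(L$events) + 1)
    attr(out, "sequence") <- s
    class(out) <- c("ebm_staging", class(out))
    return(out)
  }
  m <- stage_loglik_matrix(L, s)
  stage <- max.col(m, ties.method = "first") - 1L
  out <- data.frame(subject_id = L$subject_id, visit = L$visit,
                    group = L$group, stage = stage,
                    stage_log_lik = m[cbind(seq_len(n), stage + 1L)],
                    stringsAsFactors = FALSE)
  attr(out, "log_liks") <- m
  attr(out, "sequence") <- s
  class(out) <- c("ebm_staging", class(out))
  out
}

#' Classify case versus control by a stage threshold
#'
#' Predicts "case" for every subject-visit staged at or beyond
#' `threshold_stage` and reports the resulting accuracy, sensitivity and
#' specificity against the recorded group labels.
#'
#' @param staging An `ebm_staging` data frame.
#' @param threshold_stage Integer stage cut-off (predict case iff
#'   `stage >= threshold_stage`).
#' @return List with `accuracy`, `sensitivity`, `specificity`, and the 2x2
#'   `confusion` matrix. With a single-class input the undefined rate is
#'   returned as `NA`.
#' @export
classify_by_stage <- function(staging, threshold_stage = 2) {
  stopifnot(inherits(staging, "ebm_staging"))
  if (nrow(staging) == 0) stop("empty staging result")
  pred_case <- staging$stage >= threshold_stage
  is_case <- staging$group == "case"
  tp <- sum(pred_case & is_case)
  tn <- sum(!pred_case & !is_case)
  fp <- sum(pred_case & !is_case)
  fn <- sum(!pred_case & is_case)
  list(
    accuracy = (tp + tn) / nrow(staging),
    sensitivity = if (any(is_case)) tp / (tp + fn) else NA_real_,
    specificity = if (any(!is_case)) tn / (tn + fp) else NA_real_,
    confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                       dimnames = list(predicted = c("case", "control"),
                                       truth = c("case", "control")))
  )
}

#' Staging histogram counts
#'
#' Per-group proportion of subjects at each stage `0..Z`, the quantity shown
#' in a staging histogram.
#'
#' @param staging An `ebm_staging` data frame.
#' @param z Number of events (inferred from the stored sequence by default).
#' @return Matrix with one row per group and `Z + 1` columns of proportions.
#' @export
staging_histogram <- function(staging, z = NULL) {
  stopifnot(inherits(staging, "ebm_staging"))
  z <- z %||% length(attr(staging, "sequence"))
  groups <- sort(unique(staging$group))
  out <- t(vapply(groups, function(g) {
    st <- staging$stage[staging$group == g]
    tabulate(st + 1L, nbins = z + 1) / length(st)
  }, numeric(z + 1)))
  colnames(out) <- paste0("stage_", 0:z)
  out
}
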