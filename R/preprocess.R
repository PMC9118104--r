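# Covariate adjustment against controls, lateral-region combination,
# biomarker selection, and summary-statistic utilities.

#' Combine left/right region columns into single bilateral volumes
#'
#' Regions carrying separate left and right labels are combined by summing
#' the two columns; all other columns are untouched. The combined column
#' takes the supplied name and is placed where the left column was.
#'
#' @param table A biomarker table.
#' @param pairs A named list: `list(combined_name = c("left_col", "right_col"), ...)`.
#'   An empty list returns the table unchanged.
#' @return The table with each pair replaced by its sum.
#' @export
combine_lateral_regions <- function(table, pairs) {
  stopifnot(is.data.frame(table))
  if (length(pairs) == 0) return(table)
  if (is.null(names(pairs)) || any(names(pairs) == "")) {
    stop("`pairs` must be a named list of c(left, right) column pairs")
  }
  for (nm in names(pairs)) {
    pr <- pairs[[nm]]
    missing <- setdiff(pr, names(table))
    if (length(missing)) {
      stop("columns not present in table: ", paste(missing, collapse = ", "))
    }
    combined <- table[[pr[1]]] + table[[pr[2]]]
    table[[pr[1]]] <- combined
    names(table)[names(table) == pr[1]] <- nm
    table[[pr[2]]] <- NULL
  }
  table
}

#' Fit per-event covariate models on the control cohort
#'
#' Ordinary least-squares regression of each event column on age, sex,
#' scanner (reference-level indicators) and total intracranial volume, using
#' control rows only. The fitted models are later applied to cases and
#' controls alike to produce covariate-adjusted volumes whose control
#' distribution is centred at zero.
#'
#' @param controls A biomarker table restricted to control rows.
#' @param covariates Covariate columns to use (default age, sex, tiv,
#'   scanner). Zero-variance covariates (e.g. a single scanner level) are
#'   dropped with a warning, falling back to an intercept-only model if none
#'   remain.
#' @return An object of class `ebm_covariate_model`: per-event coefficient
#'   vectors plus the design description.
#' @export
fit_covariate_model <- function(controls,
                                covariates = c("age", "sex", "tiv", "scanner")) {
  stopifnot(is.data.frame(controls))
  if (any(controls$group != "control")) {
    stop("`controls` must contain control rows only")
  }
  events <- event_columns(controls)
  keep <- covariates[vapply(covariates, function(v) {
    x <- controls[[v]]
    ok <- length(unique(x)) > 1
    if (!ok) warning("dropping zero-variance covariate `", v, "`",
                     call. = FALSE)
    ok
  }, logical(1))]
  scanner_levels <- if ("scanner" %in% keep) {
    sort(unique(as.character(controls$scanner)))
  } else NULL
  rhs <- if (length(keep)) paste(keep, collapse = " + ") else "1"
  df <- controls
  if (!is.null(scanner_levels)) {
    df$scanner <- factor(df$scanner, levels = scanner_levels)
  }
  if (nrow(df) < length(keep) + 2 + length(scanner_levels %||% character(0))) {
    stop("too few control rows to fit the covariate model")
  }
  fits <- lapply(events, function(ev) {
    fml <- stats::as.formula(paste0("`", ev, "` ~ ", rhs))
    fit <- stats::lm(fml, data = df)
    co <- stats::coef(fit)
    if (anyNA(co)) {
      warning("rank-deficient design for event `", ev,
              "`; dropping aliased terms", call. = FALSE)
      co[is.na(co)] <- 0
    }
    co
  })
  names(fits) <- events
  structure(list(coefficients = fits, covariates = keep,
                 scanner_levels = scanner_levels, events = events),
            class = "ebm_covariate_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Model-matrix for prediction under a fitted covariate model; unseen scanner
# levels map to the reference level with a warning.
predict_covariates <- function(model, table) {
  df <- table
  if (!is.null(model$scanner_levels)) {
    unseen <- setdiff(unique(as.character(df$scanner)), model$scanner_levels)
    if (length(unseen)) {
      warning("unseen scanner level(s) mapped to reference: ",
              paste(unseen, collapse = ", "), call. = FALSE)
      df$scanner[df$scanner %in% unseen] <- model$scanner_levels[1]
    }
    df$scanner <- factor(df$scanner, levels = model$scanner_levels)
  }
  rhs <- if (length(model$covariates)) {
    paste(model$covariates, collapse = " + ")
  } else "1"
  mm <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = df)
  pred <- sapply(model$events, function(ev) {
    co <- model$coefficients[[ev]]
    drop(mm[, names(co), drop = FALSE] %*% co)
  })
  matrix(pred, nrow = nrow(df), dimnames = list(NULL, model$events))
}

#' Covariate-adjust a biomarker table
#'
#' Replaces each event value by its residual from the control-fitted
#' covariate model (observed minus predicted). The same control-based model
#' is applied to cases and controls, so adjusted control volumes are centred
#' at zero and case abnormality shows as negative adjusted values.
#'
#' @param table A biomarker table (cases, controls, or both; any visit).
#' @param model An `ebm_covariate_model` from [fit_covariate_model()].
#' @return The table with event columns replaced by adjusted residuals.
#' @export
adjust_covariates <- function(table, model) {
  stopifnot(inherits(model, "ebm_covariate_model"))
  missing <- setdiff(model$events, names(table))
  if (length(missing)) {
    stop("table lacks event columns: ", paste(missing, collapse = ", "))
  }
  pred <- predict_covariates(model, table)
  table[, model$events] <- as.matrix(table[, model$events]) - pred
  table
}

#' Select biomarkers by Bonferroni-corrected group difference
#'
#' Per event, a two-sided Welch (unequal-variance) t-test of covariate-
#' adjusted case versus control values. An event passes selection when its
#' p-value is below the family-wise level divided by the number of events
#' tested (Bonferroni); with 19 events at family-wise 0.05 the threshold is
#' 0.05/19 = 2.63e-3.
#'
#' @param cases,controls Covariate-adjusted biomarker tables.
#' @param family_alpha Family-wise error level (default 0.05).
#' @return A data frame of class `ebm_selection` with columns `event`, `t`,
#'   `p`, `pass`, plus attribute `threshold`.
#' @export
select_biomarkers <- function(cases, controls, family_alpha = 0.05) {
  events <- event_columns(cases)
  if (!identical(events, event_columns(controls))) {
    stop("case and control tables must share identical event columns")
  }
  if (nrow(cases) < 2 || nrow(controls) < 2) {
    stop("need at least two rows per group")
  }
  threshold <- family_alpha / length(events)
  rows <- lapply(events, function(ev) {
    x <- cases[[ev]]; y <- controls[[ev]]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      warning("event `", ev, "` has zero variance in both groups; not selected",
              call. = FALSE)
      return(data.frame(event = ev, t = NA_real_, p = NA_real_, pass = FALSE))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    data.frame(event = ev, t = unname(tt$statistic), p = tt$p.value,
               pass = is.finite(tt$p.value) && tt$p.value < threshold)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  class(out) <- c("ebm_selection", class(out))
  out
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson chi-square without continuity correction, 1 degree of freedom;
#' the form that reproduces printed demographic comparisons such as a
#' male/female split between groups.
#'
#' @param a,b,c,d Cell counts, row-wise: `matrix(c(a, b, c, d), 2, byrow = TRUE)`.
#' @return List with `statistic` and `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("counts must be non-negative with a positive total")
  }
  m <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-square undefined: a marginal total is zero")
  }
  ht <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t statistic and two-sided p-value computed from group
#' means, standard deviations and sizes, with Welch-Satterthwaite degrees of
#' freedom. Sign convention: `mean1 - mean2`.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `statistic`, `df`, `p`.
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
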