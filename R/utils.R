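# Internal numerical and bookkeeping helpers.

# Columns every biomarker table carries besides the event columns.
.meta_cols <- c("subject_id", "visit", "group", "age", "sex", "tiv", "scanner")

#' Event (biomarker) columns of a biomarker table
#'
#' A biomarker table is an ordinary data frame with the metadata columns
#' `subject_id`, `visit`, `group`, `age`, `sex`, `tiv`, `scanner`; every other
#' column is treated as one event (region-of-interest volume).
#'
#' @param table A biomarker table (data frame).
#' @return Character vector of event column names, in table order.
#' @export
event_columns <- function(table) {
  stopifnot(is.data.frame(table))
  setdiff(names(table), .meta_cols)
}

# Row-wise log-sum-exp of a numeric matrix, guarded against -Inf rows.
logsumexp_rows <- function(m) {
  stopifnot(is.matrix(m))
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx <- ifelse(is.finite(mx), mx, 0)
  mx + log(rowSums(exp(m - mx)))
}

logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

# Validate that s is a permutation of 1..z.
check_sequence <- function(s, z) {
  if (length(s) != z || !identical(sort(as.integer(s)), seq_len(z))) {
    stop("`sequence` must be a permutation of 1..", z, call. = FALSE)
  }
  as.integer(s)
}

#' Kendall rank correlation between two event sequences
#'
#' Scores how well an estimated event ordering recovers a reference ordering.
#' Both sequences are permutations of the same event indices; the statistic is
#' Kendall's tau between the event positions under the two orderings (1 =
#' identical order, -1 = exactly reversed).
#'
#' @param s1,s2 Integer permutations of `1..Z` (event indices in order of
#'   occurrence).
#' @return Kendall's tau, a number in `[-1, 1]`.
#' @export
kendall_tau <- function(s1, s2) {
  z <- length(s1)
  s1 <- check_sequence(s1, z)
  s2 <- check_sequence(s2, z)
  stats::cor(match(seq_len(z), s1), match(seq_len(z), s2), method = "kendall")
}

# Shannon entropy (nats) of one probability row, 0 log 0 = 0.
row_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Draw a seed for a sub-task from a master seed without exhausting it.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}
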