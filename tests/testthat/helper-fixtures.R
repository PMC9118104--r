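# Shared fixtures and independent oracles for the test suite.

# Wrap likelihood matrices (natural scale) into the package's container.
mk_elm <- function(p_e, p_ne, group = "case") {
  structure(list(
    log_p_e = log(p_e), log_p_ne = log(p_ne),
    events = paste0("e", seq_len(ncol(p_e))),
    subject_id = paste0("s", seq_len(nrow(p_e))),
    visit = rep("baseline", nrow(p_e)),
    group = rep(group, nrow(p_e))
  ), class = "event_likelihood_matrix")
}

# Independent oracle: literally materialize every stage product.
brute_sequence_loglik <- function(L, s) {
  z <- length(s)
  pe <- exp(L$log_p_e)
  pn <- exp(L$log_p_ne)
  tot <- 0
  for (j in seq_len(nrow(pe))) {
    terms <- vapply(0:z, function(k) {
      abn <- s[seq_len(k)]
      nrm <- setdiff(s, abn)
      prod(pe[j, abn]) * prod(pn[j, nrm]) / (z + 1)
    }, numeric(1))
    tot <- tot + log(sum(terms))
  }
  tot
}

# All permutations of 1..z (z small).
all_perms <- function(z) {
  rec <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(rec(v[-i]), function(q) c(v[i], q))
    }))
  }
  rec(seq_len(z))
}

# Exhaustive maximum-likelihood sequence.
exhaustive_ml <- function(L) {
  z <- length(L$events)
  ps <- all_perms(z)
  lls <- vapply(ps, function(s) sequence_log_likelihood(L, s), numeric(1))
  list(sequence = ps[[which.max(lls)]], log_likelihood = max(lls))
}

# Staged likelihood-matrix instance with a known ground-truth ordering:
# event j of a stage-k subject is "abnormal-looking" iff j occurs within the
# first k positions of s_true.
mk_staged_instance <- function(n, z, s_true, stage = NULL,
                               p_hi = 0.9, p_lo = 0.1, jitter = 0.2,
                               seed = 1) {
  set.seed(seed)
  if (is.null(stage)) stage <- sample(0:z, n, replace = TRUE)
  pos <- match(seq_len(z), s_true)
  pe <- matrix(p_lo, n, z)
  pn <- matrix(p_hi, n, z)
  for (j in seq_len(z)) {
    abn <- stage >= pos[j]
    pe[abn, j] <- p_hi
    pn[abn, j] <- p_lo
  }
  pe <- pe * matrix(stats::runif(n * z, 1 - jitter, 1 + jitter), n)
  pn <- pn * matrix(stats::runif(n * z, 1 - jitter, 1 + jitter), n)
  list(L = mk_elm(pe, pn), stage = stage)
}

# Small synthetic cohort for pipeline-level tests.
small_cohort <- function(seed = 1, n_events = 6, n_cases = 120,
                         n_controls = 80, separation = 3) {
  cfg <- sim_config(n_cases = n_cases, n_controls = n_controls,
                    n_events = n_events,
                    abnormal_mean = 100 - separation, seed = seed)
  list(cfg = cfg, cohort = generate_cohort(cfg))
}

# Fabricated staging table for association utilities.
mk_staging <- function(stage, group = rep("case", length(stage))) {
  out <- data.frame(subject_id = paste0("s", seq_along(stage)),
                    visit = "baseline", group = group, stage = stage,
                    stage_log_lik = 0, stringsAsFactors = FALSE)
  attr(out, "sequence") <- seq_len(max(stage, 1))
  class(out) <- c("ebm_staging", class(out))
  out
}
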