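test_that("sequence likelihood matches hand enumeration and identities", {
  # two events, one subject, worked by hand over stages k in {0, 1, 2}
  L <- mk_elm(matrix(c(0.9, 0.2), 1), matrix(c(0.1, 0.8), 1))
  expect_equal(exp(sequence_log_likelihood(L, c(1, 2))),
               (0.1 * 0.8 + 0.9 * 0.8 + 0.9 * 0.2) / 3, tolerance = 1e-12)
  expect_equal(exp(sequence_log_likelihood(L, c(2, 1))),
               (0.1 * 0.8 + 0.1 * 0.2 + 0.9 * 0.2) / 3, tolerance = 1e-12)
  # flat likelihoods collapse the stage sum for every sequence
  Lf <- mk_elm(matrix(0.3, 4, 5), matrix(0.3, 4, 5))
  expect_equal(sequence_log_likelihood(Lf, 1:5), 4 * 5 * log(0.3),
               tolerance = 1e-12)
  expect_equal(sequence_log_likelihood(Lf, 5:1), 4 * 5 * log(0.3),
               tolerance = 1e-12)
  expect_error(sequence_log_likelihood(L, c(1, 1)), "permutation")
})

test_that("sequence likelihood agrees with the brute-force stage-product oracle", {
  set.seed(7)
  for (i in 1:30) {
    z <- sample(2:6, 1)
    n <- sample(3:10, 1)
    pe <- matrix(runif(n * z, 0.01, 1), n)
    pn <- matrix(runif(n * z, 0.01, 1), n)
    L <- mk_elm(pe, pn)
    s <- sample.int(z)
    expect_equal(sequence_log_likelihood(L, s), brute_sequence_loglik(L, s),
                 tolerance = 1e-9)
  }
})

test_that("likelihood is invariant under consistent relabeling and scales with duplication", {
  set.seed(8)
  z <- 5; n <- 12
  L <- mk_elm(matrix(runif(n * z, 0.05, 1), n), matrix(runif(n * z, 0.05, 1), n))
  s <- sample.int(z)
  perm <- sample.int(z)
  Lp <- mk_elm(exp(L$log_p_e[, perm]), exp(L$log_p_ne[, perm]))
  # relabeled columns with a matching sequence give the same value
  expect_equal(sequence_log_likelihood(L, s),
               sequence_log_likelihood(Lp, match(s, perm)), tolerance = 1e-12)
  # duplicating every subject doubles log-likelihood differences
  L2 <- mk_elm(exp(rbind(L$log_p_e, L$log_p_e)),
               exp(rbind(L$log_p_ne, L$log_p_ne)))
  s2 <- sample.int(z)
  d1 <- sequence_log_likelihood(L, s) - sequence_log_likelihood(L, s2)
  d2 <- sequence_log_likelihood(L2, s) - sequence_log_likelihood(L2, s2)
  expect_equal(d2, 2 * d1, tolerance = 1e-9)
})

test_that("greedy ascent finds the exhaustive optimum on small instances", {
  hits <- vapply(1:20, function(i) {
    inst <- mk_staged_instance(40, 5, sample.int(5), seed = i)
    best <- exhaustive_ml(inst$L)
    g <- greedy_ascent(inst$L, n_init = 5, seed = i)
    identical(as.integer(g$sequence), as.integer(best$sequence))
  }, logical(1))
  expect_true(all(hits))
})

test_that("greedy ascent is a fixed point at an optimum and halts on flat landscapes", {
  inst <- mk_staged_instance(40, 5, c(3, 1, 5, 2, 4), seed = 99)
  best <- exhaustive_ml(inst$L)
  g <- greedy_ascent(inst$L, n_init = 1, seed = 1, init = best$sequence)
  expect_identical(as.integer(g$sequence), as.integer(best$sequence))
  Lf <- mk_elm(matrix(0.5, 3, 4), matrix(0.5, 3, 4))
  gf <- greedy_ascent(Lf, n_init = 1, seed = 2)
  expect_length(gf$sequence, 4)
  expect_equal(gf$log_likelihood, 3 * 4 * log(0.5), tolerance = 1e-12)
})

test_that("MCMC is deterministic under a fixed seed and accepts freely when flat", {
  Lf <- mk_elm(matrix(0.5, 3, 6), matrix(0.5, 3, 6))
  m1 <- mcmc_sequences(Lf, 1:6, n_samples = 500, burn_in = 100, seed = 5)
  m2 <- mcmc_sequences(Lf, 1:6, n_samples = 500, burn_in = 100, seed = 5)
  expect_identical(m1$samples, m2$samples)
  expect_equal(m1$acceptance_rate, 1)
  # a dominant sequence captures nearly all samples
  inst <- mk_staged_instance(200, 4, c(2, 4, 1, 3), jitter = 0.05, seed = 3)
  best <- exhaustive_ml(inst$L)
  mc <- mcmc_sequences(inst$L, best$sequence, n_samples = 2000, burn_in = 500,
                       seed = 4)
  frac_ml <- mean(apply(mc$samples, 1, function(r) {
    identical(as.integer(r), as.integer(best$sequence))
  }))
  expect_gte(frac_ml, 0.95)
})

test_that("positional variance counts positions and stays doubly stochastic", {
  s <- c(2, 3, 1)
  pv <- positional_variance(rbind(s, s, s))
  expect_equal(unname(pv), diag(3)[c(3, 1, 2), ])
  # two samples differing by one swap put 0.5 in the affected cells
  pv2 <- positional_variance(rbind(c(1, 2, 3), c(2, 1, 3)))
  expect_equal(unname(pv2[, 1]), c(0.5, 0.5, 0))
  expect_equal(unname(pv2[, 3]), c(0, 0, 1))
  set.seed(11)
  samp <- t(replicate(500, sample.int(7)))
  pv3 <- positional_variance(samp)
  expect_equal(rowSums(pv3), rep(1, 7), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(colSums(pv3), rep(1, 7), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(positional_variance(list(c(1, 2), c(1, 2, 3))), "inconsistent")
})

test_that("uniform random permutations give a near-uniform positional variance", {
  set.seed(12)
  z <- 10
  samp <- t(replicate(1e5, sample.int(z)))
  pv <- positional_variance(samp)
  expect_lt(max(abs(pv - 1 / z)), 0.01)
})

test_that("fit_ebm matches the exhaustive optimum and exposes diffuse events", {
  for (i in 1:5) {
    inst <- mk_staged_instance(30, 5, sample.int(5), seed = 40 + i)
    best <- exhaustive_ml(inst$L)
    fit <- fit_ebm(inst$L, n_init = 4, n_samples = 300, burn_in = 200,
                   seed = i)
    expect_identical(as.integer(fit$ml_sequence), as.integer(best$sequence))
    expect_equal(fit$log_likelihood, best$log_likelihood, tolerance = 1e-9)
  }
  # an event with identical normal/abnormal likelihoods has a diffuse row
  inst <- mk_staged_instance(25, 5, 1:5, p_hi = 0.7, p_lo = 0.3,
                             jitter = 0.2, seed = 77)
  pe <- exp(inst$L$log_p_e); pn <- exp(inst$L$log_p_ne)
  pe[, 3] <- pn[, 3] <- 0.5
  L <- mk_elm(pe, pn)
  fit <- fit_ebm(L, n_init = 4, n_samples = 4000, burn_in = 1000, thin = 5,
                 seed = 9)
  expect_lt(max(fit$positional_variance[3, ]), 0.5)
  # every PVD from MCMC samples is doubly stochastic
  expect_equal(rowSums(fit$positional_variance), rep(1, 5), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(colSums(fit$positional_variance), rep(1, 5), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("EBM fits serialize with their positional variance", {
  dir <- withr::local_tempdir()
  inst <- mk_staged_instance(30, 4, c(2, 1, 4, 3), seed = 13)
  fit <- fit_ebm(inst$L, n_init = 2, n_samples = 200, burn_in = 100, seed = 1)
  write_ebm_fit(fit, dir)
  meta <- jsonlite::read_json(file.path(dir, "ebm_fit.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$ml_sequence, fit$ml_sequence)
  pv <- as.matrix(utils::read.table(file.path(dir, "positional_variance.tsv"),
                                    sep = "\t", header = TRUE, row.names = 1))
  expect_equal(unname(pv), unname(fit$positional_variance), tolerance = 1e-12)
})
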