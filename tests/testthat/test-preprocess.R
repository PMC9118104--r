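mk_table <- function(n, values, group = "control", seed = 1) {
  set.seed(seed)
  cbind(data.frame(subject_id = paste0(group, seq_len(n)), visit = "baseline",
                   group = group,
                   age = rnorm(n, 65, 9), sex = rbinom(n, 1, 0.5),
                   tiv = rnorm(n, 1450, 130),
                   scanner = sample(paste0("scanner_", 1:3), n, TRUE),
                   stringsAsFactors = FALSE),
        as.data.frame(values))
}

test_that("lateral regions combine by summation and only when present", {
  tab <- mk_table(4, data.frame(hip_l = c(3, 1, 2, 5), hip_r = c(4, 2, 0, 1),
                                pons = 9:12))
  out <- combine_lateral_regions(tab, list(hippocampus = c("hip_l", "hip_r")))
  expect_equal(out$hippocampus, c(7, 3, 2, 6))
  expect_false(any(c("hip_l", "hip_r") %in% names(out)))
  expect_equal(out$pons, tab$pons)
  expect_identical(combine_lateral_regions(tab, list()), tab)
  expect_error(combine_lateral_regions(tab, list(x = c("hip_l", "nope"))),
               "not present")
})

test_that("a lateralized layout collapses to the 19-region event set", {
  # 12 paired regions + 7 midline regions -> 19 events after combination
  paired <- c("thalamus", "globus_pallidus", "striatum", "ventral_dc",
              "subthalamic_nucleus", "hippocampus", "amygdala",
              "insula", "frontal", "temporal", "parietal", "occipital")
  midline <- c("medulla", "pons", "scp", "midbrain",
               "cerebellar_cortex", "cerebellar_deep_nuclei",
               "cerebellar_vermis")
  vals <- as.data.frame(matrix(rnorm(10 * (2 * 12 + 7)), 10))
  names(vals) <- c(paste0(rep(paired, each = 2), c("_l", "_r")), midline)
  tab <- mk_table(10, vals)
  pairs <- stats::setNames(lapply(paired, function(p) paste0(p, c("_l", "_r"))),
                           paired)
  out <- combine_lateral_regions(tab, pairs)
  expect_length(event_columns(out), 19)
  expect_setequal(event_columns(out), c(paired, midline))
})

test_that("covariate model recovers generative slopes and centres controls", {
  set.seed(42)
  n <- 500
  tab <- mk_table(n, data.frame(roi = 0), seed = 42)
  tab$roi <- 100 - 0.5 * tab$age + rnorm(n, 0, 1)
  m <- fit_covariate_model(tab)
  expect_lt(abs(m$coefficients$roi["age"] + 0.5), 0.05)
  adj <- adjust_covariates(tab, m)
  expect_lt(abs(mean(adj$roi)), 1e-8)
})

test_that("zero-variance covariates fall back to an intercept-only model", {
  tab <- mk_table(50, data.frame(roi = rnorm(50, 10)))
  tab$age <- 60; tab$sex <- 1; tab$tiv <- 1400; tab$scanner <- "scanner_1"
  w <- capture_warnings(m <- fit_covariate_model(tab))
  expect_true(any(grepl("zero-variance", w)))
  expect_equal(unname(m$coefficients$roi["(Intercept)"]), mean(tab$roi),
               tolerance = 1e-10)
  expect_length(m$coefficients$roi, 1)
})

test_that("adjustment removes control-fitted effects from cases too", {
  # cases shifted by -2 for a fraction of subjects: adjusted case mean
  # approximates -2 times that fraction
  set.seed(9)
  n <- 1000
  ctrl <- mk_table(n, data.frame(roi = 0), seed = 9)
  ctrl$roi <- 50 + 0.1 * ctrl$age + 0.01 * ctrl$tiv + rnorm(n, 0, 0.5)
  m <- fit_covariate_model(ctrl)
  frac <- 0.4
  cas <- mk_table(n, data.frame(roi = 0), group = "case", seed = 10)
  shift <- ifelse(runif(n) < frac, -2, 0)
  cas$roi <- 50 + 0.1 * cas$age + 0.01 * cas$tiv + shift + rnorm(n, 0, 0.5)
  adj <- adjust_covariates(cas, m)
  expect_lt(abs(mean(adj$roi) - (-2 * frac)), 0.1)
})

test_that("adjustment is idempotent on controls under refitting", {
  ctrl <- mk_table(200, data.frame(a = rnorm(200, 20), b = rnorm(200, 30)),
                   seed = 3)
  m1 <- fit_covariate_model(ctrl)
  adj1 <- adjust_covariates(ctrl, m1)
  m2 <- fit_covariate_model(adj1)
  adj2 <- adjust_covariates(adj1, m2)
  expect_lt(max(abs(as.matrix(adj2[, c("a", "b")]) -
                      as.matrix(adj1[, c("a", "b")]))), 1e-8)
})

test_that("unseen scanner levels map to the reference with a warning", {
  ctrl <- mk_table(100, data.frame(roi = rnorm(100)), seed = 4)
  m <- fit_covariate_model(ctrl)
  cas <- mk_table(5, data.frame(roi = rnorm(5)), group = "case", seed = 5)
  cas$scanner <- "scanner_99"
  expect_warning(adjust_covariates(cas, m), "unseen scanner")
})

test_that("selection applies the Bonferroni threshold per event", {
  z <- 19
  mkv <- function(n, shift_cols = integer(0), seed) {
    set.seed(seed)
    v <- matrix(rnorm(n * z), n)
    v[, shift_cols] <- v[, shift_cols] - 2
    colnames(v) <- paste0("roi_", seq_len(z))
    as.data.frame(v)
  }
  cases <- mk_table(300, mkv(300, 1:10, seed = 21), group = "case")
  ctrls <- mk_table(200, mkv(200, seed = 22))
  rep <- select_biomarkers(cases, ctrls)
  expect_equal(attr(rep, "threshold"), 0.05 / 19)
  expect_identical(rep$event[rep$pass], paste0("roi_", 1:10))
  # null: pass count stays near its Bonferroni-controlled expectation
  passes <- vapply(1:60, function(i) {
    cas <- mk_table(60, mkv(60, seed = 100 + i), group = "case")
    ctl <- mk_table(60, mkv(60, seed = 200 + i))
    sum(select_biomarkers(cas, ctl)$pass)
  }, numeric(1))
  expect_lte(sum(passes), 10)  # Binomial(60 * 19, 0.05/19), mean 3
})

test_that("selection evidence is monotone in the case shift", {
  z <- 5
  set.seed(31)
  base_cas <- matrix(rnorm(150 * z), 150)
  base_ctl <- matrix(rnorm(150 * z), 150)
  colnames(base_cas) <- colnames(base_ctl) <- paste0("roi_", 1:z)
  ctl <- mk_table(150, as.data.frame(base_ctl))
  passed <- vapply(seq(0, 2, by = 0.25), function(shift) {
    v <- base_cas
    v[, 1] <- v[, 1] - shift
    cas <- mk_table(150, as.data.frame(v), group = "case")
    select_biomarkers(cas, ctl)$pass[1]
  }, logical(1))
  expect_true(all(diff(passed) >= 0))
})

test_that("chi-square matches printed and hand-computed values", {
  expect_equal(round(chi_square_2x2(176, 165, 112, 148)$statistic, 1), 4.3)
  expect_equal(chi_square_2x2(10, 10, 10, 10)$statistic, 0)
  expect_equal(suppressWarnings(chi_square_2x2(5, 0, 0, 5))$statistic, 10)
  expect_error(chi_square_2x2(5, 0, 5, 0), "marginal")
  # symmetric under simultaneous row and column swaps
  expect_equal(suppressWarnings(chi_square_2x2(7, 3, 2, 9))$statistic,
               suppressWarnings(chi_square_2x2(9, 2, 3, 7))$statistic)
})

test_that("Welch t from summaries matches printed and closed-form values", {
  # control minus case on the cohort's printed age summaries
  expect_equal(round(welch_t_from_summary(62.8, 9.4, 260,
                                          67.9, 6.8, 341)$statistic, 1), -7.4)
  expect_equal(welch_t_from_summary(5, 1, 30, 5, 1, 30)$statistic, 0)
  expect_equal(welch_t_from_summary(1, 1, 100, 0, 1, 100)$statistic,
               sqrt(100 / 2), tolerance = 1e-12)
  expect_error(welch_t_from_summary(1, 1, 1, 0, 1, 100), "at least 2")
})
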