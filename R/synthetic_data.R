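# Synthetic cohort generator: cross-sectional (and follow-up) biomarker
# tables with a known ground-truth event ordering and latent stages, the
# exact generative structure the event-based model assumes.

# Default 19-region layout: 4 brainstem, 3 cerebellar, 7 subcortical,
# 5 cortical volumes (lateral regions already combined).
default_roi_names <- function() {
  c("medulla", "pons", "scp", "midbrain",
    "cerebellar_cortex", "cerebellar_deep_nuclei", "cerebellar_vermis",
    "thalamus", "globus_pallidus", "striatum", "ventral_dc",
    "subthalamic_nucleus", "hippocampus", "amygdala",
    "insula", "frontal", "temporal", "parietal", "occipital")
}

#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort in which each control sits entirely in the normal
#' (pre-event) distribution of every biomarker, while each case carries a
#' latent disease stage `k`: the first `k` events of a ground-truth ordering
#' have occurred, so exactly those biomarkers are drawn from their abnormal
#' distribution. Abnormal means atrophic, i.e. a lower volume, for every
#' event. Additive covariate effects (age, sex, total intracranial volume,
#' scanner) are layered on top so the covariate-adjustment step has real work
#' to do and remains exactly invertible.
#'
#' @param n_cases,n_controls Cohort sizes. Defaults are the post-QC sizes of
#'   the motivating study (341 cases, 260 controls).
#' @param n_events Number of events/regions `Z` (default 19).
#' @param true_sequence `"random"` (draw a permutation from the seed) or an
#'   integer permutation of `1..n_events` giving the order in which events
#'   occur.
#' @param stage_distribution Probability vector of length `n_events + 1` over
#'   latent case stages `0..Z`; default uniform, mirroring the model's
#'   uninformative stage prior.
#' @param normal_mean,normal_sd,abnormal_mean,abnormal_sd Per-event component
#'   parameters, recycled to length `n_events`. `abnormal_mean` must be below
#'   `normal_mean` for every event (atrophy direction). The default 3-SD
#'   separation emulates well-separated volumetric markers.
#' @param skew Per-event skewness parameter of a skew-normal transform
#'   (0 = Gaussian); applied to both components of that event. Components are
#'   centred so their mean equals the stated location whatever the skew.
#' @param covariate_effects Named list of additive slopes/offsets:
#'   `age` (per year), `sex` (male offset), `tiv` (per ml), `scanner`
#'   (numeric offset per scanner level; its length sets the number of
#'   scanners). Use [zero_covariate_effects()] to switch covariates off.
#' @param followup_increment Distribution of the per-case stage increment at
#'   follow-up: a single non-negative integer (point mass), a probability
#'   vector over increments `0, 1, 2, ...`, or `list(poisson = lambda)` for a
#'   Poisson draw (truncated at `Z` when applied).
#' @param seed Integer seed; all randomness flows from it, and a fixed seed
#'   reproduces a byte-identical table.
#' @return An object of class `ebm_sim_config` (a validated list).
#' @seealso [generate_cohort()], [generate_followup()]
#' @export
sim_config <- function(n_cases = 341, n_controls = 260, n_events = 19,
                       true_sequence = "random",
                       stage_distribution = NULL,
                       normal_mean = 100, normal_sd = 1,
                       abnormal_mean = 97, abnormal_sd = 1,
                       skew = 0,
                       covariate_effects = default_covariate_effects(),
                       followup_increment = 1L,
                       seed = 1L) {
  z <- as.integer(n_events)
  if (is.na(z) || z < 1) stop("`n_events` must be a positive integer")
  if (n_cases < 0 || n_controls < 0) stop("cohort sizes must be non-negative")
  if (is.null(stage_distribution)) {
    stage_distribution <- rep(1 / (z + 1), z + 1)
  }
  if (length(stage_distribution) != z + 1 || any(stage_distribution < 0) ||
      abs(sum(stage_distribution) - 1) > 1e-8) {
    stop("`stage_distribution` must be a probability vector over stages 0..Z")
  }
  if (!identical(true_sequence, "random")) {
    true_sequence <- check_sequence(true_sequence, z)
  }
  rec <- function(x) rep_len(as.numeric(x), z)
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_events = z, true_sequence = true_sequence,
    stage_distribution = as.numeric(stage_distribution),
    normal_mean = rec(normal_mean), normal_sd = rec(normal_sd),
    abnormal_mean = rec(abnormal_mean), abnormal_sd = rec(abnormal_sd),
    skew = rec(skew),
    covariate_effects = covariate_effects,
    followup_increment = followup_increment,
    seed = as.integer(seed),
    roi_names = if (z == 19) default_roi_names() else paste0("roi_", seq_len(z))
  )
  if (any(cfg$abnormal_mean >= cfg$normal_mean)) {
    stop("abnormal mean must lie below the normal mean for every event ",
         "(abnormal = atrophic = smaller volume)")
  }
  if (any(cfg$normal_sd <= 0) || any(cfg$abnormal_sd <= 0)) {
    stop("component scales must be positive")
  }
  structure(cfg, class = "ebm_sim_config")
}

#' Default additive covariate effects for the generator
#'
#' Age in years, sex as a male/female indicator, total intracranial volume in
#' ml, and a three-scanner site offset; magnitudes are modest relative to the
#' unit within-component standard deviation so adjustment matters but does not
#' dominate.
#' @export
default_covariate_effects <- function() {
  list(age = -0.05, sex = 0.5, tiv = 0.002, scanner = c(0, 0.3, -0.3))
}

#' @rdname default_covariate_effects
#' @export
zero_covariate_effects <- function() {
  list(age = 0, sex = 0, tiv = 0, scanner = c(0, 0, 0))
}

# Skew-normal-style component draw, centred so E[x] = location.
rskew_component <- function(n, location, scale, alpha) {
  if (alpha == 0) return(stats::rnorm(n, location, scale))
  delta <- alpha / sqrt(1 + alpha^2)
  z <- delta * abs(stats::rnorm(n)) + sqrt(1 - delta^2) * stats::rnorm(n)
  location + scale * (z - delta * sqrt(2 / pi))
}

draw_increment <- function(n, spec) {
  if (is.list(spec) && !is.null(spec$poisson)) {
    return(stats::rpois(n, spec$poisson))
  }
  if (length(spec) == 1 && spec >= 0 && spec == round(spec)) {
    return(rep(as.integer(spec), n))
  }
  p <- as.numeric(spec)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("`followup_increment` must be an integer, a probability vector, ",
         "or list(poisson = lambda)")
  }
  sample.int(length(p), n, replace = TRUE, prob = p) - 1L
}

# Additive covariate contribution matrix (n x Z): same shift for every
# event column scaled by that event's slope set (slopes are shared across
# events here; per-event variation adds nothing the pipeline tests need).
covariate_shift <- function(covars, effects, z) {
  scan_idx <- as.integer(factor(covars$scanner,
                                levels = paste0("scanner_", seq_along(effects$scanner))))
  shift <- effects$age * (covars$age - 65) +
    effects$sex * covars$sex +
    effects$tiv * (covars$tiv - 1450) +
    effects$scanner[scan_idx]
  matrix(shift, nrow = nrow(covars), ncol = z)
}

# Draw the event-value matrix for given per-row stages under a sequence.
draw_values <- function(stages, cfg, true_sequence, covars) {
  n <- length(stages)
  z <- cfg$n_events
  vals <- matrix(NA_real_, n, z)
  # event j abnormal for row r iff position of j in sequence <= stage r
  pos <- match(seq_len(z), true_sequence)
  for (j in seq_len(z)) {
    abn <- stages >= pos[j]
    vals[!abn, j] <- rskew_component(sum(!abn), cfg$normal_mean[j],
                                     cfg$normal_sd[j], cfg$skew[j])
    vals[abn, j] <- rskew_component(sum(abn), cfg$abnormal_mean[j],
                                    cfg$abnormal_sd[j], cfg$skew[j])
  }
  vals + covariate_shift(covars, cfg$covariate_effects, z)
}

draw_covariates <- function(n, effects) {
  n_scan <- length(effects$scanner)
  data.frame(
    age = round(stats::rnorm(n, 65, 9), 1),
    sex = stats::rbinom(n, 1, 0.5),
    tiv = round(stats::rnorm(n, 1450, 130), 1),
    scanner = paste0("scanner_", sample.int(n_scan, n, replace = TRUE)),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic baseline cohort with known ground truth
#'
#' Controls are drawn entirely from the normal components (latent stage 0).
#' Each case receives a latent stage `k` from `stage_distribution`; exactly
#' the first `k` events of the ground-truth ordering are drawn from their
#' abnormal (lower-volume) components. Covariate effects are then added and
#' the covariates recorded in the table, so the downstream adjustment step
#' can remove them.
#'
#' @param config An [sim_config()] object.
#' @return A list with components
#'   \describe{
#'     \item{table}{biomarker table (data frame): `subject_id`, `visit`,
#'       `group`, `age`, `sex`, `tiv`, `scanner`, then one column per event.}
#'     \item{truth}{ground truth: `$stages` (data frame `subject_id`, `visit`,
#'       `true_stage`), `$true_sequence` (integer permutation), and
#'       `$abnormal_direction` (named, `"lower"` for every volume event).}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ebm_sim_config"))
  set.seed(config$seed)
  z <- config$n_events
  s <- if (identical(config$true_sequence, "random")) {
    sample.int(z)
  } else config$true_sequence
  n <- config$n_cases + config$n_controls
  group <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  stages <- integer(n)
  if (config$n_cases > 0) {
    stages[group == "case"] <- sample(0:z, config$n_cases, replace = TRUE,
                                      prob = config$stage_distribution)
  }
  covars <- draw_covariates(n, config$covariate_effects)
  vals <- draw_values(stages, config, s, covars)
  colnames(vals) <- config$roi_names
  ids <- sprintf("%s_%03d", group,
                 ave(seq_len(n), group, FUN = seq_along))
  table <- cbind(
    data.frame(subject_id = ids, visit = "baseline", group = group,
               stringsAsFactors = FALSE),
    covars, as.data.frame(vals))
  truth <- list(
    stages = data.frame(subject_id = ids, visit = "baseline",
                        true_stage = stages, stringsAsFactors = FALSE),
    true_sequence = s,
    abnormal_direction = stats::setNames(rep("lower", z), config$roi_names)
  )
  list(table = table, truth = truth)
}

#' Generate a follow-up visit for a synthetic cohort
#'
#' Each case's follow-up stage is `min(Z, baseline stage + increment)` with
#' the increment drawn from `config$followup_increment` (default: exactly one
#' additional event, emulating an average progression of one stage over 12
#' months). Controls stay at stage 0. Event values are re-drawn under the new
#' stage with the subject's baseline covariates, i.e. fresh measurement noise.
#'
#' @param table Baseline biomarker table from [generate_cohort()].
#' @param truth Matching ground truth.
#' @param config The [sim_config()] used at baseline.
#' @return A list `(table, truth)` as in [generate_cohort()], with
#'   `visit = "m12"`.
#' @export
generate_followup <- function(table, truth, config) {
  stopifnot(inherits(config, "ebm_sim_config"))
  if (is.null(truth$stages) || is.null(truth$true_sequence)) {
    stop("baseline ground truth is required to generate follow-up")
  }
  set.seed(derive_seed(config$seed, 2L))
  z <- config$n_events
  base_stage <- truth$stages$true_stage[match(table$subject_id,
                                              truth$stages$subject_id)]
  inc <- draw_increment(nrow(table), config$followup_increment)
  inc[table$group == "control"] <- 0L
  new_stage <- pmin(z, base_stage + inc)
  covars <- table[, c("age", "sex", "tiv", "scanner")]
  vals <- draw_values(new_stage, config, truth$true_sequence, covars)
  colnames(vals) <- config$roi_names
  fu <- table
  fu$visit <- "m12"
  fu[, config$roi_names] <- vals
  fu_truth <- truth
  fu_truth$stages <- data.frame(subject_id = table$subject_id, visit = "m12",
                                true_stage = new_stage,
                                stringsAsFactors = FALSE)
  list(table = fu, truth = fu_truth)
}

#' Write / read a biomarker table and its ground truth
#'
#' CSV round-trip for the table (one row per subject-visit) and, for the
#' ground truth, a sidecar CSV of per-visit stages plus a JSON file holding
#' the true sequence.
#'
#' @param cohort A `(table, truth)` list from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_biomarker_table`
#'   returns the table data frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$table, file.path(dir, "biomarkers.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth$stages, file.path(dir, "true_stages.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(true_sequence = cohort$truth$true_sequence,
         abnormal_direction = as.list(cohort$truth$abnormal_direction)),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param path CSV file path.
#' @export
read_biomarker_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
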