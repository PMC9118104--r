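# ebmseq — event-based modelling of biomarker abnormality sequences

`ebmseq` infers the order in which biomarkers become abnormal over the
course of a progressive disease, from purely cross-sectional data. It was
built for the setting of regional brain atrophy in a neurodegenerative
disease (one biomarker per brain region, measured by volumetric MRI, with
atrophy = abnormally low covariate-adjusted volume), but the machinery is
generic: any panel of markers that move monotonically from a normal to an
abnormal distribution fits the model. The intended users are biostatisticians
and imaging researchers who want a tested, scriptable event-based model
(EBM) pipeline — from raw subject-by-region tables to an event ordering with
uncertainty, per-subject disease stages, and the standard validation checks
— without patient data leaving their machine.

## The model

An *event* $E_i$ is the transition of biomarker $i$ from its normal to its
abnormal distribution. Given per-subject values $x_{ij}$ and mixture-derived
likelihoods $P(x_{ij}\mid E_i)$ and $P(x_{ij}\mid \neg E_i)$, the likelihood
of an ordering $S$ marginalizes each subject's unknown stage $k$ under a
uniform prior $P(k) = 1/(Z+1)$:

$$
P(X \mid S) = \prod_{j=1}^{N}\left[\sum_{k=0}^{Z} P(k)
\prod_{i=1}^{k} P\!\left(x_{S(i)j}\mid E_{S(i)}\right)
\prod_{i=k+1}^{Z} P\!\left(x_{S(i)j}\mid \neg E_{S(i)}\right)\right].
$$

The package provides:

* **Preprocessing** — left/right region combination, per-event linear
  covariate adjustment (age, sex, scanner, total intracranial volume) fitted
  on controls only, biomarker selection by Bonferroni-corrected Welch
  t-tests, and summary-table utilities (`welch_t_from_summary()`,
  `chi_square_2x2()`).
* **KDE mixture models** — per event, a two-component mixture of weighted
  kernel density estimates for the normal and abnormal distributions
  (`fit_kde_mixture()`), robust to skewed data, with a monotone posterior
  probability of abnormality.
* **Sequence inference** — the likelihood above (`sequence_log_likelihood()`),
  multiply initialized greedy ascent plus Metropolis MCMC over permutations
  (`fit_ebm()`), and positional variance diagrams (`positional_variance()`,
  `plot_pvd()`).
* **Staging** — maximum-likelihood stage per subject-visit
  (`stage_cohort()`), staging histograms, and a stage-threshold
  case/control classifier (`classify_by_stage()`).
* **Validation** — bootstrap and repeated stratified k-fold re-estimation of
  the sequence (`bootstrap_sequences()`, `repeated_stratified_kfold()`),
  longitudinal staging consistency (`longitudinal_consistency()`), and
  stage-outcome association (`stage_association()`).
* **Synthetic cohorts** — a generator with known ground-truth ordering and
  latent stages (`sim_config()`, `generate_cohort()`, `generate_followup()`)
  so the whole pipeline is testable without patient data.

## Worked example

```r
library(ebmseq)

cfg <- sim_config(n_cases = 150, n_controls = 100, n_events = 8,
                  abnormal_mean = 96, seed = 42)   # 4-SD separation
cohort <- generate_cohort(cfg)

pipeline <- run_ebm_pipeline(cohort$table, select = FALSE, n_init = 6,
                             n_samples = 5000, burn_in = 2000, seed = 42)
print(pipeline$ebm)
#> Event-based model fit
#>   events: 8
#>   ML sequence: roi_1 > roi_5 > roi_8 > roi_6 > roi_2 > roi_4 > roi_3 > roi_7
#>   log-likelihood: -2013.746
#>   MCMC samples: 5000 (acceptance 0.00)
```

The recovered ordering equals the generator's ground truth (Kendall
tau = 1), and staging separates the groups:

```r
round(staging_histogram(pipeline$staging)[, 1:5], 2)
#>         stage_0 stage_1 stage_2 stage_3 stage_4
#> case       0.14    0.10    0.13    0.05    0.12
#> control    0.99    0.01    0.00    0.00    0.00

pipeline$classification   # predict case iff stage >= 2
#> accuracy 0.86, sensitivity 0.76, specificity 1.00
```

99% of controls sit at stage 0 while cases spread across stages, as their
uniform latent stages dictate. The stage-2 classifier's sensitivity is
bounded by design here: about a fifth of the simulated cases are at latent
stage 0 or 1 and genuinely precede the threshold. The near-zero MCMC
acceptance rate reflects a sharply peaked ordering posterior at this
separation — the positional variance diagram (`plot_pvd()`) is
correspondingly diagonal.

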