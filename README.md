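# effortrl

Computational modelling of effort-based decision making on the Effort
Expenditure for Rewards Task (EEfRT), for researchers in computational
psychiatry and decision neuroscience who want a fully testable,
simulation-backed version of the standard analysis chain: competing choice
models, hierarchical Bayesian estimation, formal model comparison, and
classification of clinical groups from fitted parameters.

## The models

On each EEfRT trial a participant chooses between an easy option ($1.00,
effort cost 0.3) and a hard option ($1.24–$4.30, effort cost 1.0), with a
displayed 12/50/88% chance that a completed trial pays out. Three models of
the choice process are implemented:

- **Full subjective value**: `SV = R·P^h − kE`, with effort weight
  `k ∈ (0,10)` and probability weight `h ∈ (0,10)`;
- **Reward-only subjective value**: `SV = R − kE`;
- **Temporal-difference reinforcement learning (TDRL)**: Q-learning over
  three within-trial time points, `δᵢ = outcomeᵢ + γ·max Q(sᵢ₊₁,·) − Q(sᵢ,aᵢ)`
  and `Q ← Q + αδᵢ`, with learning rate `α ∈ (0,1)` and temporal discount
  `γ ∈ (0,1)`.

All models choose via a softmax policy with inverse temperature
`β ∈ (0,100)`. Trials where the participant failed to choose in time (forced
random assignment) update values but never enter a likelihood.

Estimation is hierarchical (individuals nested in cohorts, non-centered, on
logistic-transformed scales) by Hamiltonian Monte Carlo with analytic
gradients. Models are compared by bridge-sampling marginal likelihood and by
PSIS-LOO expected log predictive density. Per-subject MAP parameter vectors
feed a PCA → MANOVA → leave-one-out cross-validated LDA → DeLong ROC
classification stage. A synthetic-data module simulates complete studies from
known parameters so that every stage is verifiable without participant data.

## Worked example

Simulate a four-cohort study of TDRL agents, fit the TDRL model, and inspect
recovery of the cohort structure:

```r
library(effortrl)

study <- simulate_study(default_study_cohorts(), n_trials = 50, rng_seed = 1)
kept  <- filter_sessions(study$sessions)$kept

fit <- sample_posterior(hierarchical_spec("tdrl"), kept,
                        chains = 4, iter = 1000, warmup = 250, seed = 1)
print(fit)
#> Hierarchical Bayesian fit: tdrl
#>   99 subjects in 4 cohorts; 4 chains x 750 draws (+250 warmup)
#>   mean acceptance 0.95; max split-Rhat 1.214 (2 of 321 > 1.1)

maps <- map_table(fit)
head(maps, 3)
#>     subject_id   cohort     alpha     gamma     beta
#> 1 NeverTUD_001 NeverTUD 0.3327554 0.6029257 3.326167
#> 2 NeverTUD_002 NeverTUD 0.3182151 0.8791495 4.083104
#> 3 NeverTUD_003 NeverTUD 0.3329260 0.8694848 3.958739
```

One simulated subject chose the easy option on every free trial and was
excluded by the 50-trial/single-option filter (hence 99 of 100); at this
desk-scale sampler setting two of 321 parameters sit just above the 1.1
split-Rhat flag — rerun with more iterations (e.g. `iter = 2000, warmup =
750`) for a fully clean report.

The MAP table gives one `(α, γ, β)` vector per subject — learning rate,
temporal discount, and choice consistency. Pairwise cohort differences come
with 95% highest-density intervals:

```r
cohort_difference_report(fit, "gamma")[1:2, ]
#>   cohort_a   cohort_b parameter   mean_diff  hdi_lower hdi_upper excludes_zero credible
#> 1 NeverTUD  FormerTUD     gamma  0.18588616 -0.4010473 0.7524776         FALSE    FALSE
#> 2 NeverTUD CurrentTUD     gamma -0.01584406 -0.5874863 0.5884503         FALSE    FALSE
```

The generator puts these cohorts 0.25 apart in mean discounting, and the
posterior mean difference points that way, but at ~25 subjects per cohort
the 95% HDIs comfortably include zero — no credible cohort difference, which
mirrors how modest group effects look at this sample size. Model comparison
and classification chain on directly:

```r
loo <- psis_loo(pointwise_loglik(fit))
print(loo)
#> PSIS-LOO: elpd = -2836.7 (SE 28.1) over 4950 observations; 46 k > 0.7

cls <- classify_groups(as.matrix(maps[, c("alpha", "gamma", "beta")]),
                       maps$cohort)
round(100 * cls$pca$variance_fraction, 1)
#> [1] 82.7  9.6  7.6
```

`run_pipeline()` executes the whole chain (filter → fit all models → compare
→ MAP → PCA/MANOVA/LDA/ROC) from a single config list or JSON file and
writes CSV/JSON artifacts plus a manifest.

The bundled summary tables from a published four-cohort tobacco/opioid study
(`demo_age_summaries()`, `demo_sex_counts()`, `demo_race_counts()`,
`published_confusion_matrix()`) let the summary-statistics stage be checked
against printed values:

```r
anova_from_summaries(demo_age_summaries())$f   # 13.97 from rounded summaries
confusion_metrics(confusion = published_confusion_matrix())
#> Classification: accuracy 82.0%, kappa 0.76 (n = 100)
```

## A note on the vignette

`vignettes/effort-rl-methods.Rmd` documents the models and their
assumptions, the prior and sampler choices, what the synthetic-data
generator does and does not emulate, and the known identifiability limits of
the TDRL parameters at 50 trials.
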