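---
title: "Modelling effort-based choice: models, inference, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling effort-based choice: models, inference, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effortrl)
```

## The task and the scientific question

The Effort Expenditure for Rewards Task (EEfRT) presents a long series of
binary choices between a low-effort option worth $1.00 and a high-effort
option worth a variable $1.24–$4.30, each trial carrying a 12%, 50% or 88%
chance that a completed trial actually pays out. Because participants play as
many trials as they can inside a fixed time budget, analyses conventionally
use only the first 50 trials, and exclude participants who completed fewer
than 50 or who never chose one of the two options freely. `effortrl`
implements a complete, testable analysis of such choice data: competing
computational models of the choice process, hierarchical Bayesian estimation,
formal model comparison, and a downstream classification stage that asks
whether fitted parameters carry group (e.g. substance-use status)
information.

## The three choice models

Two *subjective value* (SV) models treat each trial independently. The full
SV model values an option as

$$\mathrm{SV} = R \cdot P^{h} - kE,$$

where $R$ is the option's dollar magnitude, $P$ the trial's win probability,
$E$ the effort cost (0.3 easy, 1.0 hard), $k \in (0,10)$ an effort-discount
weight and $h \in (0,10)$ a probability weight. The reward-only SV model
drops probability altogether: $\mathrm{SV} = R - kE$.

The *temporal-difference reinforcement learning* (TDRL) model instead learns
action values across trials. Each trial is unrolled into three time points
(options presented; action taken; outcome presented), and the chosen action's
chain of values $Q(s_1,a), Q(s_2^a), Q(s_3^a)$ is updated sequentially by the
TD rule

$$\delta_i = \text{outcome}_i + \gamma \max_a Q(s_{i+1}, a) - Q(s_i, a_i),
\qquad Q(s_i,a_i) \leftarrow Q(s_i,a_i) + \alpha \delta_i,$$

with outcome 0 at the first two points, the realized payoff at the third,
and a terminal successor value of 0. $\alpha \in (0,1)$ is the learning rate
and $\gamma \in (0,1)$ the within-trial temporal discount. All three models
choose through a softmax policy with inverse temperature
$\beta \in (0,100)$: $P(\text{choice}= \text{opt}_1) =
e^{\beta V_1} / (e^{\beta V_1} + e^{\beta V_2})$.

Design choices the model statement leaves open, and how they are resolved
here:

* **State space.** The TDRL agent learns values for generic easy/hard chains,
  not per-magnitude or per-probability states: the task description defines
  only the three within-trial time points, and the smallest structure
  faithful to that is two three-point action chains. Values persist across
  trials and never reset; chains terminate at the third time point (no
  inter-trial bridging).
* **Initialization.** Q-values start at 0 dollars, the uninformed choice;
  it also makes the $\alpha \to 0$ behavior exactly a coin flip, which the
  tests exploit.
* **Forced trials.** Trials where no choice was made in time are randomly
  assigned. They update Q-values (the agent experienced the outcome) but are
  excluded from every likelihood sum and from all predictive evaluation.
* **Units.** Outcomes are in dollars and magnitudes are stored at cent
  precision, matching the task display and avoiding float drift in payoffs.

## Hierarchical estimation

All subjects are fitted jointly: each bounded parameter is mapped to the real
line by a scaled logistic, individual values are non-centered deviations
($x_{s} = \mu_{c} + \sigma_{c} z_{s}$, $z_s \sim \mathcal N(0,1)$) from
cohort-level locations $\mu_c$ and scales $\sigma_c$, and the posterior is
explored by Hamiltonian Monte Carlo with analytic gradients (the TDRL
likelihood gradient is propagated forward through the Q recursion),
dual-averaging step-size adaptation and a diagonal mass matrix estimated
during warmup.

**Priors.** Cohort scales have half-Normal(1) priors and individual effects
are standard normal. Cohort locations have Normal($m_0$, 1.5) priors on the
unconstrained scale, with $m_0$ the image of plausible behavioral values
(learning rate and discount 0.5; effort and probability weights 1; inverse
temperature 5) rather than 0. A zero-centered prior looks innocuous but is
not: on the logistic scale of $(0,100)$ it puts the prior median inverse
temperature at 50 — an essentially deterministic chooser — and in recovery
simulations it biased every cohort's $\beta$ upward regardless of the
generating value. Centering at plausible values keeps the prior weakly
informative *in effect*, not just in form.

**Sampler scale.** The default configuration is 4 chains of 1,000 iterations
(250 warmup); the package's own validation runs use up to 4 × 2,000 (750
warmup), which fits a full 80-subject study in well under a minute. The
reference analysis scale of 10,000 iterations (2,000 warmup) per chain is
available by argument. Convergence is checked by split-$\widehat R$ with the
conventional 1.1 flag threshold.

**Point estimates.** Per-subject maximum a posteriori (MAP) values are modes
of the one-dimensional marginal posteriors on the constrained scale, located
by a Gaussian kernel density estimate with Silverman's bandwidth — the
classification stage consumes one scalar per parameter per subject, so
marginal modes (not a joint mode search) are the right object.

**Cohort differences.** Pairwise differences of cohort-level locations are
summarized by 95% highest-density intervals; a difference is flagged credible
when the HDI excludes 0 or an endpoint lies within 0.05 of 0. The 0.05 margin
is applied in parameter units (the natural reading alongside parameter HDIs);
reports carry the raw endpoints so the mass-based reading can be formed too.

## Model comparison

The log marginal likelihood is estimated by bridge sampling: a multivariate
normal proposal moment-matched to half of the posterior draws, the optimal
bridge iterated to relative tolerance $10^{-10}$, 10 repetitions on fresh
random halves, median and IQR reported. On a conjugate normal–normal toy
problem with an analytic marginal likelihood the estimator is accurate to
well under 0.05 log units at 4,000 draws.

Predictive accuracy uses PSIS-LOO: per-choice importance ratios smoothed by a
generalized Pareto fit (Zhang–Stephens estimator) to the largest 20% (or
$3\sqrt S$, whichever is smaller) of ratios, truncated at the raw maximum,
with tail shapes $\hat k > 0.7$ counted and warned about. ELPD is reported
pooled and per cohort; ranking uses the pooled value. Forced trials are
excluded as observations.

Models are ranked by median log evidence and, separately, by ELPD; the
comparison report flags any disagreement between the two criteria.

## The synthetic-data generator

No participant data ship with the package; every stage is exercised on
simulated studies.

* `default_study_cohorts()` emulates the four-cohort study design (23/22/26/29
  subjects) with TDRL agents whose parameters differ modestly across cohorts
  (learning rates 0.25–0.38, discounts 0.45–0.70, inverse temperatures
  2.0–5.0, within-cohort SDs 0.10/0.12/1.0). These values are a scientist's
  guess at plausible adult behavior, fixed once; the real study's parameters
  are not published.
* Completion probabilities default to 1 (the task reports no failure rates)
  and are configurable; the forced-trial fraction defaults to 0 with a flag
  to inject forced trials for testing the likelihood-masking rule.
* Hard magnitudes are uniform on $[1.24, 4.30]$ (rounded to cents) and
  probability levels uniform over the three values; the design matrix of the
  original task is not published, and uniform is the neutral choice.
* `recovery_study_cohorts()` is a separate benchmark for parameter-recovery
  studies: four *identically distributed*, broadly dispersed cohorts
  ($\alpha$ 0.45 ± 0.18, $\gamma$ 0.60 ± 0.15, $\beta$ 4 ± 2). Recovery
  studies must sample the range of interest — under the study-emulating
  defaults the true learning-rate spread (≈0.1) is smaller than the posterior
  uncertainty at 50 trials, so no estimator could rank individuals there.
  Equal cohort distributions avoid a second artifact: with distinct cohort
  means, hierarchical shrinkage makes ranking reflect cohort-mean geometry
  rather than estimation quality.

What the generator does **not** emulate: completion failures correlated with
effort or fatigue, reaction times, within-session drift, dropout, or any
demographic covariate structure. Passing recovery and model-selection tests
therefore demonstrates that the estimation and comparison machinery is
correct and well calibrated for the stated generative families — not that
real participants obey those families.

## Known limitations

* At 50 trials the three-point TD chain identifies its parameters weakly:
  the first-time-point values that drive choices are roughly
  $\gamma^2 \times$ expected payoff, so $\beta$ and $\gamma$ trade off, and
  the learning rate acts through a triple low-pass filter. MAP-versus-truth
  rank correlations around 0.5–0.6 at the recovery benchmark are the honest
  ceiling of this design, and values near that boundary move with the seed.
* Bridge-sampling accuracy depends on the normal proposal overlapping the
  posterior; for the hierarchical models the unconstrained posterior is
  close enough to Gaussian for stable estimates (IQR well under 1 log unit),
  but heavy funnels at very small cohort sizes would degrade it.
* The classification stage reports ROC from leave-one-out held-out
  posteriors (the conservative choice; full-fit posteriors are available by
  refitting), with LDA priors proportional to class frequencies and an
  equal-prior option.

## Validation strategy in the test suite

The package's tests follow a dual-route principle: every nontrivial
computation is checked against an independent oracle — brute-force trial
traces for session likelihoods, finite differences for gradients, closed-form
conjugate posteriors and marginal likelihoods for the sampler and bridge
estimator, exact leave-one-out for PSIS, eigendecomposition for PCA,
bootstrap for DeLong standard errors — plus published summary tables whose
statistics (chi-squares, ANOVA-from-summaries, confusion-matrix metrics)
reproduce exactly to printed precision. Stochastic checks (parameter
recovery, model-selection consistency, null calibrations) run at reduced but
stated problem sizes: 4 cohorts × 20 agents × 50 trials with 4 × 1,500–2,000
HMC iterations, chosen so a full validation pass completes on a laptop.
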