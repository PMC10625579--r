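---
title: "Valenced learning under volatility: models, statistics, and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valenced learning under volatility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`volatilearn` implements a complete analysis chain for a three-block
win/loss volatility task: schedule generation, Rescorla–Wagner agents with
valence- and block-specific learning rates, MAP/MCMC fitting with
integrated-BIC model comparison, switch/stay and learning-rate-adjustment
statistics, a pupillometry pipeline with cluster-based permutation
inference, and a synthetic-cohort generator that makes every stage testable
without access to participant data. This vignette records the scientific
and numerical decisions behind each stage.

## The task

Each of three 80-trial blocks presents two abstract shapes (A and B). On
every trial each shape can carry a win (+15p), a loss (−15p), both, or
neither; the win and loss locations are drawn independently, and the
contingencies of shape B are always the exact complement of shape A. The
monetary total starts at £1.50, and both shapes' outcomes are revealed
regardless of choice (full feedback), with the two outcomes shown
sequentially in counterbalanced order separated by a 2–6 s jittered delay.

A *volatile* outcome alternates between `P(outcome on A) = 0.85` and
`0.15` in epochs of 14–30 trials; a *stable* outcome stays at `0.5`.
Block 1 is volatile for both valences; blocks 2 and 3 each have exactly
one volatile valence (order counterbalanced across participants). Within
every block, the scheduled probability of each outcome averages exactly
50%, so neither shape is systematically favoured.

### Epoch construction

The run-length and balance rules interact tightly. With epochs in
`[14, 30]` that must alternate between the two levels and cover exactly 40
trials per level per block, each level must contribute exactly two epochs
(three 14-trial epochs already exceed 40 trials; one epoch of 40 exceeds
30). The generator therefore samples, for each level independently, a
composition of 40 trials into epochs each within the legal range (with
feasibility-truncated sequential draws), interleaves the two levels
starting from a random level, and does the same independently per valence.
This satisfies *every* stated constraint exactly — run lengths in
`[14, 30]`, levels restricted to `{0.15, 0.85}`, block mean exactly 0.5 —
rather than approximately via post-hoc trimming, which cannot in general
repair both the run-length and the balance constraint at once. The
construction generalises to other configurations and rejects infeasible
ones with a diagnostic. `validate_schedule()` re-checks all invariants on
any schedule, generated or ingested.

Outcome display order is counterbalanced by strict alternation within each
block; a random coin per trial would be counterbalanced only in
expectation.

## The agent family

Learnt values are outcome-probability estimates for shape A only
(`v_win_A`, `v_loss_A`), exploiting complementarity: shape B's estimates
are `1 − v_A`. After every trial both estimates are updated by the delta
rule

    v <- v + alpha * (outcome_on_A - v)

regardless of choice, because both outcomes are always shown. Values are
initialised at 0.5 and are *reset at every block boundary*: the stimulus
pair changes between blocks, so learnt values cannot carry over. Choice
follows a softmax on the net value difference; with complementary
contingencies the decision variable is `2(v_win_A − v_loss_A)`, so

    P(choose A) = logistic(beta * 2 * (v_win_A - v_loss_A) + bias)

The candidate roster crosses three factors — learning rates split by
valence, split by block, and an optional constant shape bias — with a
single inverse temperature throughout (six models,
`model_family()`). The fullest model (`winning_model_spec()`) carries six
learning rates (3 blocks × 2 valences), so both the block-1 rates and the
volatile-vs-stable contrast are estimable downstream. Utility weights on
wins and losses are fixed equal: the reported parameters are learning
rates, an inverse temperature, and (in some candidates) a bias only.

Because feedback is complete, the latent value trajectory is a
deterministic function of the realized outcome sequence — never of the
subject's choices. This makes the likelihood cheap (the trajectory is
computed once per parameter vector) and is asserted as a property test by
permuting choices.

## Fitting

Parameters are transformed to unconstrained scales — `logit(alpha)`,
`log(beta)`, identity for the bias — with independent normal priors:
`logit(alpha) ~ N(0, 2)` (near-uniform on the unit interval),
`log(beta) ~ N(log 5, 1)` (covering the range where choice is neither
random nor degenerate), `bias ~ N(0, 1)`. These are deliberately weak so
that 240 trials dominate the posterior; shrinkage of the
volatile-minus-stable contrast, the primary outcome, stays well below the
analysis tolerances (verified by parameter recovery).

* `fit_rl_map()` maximises log-likelihood + log-prior by BFGS from the
  prior mean plus jittered restarts (Nelder–Mead fallback). Per-trial
  choice probabilities are floored at 1e−10.
* `sample_rl_posterior()` runs a random-walk Metropolis chain on the
  transformed scale, adapting a global step size during burn-in towards a
  20–45% acceptance rate, and warns (diagnostic failure) below 5%.
* `integrated_bic()` follows the empirical-Bayes scheme: iterate MAP fits
  of all subjects under the current factorised-normal group prior with
  moment re-estimation of the prior (SDs floored at 0.1 against
  degeneracy), then score each model by
  `iBIC = −2 Σ_s log p(data_s) + k_prior log(N_choices)`, where `k_prior`
  counts group-level hyperparameters (a mean and an SD per parameter) and
  the sample-size term is the total number of choices across subjects.

### Marginal likelihoods

`marginal_loglik()` estimates `∫ L(data|θ) N(θ; μ, σ) dθ` by Monte Carlo.
A plain average of the likelihood over prior draws is the textbook
estimator here, but with seven parameters and realistic between-subject
spread its weights are tail-dominated: subjects whose likelihood peak sits
in the group prior's tail give estimates with a standard deviation of 1–2
log units even at 16,000 draws, which would swamp convergence checks and
add avoidable noise to model comparison. The package therefore uses
defensive importance sampling: half the draws come from the prior, half
from a Laplace approximation centred on the subject's MAP under that
prior (diagonal curvature, inflated 1.5×, capped at the prior SD). The
mixture proposal dominates the prior, so weights are bounded and the
estimator — still unbiased for the same integral — reaches a standard
deviation of about 0.1 log units at 1,000 draws and matches 10,000-point
grid quadrature to well under 0.5 log units on a one-parameter toy.

## Behavioural statistics

* **Non-learner exclusion**: participants whose final total is at or below
  the £1.50 they started with are removed.
* **Switch/stay**: for each valence, trials where the chosen shape carried
  that outcome; a stay repeats the choice on the next within-block trial
  (the last trial of each block has no successor, and stays are never
  counted across block boundaries because the stimuli change). The
  volatile cell pools block 1 with the valence's volatile block.
  Proportions receive an add-half continuity correction
  `(k + 0.5)/(n + 1)` before the logit transform so that all-stay cells
  stay finite; the uncorrected proportion is also reported.
* **Adjustment**: per valence, `alpha_volatile` is the *mean* of the
  block-1 rate and the valence-volatile block's rate (both blocks are
  volatile for that valence; averaging is symmetric and keeps units) and
  `alpha_stable` is the remaining block's rate; the adjustment is their
  difference. One-sample t-tests stack the two valence adjustments per
  subject (n = 2 × subjects), consistent with the degrees of freedom of a
  25-person group being 49.
* **Mixed ANOVA**: type-III sums of squares with sum-to-zero contrasts via
  a multivariate linear model, full factorial decomposition of the
  declared between- (group, order) and within- (volatility, valence)
  factors, listwise deletion of subjects with missing cells, and a
  Greenhouse–Geisser correction per within term. Two-level within factors
  are spherical by construction (`epsilon = 1`); effects with zero sum of
  squares are reported as `F = 0, p = 1` rather than 0/0. Welch t-tests
  (unequal variances) serve as post-hocs; no multiple-comparison
  correction is applied anywhere, matching the analysis design.
* **Fisher r-to-z**: `z_i = atanh(r_i)`, statistic
  `(z_1 − z_2)/sqrt(1/(n_1−3) + 1/(n_2−3))`, two-sided normal p. From the
  printed rounded inputs, the RA-vs-HC comparison reproduces exactly
  (z = 2.56, p = 0.011) while the RA-vs-EA comparison recomputes to 1.64
  rather than the printed 1.71, and the EA one-sample t recomputes to 5.26
  rather than 5.29; the package documents the recomputed values rather
  than tuning to the printed ones.

## Pupillometry

Preprocessing rules are configuration-exposed (`pupil_config()`) because
the original filter settings are not fully specified; defaults follow
standard practice:

* invalid or non-positive samples are padded by ±100 ms and linearly
  interpolated from flanking valid samples (edge gaps take the nearest
  value); optional moving-average smoothing is off by default;
* epochs span −1 s to +6 s around each outcome onset, resampled to a 50 Hz
  working rate (351 samples), baseline-corrected by subtracting the mean
  of the pre-onset second (subtraction, not division, so the pipeline is
  exactly invariant to constant diameter shifts);
* epochs with more than 50% interpolated samples are dropped, and
  participants with more than 50% of task trials above that threshold are
  removed; the two rules commute because the participant rule is evaluated
  on the full epoch set;
* per subject and valence × volatility cell, the condition series is the
  mean receipt epoch minus the mean non-receipt epoch, with block-1 epochs
  pooled into the volatile cells; the per-valence subtraction series is
  volatile minus stable.

The cluster test takes one averaged subtraction series per subject per
valence. At each timepoint it evaluates the split-plot factorial of group
(between) and valence (within): because there is exactly one series per
subject and valence, a random valence slope per subject reduces to the
subject-paired valence difference, so the pointwise statistics come from
the subject means (group effect) and the paired win–loss differences
(valence and interaction effects) — verified against `car::Anova` at
single timepoints. With unequal group sizes the valence main effect uses
the observation-weighted grand mean; under permutation this choice affects
only the shape, not the validity, of the null distribution. Clusters are
maximal runs of pointwise `p < 0.05`; the cluster mass is the summed F;
the null is the maximal cluster mass over label permutations (group labels
shuffled across subjects; valence labels sign-flipped within subject), and
`p = (1 + #{null ≥ observed}) / (n_perm + 1)`, so the smallest attainable
p is `1/(n_perm + 1)`. Window post-hocs average each subject's series over
a window and permute group labels on the scalar; the pupil–behaviour
analysis correlates the reward subtraction-series window mean with the
reward learning-rate adjustment within each group (groups below n = 4 are
skipped) and compares groups with the Fisher transform.

## The synthetic cohort

The generator's defaults encode the study conditions: groups RA/EA/HC of
25/25/32 subjects; per-valence adjustments drawn from
N(0.191, 0.169), N(0.134, 0.180), N(0.107, 0.195) respectively; stable
learning rates near 0.2 (truncated normal, SD 0.06); volatile rate =
stable + adjustment, truncated to `[0.02, 0.98]` (a warning fires if
truncation moves the realised mean adjustment by more than 0.05); block-1
rates equal the volatile rates because block 1 is volatile for both
valences (the fitted model still estimates all six rates freely).
Inverse temperatures are log-normal with median 6 and `sdlog` 0.4 — a
calibration, not a reported fact: it yields stay probabilities spanning
roughly 0.6–0.9, bracketing the printed descriptives.

Pupil traces are a base diameter plus a slow spline drift, white
measurement noise, Poisson blinks (zeroed and invalid-flagged), and a
gamma-shaped impulse response (shape 3, scale 0.5 s, peaking 1 s
post-event) at every outcome onset. Receipt amplitudes are set per
valence × volatility cell with subject-level variability; the RA preset
expresses the reported pattern (greater dilation to stable rewards,
reduced dilation to stable losses, no group differences in volatile
cells), which induces a group × valence interaction on the subtraction
series. The RA preset also adds `0.72 × adjustment_win` to the
volatile-reward amplitude; with the default amplitude SD (0.15) and
adjustment SD (0.169) this places the expected within-RA correlation near
0.5.

The generator emulates the statistical structure the analyses assume — it
does not emulate reaction times, questionnaire scores, luminance effects,
gaze position, or non-stationary measurement noise. Tests passing on this
cohort therefore validate the pipeline's logic and calibration, not claims
about real pupillometry data.

## Numerical choices and problem sizes

* Likelihood floor 1e−10 per trial; learning-rate truncation
  `[0.02, 0.98]` in the generator; empirical-Bayes prior SD floor 0.1.
* Stage seeds derive deterministically from a master seed plus a stage
  label (`derive_seed()`), all below 2³¹.
* The test-suite and acceptance runs use scaled problem sizes chosen to
  keep each property measurably calibrated on a desktop: 1,000 schedule
  seeds for structural invariants; 100-replicate MAP identifiability and
  50-replicate posterior-mean checks; 500 null simulations for ANOVA
  type-I error and 300 for cluster family-wise error (each at nominal
  5% ± 3 points); 20 replicate 30-subject cohorts for model recovery;
  recovery of the printed RA/HC adjustment means with 24/30 subjects over
  3–5 replicate cohorts; 50 replicate RA+HC cohorts for the directional
  contrast; 12–20 replicate pupil cohorts (16–24 subjects per group at a
  60 Hz native rate) for end-to-end cluster detection and coupling.

## Known limitations

* The model family is the main-text roster (three factors); the original
  supplementary roster may differ, and no volatility-tracking (e.g.
  hierarchical Bayesian filter) learner is included by design.
* MCMC is a single-chain adaptive random-walk sampler — adequate for ≤ 8
  parameters, not a general-purpose replacement for gradient-based
  samplers.
* The pointwise cluster model assumes one averaged series per subject and
  valence; trial-level mixed models at the native sampling rate are out of
  scope.
* Real eye-tracker artefacts (partial blinks, pupil foreshortening,
  luminance responses) are richer than the generator's blink/noise model.
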