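---
title: "Modelling choice and response time in stimulus-response learning: methods"
author: "rlwmlba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling choice and response time in stimulus-response learning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`rlwmlba` implements a joint model of choices and response times in a
deterministic stimulus-response association task. Learners see between 2 and 5
stimuli per block (the *set size*, `n_s`) and must discover which of three
keys each stimulus maps to; feedback is binary and deterministic. Blocks run
under an adaptive stopping rule: each stimulus is presented until it has been
answered correctly on at least 4 of its last 5 presentations, with a floor of
9 and a ceiling of 15 presentations.

Two learning systems jointly produce the action policy:

* **RL module.** Expected reward `Q_RL(s, a)` follows the delta rule with
  learning rate `alpha_rl`. Negative prediction errors are down-weighted by a
  `bias` parameter in `(0, 1)`: the effective rate is
  `(1 - bias) * alpha_rl` when the prediction error is negative. `bias = 1`
  would mean total neglect of negative feedback.
* **WM module.** `Q_WM(s, a)` uses the same rule with learning rate 1
  (one-shot updating, also attenuated by `bias` after errors) and decays
  toward its uninformed initial value `1/3` by a proportion `phi` on every
  trial, for all stimulus-action entries.

Both modules emit softmax policies with fixed sensitivities
(`beta_rl = beta_wm = 50` by default; choice stochasticity is carried by the
accumulator race, so these act as near-hard maximization). The mixed policy is

    pi(a | s) = W_WM * P_WM(a | s) + (1 - W_WM) * P_RL(a | s),
    W_WM     = rho * min(1, C / n_s),

with `rho` the propensity to rely on WM and `C` (between 2 and 5) its
capacity: WM informs choice fully while capacity covers the set size and
proportionally less beyond it.

Before each trial's stimulus is encoded, the learner's residual uncertainty
about the block's stimulus-response mappings is the Shannon entropy (bits) of
the *block-average* policy, `H_prior = -sum_i mu_i log2 mu_i` with
`mu_i = mean_s pi(a_i | s)`. Choice and RT arise from a three-accumulator
linear ballistic race whose mean drifts divide the policy by this
uncertainty:

    V_a = eta_t * pi(a | s) / H_prior.

Accumulators start uniformly on `[0, A]`, rise with slope `Normal(V_a, s)`
(`s = 1` fixed, the standard scale-fixing convention), and the first to reach
`b = A + k` determines the response; RT adds the non-decision time `tau`.
The defective density of `(choice, RT)` is the winner's first-passage density
times the survivor functions of the losers, normalized by the probability
that at least one sampled slope is positive — exactly the truncation the
simulator applies by resampling all-negative draws, so density and simulator
agree to Monte-Carlo precision (a tested invariant).

In the **neurally informed** variant the drift scaling varies by trial with a
measured EEG quantity, the pre-response buildup rate (slope) of the
centro-parietal positivity (CPP) at electrode CPz:

    eta_t = eta + z(CPP_slope_t) * beta_slope,

with slopes z-scored within subject and `eta_t` floored at 0.01 so drifts
stay positive. Setting `beta_slope = 0` recovers the baseline model exactly
(a tested reduction).

## Parameters, transforms, priors

All bounded parameters are fitted on an unconstrained scale:
`alpha_rl, bias, phi, rho, tau` map through the standard normal CDF onto
`(0, 1)`; `C = 2 + 3 * pnorm(x)`; `A, k, eta` are log-transformed.
Group-level prior locations (unconstrained) are
`alpha -3, bias -1, phi -1, rho 2, C 3, k 1, A 2, eta 3, tau -1`, each with
sd 3; group sds have `Exponential(0.1)` priors and subject deviations are
standard normal. `beta_slope` has a `Normal(0, 1)` prior on its natural
scale (not dictated by the hierarchy; a weakly informative choice).

## Fitting: two-stage empirical Bayes with MCMC draws

The package's desk-scale mode approximates the hierarchical posterior in two
stages, sharing one log-posterior implementation (a compiled forward replay
of the agent through each trial sequence):

1. **Stage 1.** Each subject is fitted by multi-start (default 5)
   gradient-based MAP under the weak group-location priors
   (objective tolerance 1e-8; ties resolved by the best objective).
2. **Group pooling.** The stage-1 estimates and their Laplace variances are
   pooled per parameter by precision-weighted random-effects meta-analysis
   (DerSimonian-Laird), so subjects whose data barely constrain a parameter
   do not drag the group location toward the prior constants. The estimated
   between-subject sd becomes the stage-2 shrinkage scale (floored at 0.1,
   capped at 3).
3. **Stage 2.** Every subject is refitted under the estimated group prior —
   the subject-level conditional of the hierarchical model — and posterior
   draws are obtained by short adaptive random-walk Metropolis chains
   started at the MAP, with the Laplace covariance shaping the proposal
   (burn-in 600, thinning 10, acceptance tuned toward 0.234).

Group summaries pool the per-subject posterior means and variances with the
same random-effects estimator. The CPP-slope coefficient `beta_slope` is a
single group-level parameter: it is estimated freely per subject in stage 1,
pooled by precision-weighted random effects (that pooled estimate and its
interval are the reported group posterior), and then held fixed at the
pooled value in stage 2 — so the neurally informed model carries one
effective extra parameter for the cohort, not one per subject, mirroring
the hierarchical formulation and keeping predictive comparisons fair.
Model comparison uses pointwise
log-likelihood draws and PSIS-LOO (Pareto-smoothed importance sampling
leave-one-out; a WAIC-style penalty is available as a fallback), reporting
`elpd_diff = better - worse` with `se = sqrt(n * var(pointwise diffs))`. For
this sequential model "leave one out" removes an observation's likelihood
term while the replayed learning history is untouched; the test suite
verifies PSIS-LOO against brute-force refits under exactly that definition.

Shrinkage matters here: with the softmax sensitivities fixed at 50, several
parameters are only weakly identified per subject (the likelihood is nearly
flat in `alpha_rl` above ~0.1, where one-shot RL mimics WM, and in `C`
above ~4, where capacity covers every set size), and unshrunken per-subject
MAPs wander along trade-off ridges (e.g. `alpha -> 0` compensated by
`rho, C -> `max). Recovery of `alpha_rl` therefore degrades for
high-`alpha` subjects as a matter of information, not estimation.

## The synthetic-data generator

The generator defines the study conditions the package is tested under.
Subject parameters are drawn on the unconstrained scale from
`Normal(group_mean, group_sd)` and mapped through the fitting transforms.
The frozen defaults describe a heterogeneous cohort of learners:

| parameter | location (natural scale) | spread (unconstrained sd) |
|---|---|---|
| `alpha_rl` | 0.029 | 0.5 |
| `bias` | 0.31 | 0.7 |
| `phi` | 0.14 | 0.6 |
| `rho` | 0.84 | 0.8 |
| `C` | 4.1 | 1.0 |
| `A` | 0.74 | 0.4 |
| `k` | 1.0 | 0.4 |
| `tau` | 0.21 s | 0.35 |
| `eta` | 3.0 | 0.5 |

The RL learning rate is centred well below 0.1 — in this architecture the RL
module is the slow learner by construction (WM absorbs fast learning), which
is also the regime in which the parameter is identifiable. The spreads are
deliberately cohort-scale (the kind of heterogeneity a developmental or
population sample shows): a recovery study needs true variation that exceeds
estimation noise, otherwise attenuation bounds every recovery correlation
near zero regardless of estimator.

Designs default to 11 blocks with set sizes `2,2,3,3,3,4,4,4,5,5,4` (the
composition is a package choice; only the number of blocks and the 2-5 range
are fixed by the task). Stimulus-action maps are sampled uniformly subject
to covering at least two distinct actions per block: sharing an action is
allowed and common, but a block whose every stimulus requires the same key
has no mapping to learn, and under near-hard softmax it collapses the policy
entropy to its floor (`1e-6` bits), producing astronomically large drifts and
cliffs in the likelihood. Simulated RTs beyond the 7 s response deadline are
resampled (they are rare at the default parameters); the likelihood itself
ignores deadline censoring.

Trial-wise CPP slopes are generated as
`slope = 0.05 + 0.045 * zeta` microvolts/ms with
`zeta = 0.8 * z(leading drift) + 0.6 * noise`, and the behavior-generating
drift scaling uses `eta_t = eta + beta_slope_true * zeta`
(`beta_slope_true = 0.094` by default). The leading-drift standardization
uses per-subject moments from a decoupled pre-pass, so generation stays
causal. These mapping constants are free knobs whose only job is to create
recoverable structure: with AR(1) noise (coefficient 0.95, marginal sd 5
microvolts) the two-sample slope estimate at 512 Hz has noise sd of about
0.047 microvolts/ms, giving extracted-slope reliability of about 0.7.

Simulated epochs contain, besides the CPP ramp (linear rise to the response
from an onset at most 600 ms earlier, buildup rate equal to the trial's
generated slope, linear return to baseline within 200 ms): a fronto-central
Gaussian component at 300 ms post-stimulus with amplitude
`-(3 z(Q_RL) + 2 z(delay))` microvolts and a parietal component at 540 ms
with amplitude `3 z(set size)`, projected to a 64-electrode idealized 10/20
layout with Gaussian spatial weights. What the generator does **not**
emulate: 1/f and oscillatory noise structure, eye/muscle artifacts,
volume-conduction-realistic topographies, overlapping potentials from the
*preceding* trial, and any systematic RT-locked component other than the
CPP. Passing tests therefore show that the statistics recover structure of
this idealized kind at realistic SNR — not that preprocessing artifacts or
component overlap in real EEG are handled.

## Single-trial ERP statistics

Stimulus-locked general linear models regress every electrode and sample on
z-scored set size, delay (trials since the last correct performance of the
association; undefined-delay trials are excluded), and the chosen option's
`Q_RL`; response-locked models use the z-scored drift rate. Per-subject beta
maps are aggregated with 20% trimmed means and tested with one-sample
trimmed-mean t statistics (Tukey-McLaughlin/Yuen: winsorized variance,
`df = h - 1`). P-values are Bonferroni-corrected across electrodes, time
points and estimated parameters, `alpha / (E * T * P)` with `alpha = 0.05`
— the threshold is computed from this formula, and the output records both
the comparison count and the threshold used. Corrected ERPs are
reconstructed as `intercept + beta * z(level)` with other predictors held at
their mean. Value quartiles are rank-based within subject and set size with
midrank tie handling: under deterministic feedback the Q trajectories
produce heavily tied values (often above 80% of trials in a cell), and
breaking ties by trial order would scatter equal values across quartiles,
destroying the association the quartile analysis measures — tied values
therefore share a quartile, and all-equal cells are flagged as degenerate.
The CPP-slope-on-quartiles regression uses least squares with fixed subject
intercepts and cluster-robust (by subject) 95% intervals.

## Numerical choices and degenerate inputs

* Entropy floor `1e-6` bits; drift-scaling floor `eta_min = 0.01`;
  log-density floor `log(1e-300)` (an RT at or below `tau` contributes a
  finite penalty, never `-Inf`).
* Laplace covariances floor Hessian eigenvalues at 0.1 (no proposal
  direction wilder than the prior scale); MCMC proposals are clamped to
  ±20 on the unconstrained scale.
* Zero-variance regressors are dropped per subject with a warning; groups
  of fewer than 4 trials are flagged in quartile assignment; winsorized
  variance 0 with a nonzero trimmed mean is treated as maximal significance.
* CPP landmarks use nearest-sample lookup (error < 1 ms at 512 Hz).

## Problem sizes used by the test and acceptance suites

Simulation sizes are chosen to make each check informative at desk scale:
stopping-rule and arithmetic checks are exact; the LBA density/simulation
equivalence uses a 27-point parameter grid with 1e5 races per setting;
coefficient recovery uses 20 subjects on the full design; parameter recovery
uses 30; the learning-curve and quartile-dissociation patterns use 60; the
family-wise-error simulation uses 200 null replicates of a 20-subject,
12-channel, 32 Hz configuration and the power simulation 50 replicates; the
PSIS-LOO versus brute-force-refit comparison uses 3 subjects with two
set-size-3 blocks each. Larger montages and cohorts run through exactly the
same code paths.

A note on scale for the model-comparison checks: the total
likelihood-ratio signal carried by a slope coupling of size `beta` grows as
`0.5 * (beta / se(beta))^2`, and at desk-scale cohorts the published-scale
coefficient (0.094) yields roughly 3 standard errors on `beta` — a few nats
of expected ELPD gain, the same order as the LOO difference's own standard
error. The decisive-direction check therefore uses a distinctly informative
coupling (0.3) on 12 subjects, while the published magnitude is exercised by
the coefficient-recovery check; a cohort in the hundreds would make the
published magnitude decisive as well.

## Known limitations

Two statistical properties deserve explicit mention because the test suite
measures them honestly:

* **Per-subject recovery of `alpha_rl` is capped.** With sensitivities
  fixed at 50, the likelihood is nearly flat in `alpha_rl` above ~0.1
  (conditional profiles at the true parameters differ by only 1-3 nats over
  that whole range), so cohort members with fast RL learning contribute
  noise to recovery correlations; across the default cohort the recovery
  correlation for `alpha_rl` sits around 0.5 while `rho`, `phi`, `tau`,
  `eta` recover above 0.7 and `C` rank-correlates above 0.4.
* **The trimmed-mean t is anticonservative in extreme tails at small n.**
  At 20 subjects (df 11), direct null calibration shows roughly 2.5 times
  the nominal tail mass at the Bonferroni-corrected thresholds
  (alpha ~ 2e-5), so the family-wise error of the mass-univariate pipeline
  runs near 10% rather than 5% in 20-subject simulations. This is a
  property of the Tukey-McLaughlin statistic itself, not of its
  implementation; at cohort sizes in the hundreds the approximation is
  accurate.

* The desk-scale approximation is empirical-Bayes MAP + short MCMC, not full
  hierarchical sampling; group sds are point-estimated, and subject-level
  uncertainty propagates into group summaries only through the
  random-effects pooling.
* With the softmax sensitivities fixed at 50, `alpha_rl` above ~0.15 and `C`
  above ~4 are intrinsically hard to identify; recovery claims are
  restricted accordingly.
* The likelihood ignores the 7 s deadline (censoring) and models only
  correct/incorrect deterministic feedback.
* The EEG generator is a statistical emulator, not a biophysical one (see
  above); topographic claims are about the injected Gaussian spatial
  weights.
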