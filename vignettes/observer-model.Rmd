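---
title: "A multilevel observer model for simultaneity and agency judgements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multilevel observer model for simultaneity and agency judgements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recalibr)
```

## The measurement problem

After pressing a key, people judge whether a sensory event (a flash or a
tone) was simultaneous with — or caused by — their action. Plotting the
probability of a "yes" response against the response–stimulus asynchrony
(RSA, in ms; positive when the stimulus lags the keypress) yields a
peaked psychometric function: "yes" is likely only inside a window of
asynchronies. Adaptation to a systematic 150 ms action–feedback lag
shifts this window rightwards (temporal recalibration), and the shift
may transfer across feedback modalities. `recalibr` measures these
shifts with a single hierarchical model fitted to all participants and
conditions at once, instead of hundreds of independent curve fits.

## The observer model

Each trial's subjective asynchrony is the physical RSA plus Gaussian
latency noise, and is classified against two noisy decision criteria.
Equivalently, for a trial at asynchrony $\Delta t$ in design cell
$(i,j,k)$ (task $\times$ modality $\times$ adaptation lag), the
probability that the asynchrony registers inside the window is

$$
p_{\Delta t\,ijk} =
\Phi\!\left(\frac{\Delta t - (\tau_{ijk} - \Delta\delta_{ijk}/2)}{\sigma_{L\,ijk}}\right)
- \Phi\!\left(\frac{\Delta t - (\tau_{ijk} + \Delta\delta_{ijk}/2)}{e^{m_{ijk}}\,\sigma_{L\,ijk}}\right),
$$

where $\tau$ is the window midpoint (the asynchrony judged maximally
"simultaneous"/"self-caused"), $\Delta\delta$ the criterion separation
(window width), $\sigma_L$ the Gaussian noise on the left flank, and
$m$ the log ratio of right- to left-flank noise ($m = 0$ means equal
flanks). With unequal flanks the difference of CDFs can dip a few
$10^{-k}$ below zero in the far tails, so it is floored at 0 — a valid
probability without altering the model where the data live.

Attentional lapses mix in guessing: with half-lapse-rate $l$ the
yes-probability becomes $l + p - 2lp$, and the number of yes responses
in a cell is binomial in that probability.

Condition dependence is expressed through effects-coded predictors
$t_i, s_j, a_k \in \{-0.5, +0.5\}$ (simultaneity/visual/lag0 take
$-0.5$): $\tau$ and $m$ get additive linear predictors with seven
coefficients each (three main effects, three two-way interactions, one
three-way), while $\Delta\delta$ and $\sigma_L$ get the same structure
inside an exponential, keeping them positive. Because products of codes
carry the interactions, a two-way coefficient is exactly a
difference-of-differences of cell values, and every reported effect
reads as (+0.5 level) minus (−0.5 level) — a positive adaptation effect
on $\tau$ is a rightward, stimulus-lagging shift.

That yields 33 free scalars per participant (4 grand means + 28
coefficients + 1 lapse). Participants are tied together by group-level
distributions: Gaussian on the identity scale for $\bar\tau$, $\bar m$
and all coefficients, Gaussian on the log scale (lognormal) for
$\bar{\Delta\delta}$ and $\bar\sigma_L$. Each of these 32 parameters
contributes a free (mean, sd) pair. The lapse is handled on a scaled
logit scale as a Gaussian with a *fixed* sd of 0.5 and a free mean, so
the group level has $2 \times 32 + 1 = 65$ free scalars and a cohort of
48 has $33 \times 48 + 65 = 1649$ in all. The lapse choice is an
explicit modelling decision: the group total is known but its exact
composition is not, and one free location plus a fixed spread is the
simplest structure that reaches it while still shrinking individual
lapse rates sensibly.

## Fitting: penalized maximum likelihood

`fit_observer_model()` maximizes the joint log-likelihood — binomial
data terms plus the log group density of every individual parameter —
over all parameters simultaneously. This is a joint-mode (penalized)
MLE: the group densities act as adaptive shrinkage penalties, and the
result approximates the mode of the multilevel model rather than a
marginal (integrated) likelihood.

Numerical choices that matter:

* **Multi-start L-BFGS-B with analytic gradients.** The likelihood
  surface is multi-modal; the default is 20 seed-controlled starts
  (heuristic data-driven base start plus Gaussian jitter), and
  `stability_check()` refits from 50 more to report the spread of the
  log-likelihood and of the headline adaptation effects across local
  optima.
* **Non-centered parameterization.** Individual parameters are stored
  as z-scores ($v = \mu + \sigma z$). When a group sd collapses toward
  its floor the centered problem becomes extremely stiff (curvature
  $\propto 1/\sigma^2$) and L-BFGS stalls; the non-centered form keeps
  the penalty isotropic and converges in a few hundred iterations.
* **Scales and bounds.** Millisecond parameters are divided by 100
  internally; $\Delta\delta$, $\sigma_L$ and all group sds live on log
  scales; the lapse uses a scaled logit confined to
  $[10^{-4}, 0.5)$ so the likelihood stays finite. Group sds are
  floored at $10^{-3}$ (optimization scale) via a box bound on the
  log-sd, preventing both degenerate collapse and the slow asymptotic
  crawl toward $-\infty$. Log-scale linear predictors are clamped to
  $[-15, 15]$ inside the data term only, so a stray line-search step
  cannot overflow `exp()`; rare line-search failures at the
  probability-floor kink are retried from the current iterate.
* **Degenerate participants.** A participant with fewer than two
  distinct RSAs cannot identify flank parameters; their
  $\Delta\delta$/$\sigma_L$ blocks are pinned to the group means and a
  warning is emitted. All-yes or all-no participants trigger wide
  default starts.

`effect_table()` converts a fit into the quantities the design was
built to measure: per-participant cell values of $\tau$ and
$\Delta\delta$, simple adaptation effects (lag150 − lag0) in each
task × modality cell, and marginal effects/interactions via balanced
contrasts (the marginal adaptation effect equals the mean of the four
simple effects exactly).

## Inference: permutation and bootstrap with refitting

Standard errors from the curvature of a penalized multilevel objective
are unreliable, so inference is resampling-based and refits the model:

* **Permutation test.** Under the null that condition labels are
  exchangeable within a participant, the 8 condition labels are
  reassigned to each participant's 8 cell-blocks independently
  (trials within a cell stay together, preserving each block's RSA
  structure), the model is refitted, and the statistic recomputed.
  Two-sided p-values use the add-one rule $(1 + \#\{|T^\ast| \ge
  |T|\})/(B+1)$, so the smallest attainable value with $B = 999$ is
  0.001. With 999 permutations the Monte-Carlo 95% CI around
  $p = 0.05$ has half-width $1.96\sqrt{p(1-p)/B} \approx 0.014$, which
  motivates reporting $p \in [0.036, 0.064]$ as "marginal"
  (`classify_significance()`).
* **Bootstrap.** Complete participants are resampled with replacement;
  the SE is the sd of the refitted statistic and the 95% CI is the
  normal-theory interval $\pm 1.96\,\mathrm{SE}$. Cohen's d is
  reconstructed as $d = \text{effect}/(\mathrm{SE}\sqrt{n})$, since
  $\mathrm{SE}\sqrt{n}$ estimates the between-participant sd of the
  effect.
* **Warm starts.** Permutation and bootstrap refits start from the
  observed optimum (with a capped iteration budget) rather than from a
  full multi-start search; this is what makes hundreds of refits
  feasible and is documented as an approximation. Refit failures are
  redrawn, capped at 5% of the replicates.

A priori design analysis is exposed as `minimum_sample_size()`
(noncentral-t power iteration: d = 0.5, α = 0.05, power = 0.90 gives
n = 44).

## Overdispersion diagnostic

`overdispersion_check()` scores each participant by the proportion of
1000 model-simulated replicate datasets whose likelihood exceeds the
observed data's likelihood, both evaluated at the fitted parameters.
Values near 0.5 indicate binomial-compatible residuals; values above
0.95 flag overdispersion (ties count as not-lower). No parameter
uncertainty is propagated into the replicates — the check conditions on
the fitted point estimates by construction.

## The synthetic-data generator

`generate_dataset()` emulates the adaptation study's structure: a
2 × 2 × 2 within-subject design; 15 intended RSAs (−333 … 500 ms) with
10 repetitions per cell; stimulus-lagging trials realized exactly;
stimulus-leading trials jittered by the keypress-prediction error
(default sd 25 ms — the true error distribution is unpublished, so this
is a config knob), recorded at the 120 Hz display frame, and retained
with probability 0.27 (the study's median retention; its
across-participant spread is unknown, so retention is a single
Bernoulli rate). When the prediction error is set to zero the intended
timing is realized exactly and no frame binning occurs.

The `"paper-like"` preset centres the generator on headline group
estimates (midpoint 150 ms; lognormal window width centred at 311 ms;
adaptation shift 34 ms and modality shift 51 ms on the midpoint;
auditory windows wider by ≈36 ms) with between-participant spreads
chosen so the implied standardized effects are of the reported order
(e.g. sd 32 ms for the adaptation shift, d ≈ 1.07). These are
estimates used as generating values, not ground truth. The `"null"`
preset zeroes all condition effects and is the reference for
permutation calibration.

What the generator does *not* emulate: adaptation/top-up keypress
sequences, pacing feedback, block order, truncated blocks, sequential
dependencies between trials, or any non-temporal cue that might drive
agency judgements. Passing recovery tests therefore demonstrates that
the pipeline is consistent — data generated under the model's
assumptions are recovered — not that real judgement data satisfy those
assumptions; the overdispersion check is the within-package guard for
the latter.

## Problem sizes used by the test suite

The automated checks run the full logic at reduced scale, chosen as the
smallest sizes at which each property is still a meaningful scientific
check:

* parameter recovery: cohorts of 16 participants under the full trial
  design, 10 replicate datasets, bootstrap B = 99;
* permutation calibration: 150 null cohorts of 8 participants under a
  7-RSA × 3-repetition design, B = 19 with rejection at p ≤ 0.05 (the
  add-one estimator makes this exactly level 0.05 for any B);
* overdispersion calibration: 300 simulated participants scored at
  their generating parameters, and an 8-participant beta-binomial
  stress cohort (dispersion 0.2) scored after refitting;
* an end-to-end pipeline run with 4 participants and B = 19
  permutation/bootstrap replicates.

## Known limitations

* The fit is a joint mode, not a marginal MLE or posterior: group sds
  are biased low at small n (hence the floor), and headline effects
  should be read together with `stability_check()` output.
* With sparse RSA grids the right-flank parameters ($m$, and through
  them $\tau + \Delta\delta/2$) can ride a likelihood ridge; the full
  15-point grid identifies them, heavily thinned grids may not.
* Normal-theory bootstrap CIs with n ≲ 15 participants undercover
  slightly (the SE itself is noisy); percentile or studentized
  intervals are deliberately out of scope.
* The model presupposes that agency judgements are driven by the same
  temporal classification as simultaneity judgements; participants
  using non-temporal cues appear as exclusions (< 2% yes responses) or
  overdispersion flags, not as a different model.
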