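---
title: "Simulating multi-arm, multi-stage Bayesian adaptive trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multi-arm, multi-stage Bayesian adaptive trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptsim)
```

## The problem

Advanced adaptive randomised trials — multi-arm designs with many interim
(adaptive) analyses, early stopping, arm dropping and response-adaptive
randomisation (RAR) — cannot be sized or tuned with closed-form
calculations. Every design choice (number and timing of analyses, stopping
thresholds, allocation restrictions, priors) interacts with every other,
and the only practical way to learn a design's operating characteristics —
expected sample size, type-1 error, power, probability of a conclusive
result, how often participants end up on better arms — is large-scale
Monte-Carlo simulation of the whole trial, decision rules included.

`adaptsim` implements that simulation loop for trials analysed in a
Bayesian framework, together with the metric suite, reproducible batching,
scenario grids and automatic calibration of stopping thresholds to a target
type-1 error rate.

## The trial model

A design (a `trial_spec`, built with `setup_trial_binom()`,
`setup_trial_norm()` or `setup_trial()`) consists of:

* **Arms and truths.** `K >= 2` arms with true outcome parameters
  (event probabilities for binary outcomes). A *common control* may be
  designated; the direction of desirability (`highest_is_best`) is
  explicit. With an undesirable binary outcome such as mortality, outcomes
  are coded 0/1 with 1 = event and lower event probabilities are better.
* **Analysis schedule with outcome-data lag.** `data_looks[i]` is the
  cumulative number of participants *with outcome data* at analysis `i`;
  `randomised_at_looks[i]` the cumulative number *randomised* by then. The
  difference models the follow-up plus data-handling lag: those
  participants are already randomised (and their outcomes already
  generated) but masked from the analysis until a later look reaches them.
  The first look doubles as the burn-in. The final entries of both
  schedules must agree, so a stopped trial's totals are well defined.
* **Analysis model.** By default, conjugate models: beta-binomial with a
  `Beta(1, 1)` prior (equivalent to two pseudo-participants, one with and
  one without the event) for binary outcomes, or a normal approximation
  centred at the sample mean with scale `sd/sqrt(n)` (no prior
  information) for continuous outcomes. Each analysis draws `n_draws`
  posterior samples per active arm on the natural outcome scale. A
  `draw_hook` can replace the model entirely — any estimation method and
  priors — as long as it returns an `n_draws x (active arms)` matrix; the
  package validates shape and finiteness. All downstream probabilities are
  empirical fractions over the draw index, so with `n_draws = 1000` the
  granularity of any probability is 0.1 %-points; a warning is emitted
  below that size.
* **Decision rules**, evaluated each look in strict priority order:
  1. *Superiority / inferiority* (mandatory). Without a control, each
     active arm's probability of being overall best is used: the best arm
     stops the trial if it exceeds `superiority[i]`; arms below
     `inferiority[i]` are dropped (a lone survivor is declared superior).
     With a control, probabilities are pairwise against the control; a
     superior challenger *replaces* the control (ties broken by the
     highest probability of being best) and comparisons are immediately
     recomputed against the new control at the same analysis.
  2. *Practical equivalence* (optional). Without a control: stop when the
     probability that the largest absolute difference among active arms is
     below `equivalence_diff` exceeds `equivalence_prob[i]`. With a
     control: drop arms pairwise; stop when only the control remains.
  3. *Futility* (optional, control required): drop arms whose probability
     of *not* being better than control by at least `futility_diff`
     exceeds `futility_prob[i]`.

  Any threshold can vary per look; 1 (or 0 for inferiority) disables a
  rule at that look, which is how burn-in restrictions are expressed.
* **Allocation.** Start from `start_probs`. After each analysis the raw
  probabilities of being best are *softened* (raised to
  `soften_power[i] in [0, 1]`; 0 forces equal allocation, 1 leaves RAR
  unrestricted) and renormalised; fixed-probability arms are pinned;
  optional control rules (`sqrt_ratio`, `match_highest`) set the control's
  share; minimum/maximum limits are enforced by clamping to the limits and
  keeping unclamped arms proportional (a scalar water-filling solve — see
  *Numerical choices*). With `rescale_probs = "limits"`, limits are
  multiplied by (initial arms / active arms) after arms drop, capping
  rescaled minima at `1/active` so they stay feasible.

`run_trial()` simulates one trial; `run_trials()` simulates a batch.

## What the generator emulates — and what it does not

Outcome generation is exactly the assumed data-generating process of a
design evaluation: independent Bernoulli (or Gaussian) outcomes at
constant true parameters, constant accrual as encoded by the look
schedules, and a constant lag. It deliberately does not model time drift
in event rates, varying inclusion rates beyond what
`randomised_at_looks` encodes, stratified or blocked randomisation,
covariate structure, or missing data. Operating characteristics estimated
here are therefore properties of the *design under its stated
assumptions*; passing tests say nothing about robustness to drift or
model misspecification, which is why sensitivity analyses over the
*assumed* parameters (reference event rates, lag/accrual) are part of the
workflow (`scenario_grid()` plus config sweeps), always reusing the same
stopping rules without recalibration.

## Performance metrics

`extract_results()` flattens a batch to one row per simulation;
`check_performance()` summarises: sample size, summed outcome and their
ratio (mean, SD, median, 25 %/75 % quantiles, range); probabilities of
conclusiveness, superiority, equivalence, futility and of reaching the
maximum without stopping (conclusiveness and the max-probability always
sum to 1); per-arm selection probabilities under a chosen *selection
strategy* (superiority winners always count; otherwise none, the
surviving original control, a prespecified arm, or the best arm at the
last analysis); the probability of *erroneous* superiority (declaring an
arm that is not the unique truly best arm — in a null scenario this
equals the superiority probability by construction); RMSE and median
absolute error of the selected arm's posterior estimate and of the
intervention effect against a reference arm; and the ideal design
percentage (IDP), which places the expected true outcome of selected arms
between the worst (0) and best (100) arm truths and is undefined when all
truths are equal. Bootstrap CIs resample whole simulations with
replacement (percentile intervals, seeded).

The central estimate of a selected arm is its posterior mean at the final
analysis performed in that simulation; a median option is exposed for
hook-based models that prefer it.

## Calibration

`calibrate_trial()` tunes the constant symmetric stopping threshold
(superiority `x`, inferiority `1 - x`; other parameters via a custom
`install` function) so a metric — by default the probability of
superiority in the supplied (null) scenario, i.e. the type-1 error — hits
a target within a tolerance band, one-sided or two-sided (`dir`). Each
evaluation is a fresh seeded batch of `n_rep` simulations. After the two
search-range endpoints, candidates come from a Gaussian-process regression
of metric on parameter (squared-exponential kernel, length-scale 0.25 of
the scaled range, noise floor at the binomial sampling variance of the
target): the next candidate is where the GP mean crosses the target. If a
proposal repeats a previous candidate within machine tolerance, the
search falls back to bisecting the tightest bracket straddling the
target, guaranteeing progress on monotone responses. The GP internals are
deliberately contract-free: tests pin down only the acceptance band,
reproducibility given seeds, and agreement with bisection on noise-free
monotone stubs. `install_rounded_threshold()` rounds the calibrated value
to a practical number of significant digits — after which the design
should be re-evaluated with a large batch, since rounding shifts the
error rate slightly.

## Reproducibility and numerical choices

* **Random streams.** Trial `i` of a batch uses the `i`-th
  L'Ecuyer-CMRG sub-stream of the base seed, so batches are bit-identical
  for any number of workers, extensions preserve their prefix
  (`extend_trials()`), and a single trial can be reproduced in isolation.
* **Persistence.** Batches persist as RDS with the design's fingerprint —
  an MD5 of a canonical serialisation (sorted fields, 15-significant-digit
  numeric formatting) — plus base seed and replication count; reloading
  with any mismatch is a hard error rather than silent reuse.
* **Ties in the probability of being best** are split fractionally among
  tied arms, keeping the probabilities summing to exactly 1. Ties are
  measure-zero for continuous posteriors and matter only for constant
  draw hooks in tests.
* **Allocation limits** are enforced by solving
  `val_i = clip(c * w_i, min_i, max_i)` with `sum(val) = 1` for the scalar
  `c` (bisection; the sum is continuous and monotone in `c`). Arms at a
  limit sit exactly on it; the rest remain proportional to their softened
  weights. Infeasible limit sets (rescaled minima exceeding 1) are hard
  errors naming the analysis.
* **Degenerate inputs.** Arms with no data draw from the prior alone;
  `soften_power = 0` yields equal allocation among non-fixed active arms;
  an all-dropping inferiority rule can never remove the currently best
  arm; a single-observation continuous arm is an error (undefined scale).
* **Equivalence by range.** The "largest absolute difference below the
  margin" criterion is computed as the range across arms per draw, which
  coincides with the maximum pairwise distance; the equivalence of the two
  formulations is property-tested.

## Problem sizes used in the shipped checks

The package's acceptance checks re-estimate the reference design's
reference operating characteristics at desk scale: 2500 simulations and
2500 posterior draws for the null-scenario runs and 2000 simulations per
difference scenario, comparing against the reference values within three
Monte-Carlo standard errors at that replication. These sizes are the
package's own choice of a desk-scale protocol: large enough that the
3-SE bands are a fraction of the reference effects, small enough to run
routinely. Protocol-grade evaluation (reference workflows in this field use 10,000
simulations per design and 100,000 for final type-1-error confirmation,
with 10,000 posterior draws) is a matter of raising `n_rep`/`n_draws`.

## The worked reference design

Throughout the tests and the acceptance script, the reference design is a
three-arm trial without a common control, undesirable binary outcome at a
25 % event rate in the null scenario, equal starting allocation, RAR with
25 % minimum limits (rescaled on dropping) and softening 0.5, analyses at
500, 750, ..., 10,000 participants with data (700, 950, ..., 9950, 10,000
randomised — a constant lag of 200), symmetric stopping thresholds
0.99/0.01 (0.9904/0.0096 after calibration and rounding), and an
equivalence rule (margin 2.5 %-points, probability 0.9) active once 1500
participants are analysed:

```{r, eval = FALSE}
looks <- seq(500, 10000, by = 250)
spec <- setup_trial_binom(
  arms = c("Arm A", "Arm B", "Arm C"),
  true_ys = c(0.25, 0.25, 0.25), highest_is_best = FALSE,
  start_probs = rep(1/3, 3), min_probs = rep(0.25, 3),
  rescale_probs = "limits", soften_power = 0.5,
  data_looks = looks,
  randomised_at_looks = c(seq(700, 9950, by = 250), 10000),
  superiority = 0.99, inferiority = 0.01,
  equivalence_prob = ifelse(looks < 1500, 1, 0.9),
  equivalence_diff = 0.025,
  n_draws = 10000
)
batch <- run_trials(spec, n_rep = 10000, base_seed = 4131, workers = 4)
check_performance(batch, uncertainty = TRUE, n_boot = 5000, boot_seed = 4131)
```

## Known limitations

Ordinal and time-to-event outcomes, adaptive enrichment, staggered arm
entry, historical-controls-only comparisons, covariate adjustment and
full MCMC posteriors are out of scope (the `draw_hook` accommodates
custom estimation within the supported trial structures). The normal
model uses the estimated sample SD in its posterior scale — a choice that
matters only at very small interim samples and is isolated behind the
hook contract. Calibration tunes one scalar at a time; joint calibration
of several thresholds is not supported.
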