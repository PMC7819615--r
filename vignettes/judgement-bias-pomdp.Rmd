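---
title: "A belief-state POMDP account of go/stay judgement-bias behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A belief-state POMDP account of go/stay judgement-bias behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jbpomdp)
```

## The task and the modelling problem

In a go/stay judgement-bias task, a participant holds a key while a
random-dot kinematogram plays for 2 s.  Holding to the end ("stay") is the
risky choice: it pays the offered reward `R` if the dots drift in the
favourable direction and costs the threatened loss `L` otherwise.  Releasing
early ("go") is safe and pays nothing.  Coherence controls discriminability:
a reference level (0.16) is easy, two ambiguous levels (0.02, 0.01) are
near-chance, and responses to the ambiguous stimuli index an "optimistic"
(risk-seeking) versus "pessimistic" (risk-averse) disposition.  One of the
two stakes fluctuates across the 180-trial test block following a noisy
sine, creating epochs of high and low value, and a 9-by-9 affect grid probes
self-reported valence and arousal every 10 trials.

`jbpomdp` models choices *and* discretised reaction times jointly, links the
fitted parameters and the within-task experience to the affect reports, and
ships a synthetic-data generator that reproduces the task structure, so the
whole pipeline is testable end-to-end without external data.

## The decision model

The trial is a partially observable Markov decision process on states
`s = (t, X)`: discretised time `t = 0..T` (bins of `dt` seconds,
`T * dt = 2` s) and accumulated evidence `X`.  Per-bin observations are
Gaussian, `x_t ~ N(mu * theta * dt, sigma^2 * dt)`, where `mu = +1/-1` is
the true direction, `theta` the coherence and `sigma` the observer's noise.
The posterior over the six `(mu, theta)` cells at `(t, X)` follows from
symmetric direction priors and a uniform prior over the three test
coherences, with `X ~ N(mu * theta * t * dt, sigma^2 * t * dt)`; the
log-odds of the favourable direction take the closed form
`log-prior-odds + (2 * theta / sigma^2) * X`.

Interval timing is noisy: while choosing STAY the trial can subjectively
time out, with per-bin hazard derived from a gamma-distributed stay time
with shape `zeta` and scale `phi`; the terminal bin times out by fiat.
Timing out while holding *is* the stay response, so the probability of a
stay equals the probability of never releasing.

Action values obey an undiscounted Bellman recursion with `Q(s, GO) = 0`,
a timeout value `R * P(mu=+1 | s) + L * P(mu=-1 | s)`, and subjective
transitions that mix the per-stimulus evidence kernels by the posterior
belief and the hazard.  The policy is a lapse-contaminated softmax,

```
pi(s, STAY) = lambda / 2 + (1 - lambda) * logistic(B * (Q(s, STAY) + delta - n * beta_n))
```

with separate lapse rates for ambiguous and reference stimuli, inverse
temperature `B`, and a trial-wise bias `delta` composed from within-task
experience:

```
delta_n = beta0 + betaR * Rbar_{n-1} + betaPE * wPE_{n-1} + betaPE2 * wPE2_{n-1} + betaO * O_{n-1}
```

`Rbar` is a Rescorla-Wagner average of realised outcomes (learning rate
`alphaR`); `wPE` is a normalised forgetting-weighted average of prediction
errors `PE_n = O_n - V00_n`, where `V00` is the start-state value of the
trial (the expected outcome before any evidence); `wPE2` applies the same
weighting to squared prediction errors.  We read the squared term as an
unpredictability magnitude: the gamma-weighted average of `PE^2`, not the
square of the signed average, which would vanish for large alternating
errors and measure nothing of the sort.

The likelihood of a go at bin `t` is the analytic release probability at
`t`; the likelihood of a stay is the overall timeout probability.  Both come
from a forward "remain" recursion under the true-stimulus kernel, so the
same lattice yields simulated data, likelihoods and reaction-time
predictions.

## Numerical choices

* **Discretisation.** `dt = 0.1` s (`T = 20` bins), evidence step
  `chi = sigma * sqrt(dt) / 2` (half a per-bin standard deviation) and grid
  half-width `K = 40`, so the lattice is 20 x 81 and the grid spans about
  4.5 total-trajectory standard deviations; the extreme bins absorb tail
  mass.  Scaling the observation mean and variance by `dt` makes beliefs
  invariant to the bin width.
* **Terminal bin.** Decisions occur at bins `0..T-1`; all probability mass
  still holding at `t = T` times out.  This makes
  `sum(p_release) + p_timeout = 1` hold exactly (tested to 1e-8 under
  random parameter draws) and encodes "holding to the end is a stay".
* **Lapse selection.** The trial's true coherence class picks the lapse rate
  (`lambda_amb` for 0.01/0.02/0.04, `lambda_ref` for 0.16/0.32) for the
  whole trial's policy, matching the per-trial likelihood definition.
* **Floors.** Observation probabilities are floored at 1e-300 before logs;
  a gamma cdf that saturates before 2 s clips the hazard to 1 with a
  warning.
* **No memoisation.** Trial lattices are recomputed exactly: the compiled
  recursions are fast enough that caching keyed on rounded `(R, L, delta, n)`
  would add approximation without measurable benefit.  When the bias has no
  weighted-prediction-error terms, all `delta_n` depend only on realised
  outcomes, and both recursions batch across the session's trials into
  level-3 BLAS products; with `wPE`/`wPE2` terms the session is evaluated
  sequentially, since each trial's `V00` feeds later biases.

## Fitting and model selection

Each participant's 180 test trials are fitted by maximum likelihood.  The
experience trace is recomputed inside the objective because it depends on
the parameters.  The optimiser is BOBYQA on a unit box with the positive
scale parameters (`sigma`, `B`, `zeta`, `phi`) mapped logarithmically —
their plausible values span orders of magnitude, and a linear box wastes
most of the search volume.  Multistart uses Latin-hypercube initialisation
(first start at the package defaults) in two stages: a coarse pass from
every start, then full-budget refinement of the best third.  Box bounds on
the a-priori unbounded bias weights are `+/-10` for stability.

Stepwise selection mirrors the construction of the bias model: core
psychometric/timing parameters always present; step 1 tests the baseline
bias `beta0` by group-summed BIC; step 2 tests each experience/time term
singly, never co-entering the mutually correlated regressors
(`wPE`/`wPE2`/`O`; `Rbar`/`n`), then combines the best improving term of
each group; the final candidate set is compared on summed BIC (with the
AIC-best recorded).  BIC counts one observation per test trial.  Because
`zeta` and `phi` trade off strongly, downstream analyses summarise them as
the mean per-bin timeout probability.

## The synthetic cohort

The generator is first-class code and defines the study conditions:

* Schedule: 24/60/24-trial training blocks and a 180-trial test block,
  coherences and directions balanced per block, ambiguous levels on two
  thirds of test trials.  The fluctuating stake follows
  `10 + 8 * sin(2 * pi * n / 60) + N(0, 1)` rescaled affinely to span
  exactly GBP 0.87-19.16 (the printed endpoints; the underlying sine
  parameters are not documented, so the rescaling guarantees the range and
  the epoch structure, nothing more).  The fixed stake is GBP 10.  Losses
  are stored negative, so the timeout value needs no sign flips.
* Group-level generating parameters (`jb_default_truth()`):
  `sigma = 0.15` puts the reference coherence well above chance and the
  ambiguous ones near it; `zeta = 8`, `phi = 0.3` give a subjective stay
  interval of mean 2.4 s and a moderate timeout probability; `B = 3` keeps
  the 20-fold compounding of the per-bin policy from collapsing holding
  behaviour; lapse rates 0.1/0.05; bias weights at the fitted group means
  (`beta0 = 0.711`, `betaR = -0.143`).  Per-participant parameters are
  drawn around these (log-normal for positive parameters, Gaussian for
  weights) to create the between-participant variance that recovery
  correlations require.
* Affect probes: latent Gaussian valence/arousal built from the probe-time
  experience predictors — each standardised by the participant's own
  standard deviation, exactly as the analysis standardises them — plus
  noise, rounded and clipped to the 9-level grid coded -4..+4 (the neutral
  symmetric coding; the original grid coding is not documented).  The
  probe after trial `k` uses the experience state after trial `k`'s outcome
  and the stakes of the most recent trial as the potential-outcome context
  (`(R + L) / 2`); the baseline probe carries the neutral pre-task state
  and the first trial's stakes.

What the generator does *not* emulate: pixel-level dot motion, display
timing, training-block feedback semantics, and any drift of a real
participant's attention or strategy.  Passing tests therefore certify the
estimator and the statistical machinery against the model's own generative
process — parameter recovery, selection consistency, effect recovery — not
the model's adequacy for any particular human dataset.

## Affect statistics

Per-participant estimates are tested against zero with two-sided sign-flip
permutation tests (exact enumeration up to 12 participants, 10,000 seeded
flips above, add-one corrected).  Parameter-affect association uses a
general linear model of each estimate on mean valence, mean arousal and
condition, with likelihood-ratio tests for dropping each affect predictor.
Probe-wise affect uses Gaussian linear mixed models (participant random
intercept, ML fits so deviances compare): one of `wPE`/`wPE2`/`O` and one
of `Rbar`/`n` enter, chosen by BIC; condition interactions are included,
terms are tested by nested-model LRTs, and significant interactions are
followed by condition-split models with Benjamini-Hochberg adjustment
across that family.  The grid responses are treated as Gaussian on the
-4..+4 coding; an ordinal model is a reasonable alternative the package
deliberately does not implement.

## Problem sizes used by the checks

The tests exercise: exhaustive path-enumeration oracles on lattices up to
4 x 7; conservation over 100 random parameter draws; simulator/analytic
agreement at 10,000 simulated trials of a fixed stimulus (the test stimulus
is chosen concentrated so multinomial sampling noise sits well inside the
tolerance); recovery of 20 simulated participants x 180 trials refitted
with 10 starts; 50 mixed-model replicates at 39 participants x 19 probes;
and 1,000 null permutation tests.  The reproduction script runs a 20-
participant recovery at 8 starts and a 20-participant affect analysis.
These sizes are
the package's own trade-off between statistical resolution and a test suite
that runs in minutes.

## Known limitations

* `zeta` and `phi` are individually weakly identified at 180 trials (their
  product is much better determined); only their hazard summary should be
  interpreted.
* `B` trades off against the scale of `delta`; recovery of either alone is
  noisy, which is why group-level inference uses the bias weights and the
  hazard summary rather than `B`.
* The experience weights (`betaR`, `betaO`) are small relative to their
  regressors' variability; at 180 trials their *sign* is recoverable with
  high probability, their magnitude only coarsely.
* Objective-time hazard: subjective time evolving stochastically (rather
  than timeout risk in objective time) would be more realistic but makes
  the evidence statistics non-homogeneous; the package follows the
  objective-time formulation.

## A worked example

```{r example, eval = FALSE}
sch <- jb_schedule("fluctuating_reward", seed = 1)
ses <- simulate_session(sch, jb_default_truth(), jb_disc(), seed = 2)
fit <- jb_fit(ses, jb_model_spec(baseline = TRUE, experience = "rbar"),
              n_starts = 10, seed = 3)
summary(fit)
plot(fit)   # observed vs predicted mean discretised reaction time
```

The pipeline driver `run_pipeline(jb_config(...))` chains simulation (or
CSV ingestion), fitting or stepwise selection, the experience traces and
the affect statistics, and writes tidy CSV/JSON outputs with a provenance
record; identical configurations reproduce byte-identical outputs.
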