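---
title: "Models and methods: inferring social preferences from choices and decision speed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: inferring social preferences from choices and decision speed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`speedpref` implements the computational machinery of an observational-learning
paradigm built on the Dictator Game: one person (the *dictator*) repeatedly
chooses between two monetary allocations, and a third party (the *observer*)
tries to infer the dictator's preferred allocation from what they are allowed
to see — the choices, the response times (RTs), both, or neither. This
vignette explains the models, the design choices that were genuinely open, and
what the synthetic-data generator does and does not emulate.

## The subjective-value model

An allocation is a proportion-for-self $x \in [0,1]$ (0 = give everything
away, 1 = keep everything). A dictator with preferred allocation
$P \in [0,1]$ values an allocation as

$$s(x) = 1 - (x - P)^2,$$

maximal exactly at the preferred split. Trial difficulty is the absolute
subjective-value gap $|s(\mathrm{left}) - s(\mathrm{right})|$: zero when the
two options straddle the preference symmetrically (the hardest case), large
when one option is clearly better. The central empirical regularity the whole
paradigm rests on is that RT *decreases* with this gap — hesitation reveals
indifference, speed reveals a clear favourite.

## Estimating a preference from decision data

**From choices.** Choices follow a softmax (logistic) rule on the value gap
with inverse temperature $\beta$. `fit_preference_choices()` maximizes the
Bernoulli likelihood over $(P, \beta)$.

**From response times alone.** Decisions are modelled as a drift-diffusion
process whose per-trial drift is a linear function of the signed value gap,
$v_t = v_{\mathrm{scale}}\,(s(\mathrm{left}_t)-s(\mathrm{right}_t))$, with
boundary separation $b$, non-decision time $\tau$, unbiased start point and
unit diffusion coefficient. When the choice is unobserved, each RT contributes
the Wiener first-passage density summed over both boundaries,

$$\ell_t = \log\!\big(f(\mathrm{RT}_t, \mathrm{left}) +
  f(\mathrm{RT}_t, \mathrm{right})\big),$$

and `fit_preference_rt()` maximizes $\sum_t \ell_t$ over
$(P, b, \tau, v_{\mathrm{scale}})$. The first-passage density uses the
standard small-time and large-time series expansions, switching by the usual
accuracy criterion with truncation error at most $10^{-6}$.

Numerical choices here were open and are deliberate:

* upper boundary $\leftrightarrow$ left option, so that positive drift means
  "left is better" — an arbitrary but tested convention (the likelihood is
  exactly invariant under mirroring allocations and reflecting $P \to 1-P$);
* start point unbiased and diffusion coefficient 1 (field-standard
  identifiability constraints);
* RTs at or below a candidate $\tau$ contribute a density floor of
  $10^{-10}$ instead of $-\infty$, so the optimizer can traverse $\tau$;
* bounded quasi-Newton (L-BFGS-B) with 10 uniform random restarts within the
  search box; the best converged restart is kept.

A known limitation: for preferences near 0.5 the RT-only likelihood is
occasionally weakly identified — reflections of the preference around the
option midpoints, combined with a compensating drift scale, can fit one noisy
165-trial dataset slightly better than the truth. Cohort-level rank
correlations are high, but individual fits of near-central dictators can
land far away. This is a property of the estimation problem, not of the
optimizer; choice-based fits do not share it.

## Informative-trial selection

Not every trial reveals the preference. Following the regression
$\mathrm{RT} = b_0 + b_1 |s(\mathrm{left}) - s(\mathrm{right})|$ (with
$b_1 < 0$ on diffusion-like data), trials are categorized as

* **slow** ($\mathrm{RT} > b_0$): slower than the expected RT of a maximally
  difficult trial, so the preference likely sits near the options' midpoint;
* **fast** ($\mathrm{RT} < b_0 + b_1(\mathrm{left}-\mathrm{right})^2$):
  faster than expected even if the preference lay outside the option
  interval, which is where fast trials place it;
* **uninformative** otherwise.

The two thresholds are implemented exactly as stated: the slow rule uses the
subjective-value regressor's intercept, while the fast rule plugs the squared
*objective* allocation gap into the regression line. The geometric reading is
that a fast trial certifies the preference outside the interval spanned by
the two options, a slow trial places it near their midpoint.

After removing inconsistent choices (the chosen allocation strictly farther
from the preference than the rejected one; equidistant options are kept,
since neither is the worse pick), the observation set is the 6 fastest fast
trials plus the 6 slow trials whose midpoint is closest to the preference;
prediction trials are the next 2 of each. Ties break by trial index so
selection is deterministic.

The presentation order of the 12 observation trials is then optimized so
that a forward pass of the learning model, run under every visibility
condition, ends as close to the true preference as possible. Enumerating
all block orderings is combinatorially infeasible, so
`optimize_trial_order()` runs a seeded random search with a configurable
budget (default 50 candidate orders in the generator) and also exposes an
exact mode for small inputs. This is the one place the implementation
deliberately relaxes an exhaustive search; the objective is identical.

## The observational reinforcement-learning model

The observer tracks a running estimate $P_t$ with a delta rule,
$P_t = P_{t-1} + \alpha\,(O_t - P_{t-1})$, where the teaching signal $O_t$
depends on what is visible:

| condition | teaching signal $O_t$ |
|---|---|
| none | midpoint of the two allocations |
| choice only | 1 if the chosen allocation was the more selfish one, else 0 |
| RT only | slow: midpoint; fast: 1/0 from the choice *inferred* under the current estimate |
| both | $(1-\omega)\,O_{\mathrm{choice}} + \omega\,O_{\mathrm{RT}}$ |

A trial is *slow* when its RT exceeds the running mean of the RTs observed
so far from that dictator, the current trial included (so a first trial is
never slow). Because every signal lies in $[0,1]$ and $\alpha \in [0,1]$,
the estimate is a convex combination and provably never leaves $[0,1]$; no
clipping is applied.

The $\omega$-weighted combination is used only where both information
sources exist; the single-information conditions use their own rules
directly. Slider reports are modelled as Gaussian around $P_t$ with fixed
SD $\sigma$ (default 0.1, configurable — it is held fixed during fitting,
with $\alpha$, $P_0$, $\omega$ and the prediction temperature
$\beta_p$ free). One written form of the prediction objective reads as a
negated probability rather than its logarithm; the package uses
$-\log$ softmax probability as the default and keeps the literal variant
behind `literal = TRUE`. Estimation and prediction terms are summed
unweighted. $P_0$ is a single parameter shared across conditions. Fitting
uses 50 restarts by default (reduced in tests), drawn from Beta(1.1, 1.1)
for $\alpha$, Gamma(1.2, scale 5) for $\beta_p$, and uniforms for $P_0$
and $\omega$.

## The Bayes-optimal benchmark

The benchmark observer assumes the true generative model — the diffusion
process above — and performs exact sequential Bayesian inference on a grid
over its five parameters, with priors Beta(3.5, 3) for the preference,
Gamma(1.2, scale 5) for the inverse temperature on (0, 100), Gamma(2,
scale 2) for the boundary separation on (0.1, 10.1), Normal(0, 5) truncated
to (0, 20) for the drift scale, and uniform (0.1, 0.5) for the non-decision
time. The shape/scale parameterization of the Gamma priors is a
documented choice; the bounds are part of the model. Per-trial likelihoods
are the first-passage density at the observed choice and RT (both visible),
that density summed over boundaries (RT only), the softmax probability
(choice only), or a constant (none — the posterior provably equals the
prior). Updates accumulate in log space and renormalize, so batches of
conditionally independent trials commute to numerical precision.

One subtlety governs how the benchmark should be compared to the RL model:
the curated observation sets are *selected* (extreme-RT trials,
midpoint-matched slow trials) and their order is optimized for the RL
forward model, which violates the random-sampling assumption behind the
benchmark's likelihood and hands the RL learner a stream built for it. The
optimality gap — the benchmark estimating preferences from RTs better than
the delta-rule learner — therefore shows cleanly on *matched randomly drawn*
trial streams, and that is where the package's comparison is made; on the
curated sets the two can tie or reverse.

Open choices, resolved as follows: grid resolution defaults to 15 cells per
axis (cell centers at midpoints of equal-width bins; estimates move by less
than 0.01 when the preference axis is doubled on reference sessions); the
point estimate is the *marginal posterior mean* of the preference, which is
stable on coarse grids, with the joint-MAP reading available as an option;
prediction uses the full posterior-predictive mixture of softmax
probabilities.

## The synthetic-study generator

The generator reproduces the statistical structure the analysis assumes: 11
allocation levels in 10% steps, all 55 distinct pairs, 3 repeats (165
trials), per-trial truncated-normal presentation noise (SD 0.02, bounded at
±0.05 — the noise spread is read as a standard deviation, since a variance
of 0.02 would be implausibly large against the ±0.05 bounds — and clipped to
[0, 1], with exact ties resampled), 16 diffusion-model dictators whose
preferences span [0.05, 0.95], 12 observed trials each in blocks of 4
dictators per condition (assignment stratified by preference so every
condition spans the range), estimates before observation and after trials 4,
8, 12, and 4 prediction trials (2 fast, 2 slow). Dictator diffusion
parameters are drawn from ranges well inside the benchmark priors
(boundary 1.5–2.5, non-decision time 0.25–0.35 s, drift scale 4–8), which
produce realistic RT distributions (roughly 0.5–3 s) and choice consistency.
Trial selection in the generator is run against the generative preference.

The simulated observer cohort uses learning rate $\alpha = 0.2$ (typical of
human incremental learning) and RT weight $\omega = 0.3$: observers weigh
choice information far above RT when both are shown, consistent with the
behavioral finding that adding RT to visible choices does not further
improve accuracy. The dictator-to-condition assignment is re-randomized per observer
(stratified by preference), mirroring the pseudo-randomization across
participants, so condition contrasts are not confounded with particular
dictators. Under these conditions the cohort shows rising learning curves,
every information condition clearly above the no-information baseline, and
both ≈ choice only. Choice-only and RT-only accuracies are nearly equal:
with exact speed classification the delta-rule learner extracts almost as
much from curated decision speeds as from choices. Human observers do
distinctly worse with RTs only, a deficit usually attributed to imperfect
time perception — a mechanism deliberately absent from the model, and the
main respect in which simulated cohorts are cleaner than real ones.

What the generator does **not** emulate: noisy human time perception (speed
classification is exact), sequential condition-order effects, slider
kinematics, attention lapses, or any use of the observer's own preference as
a prior in the none condition beyond the midpoint rule. Passing tests on
synthetic cohorts therefore certify the machinery and its internal
consistency, not claims about human observers.

## Problem sizes and determinism

Tests and the acceptance script run the full 165-trial design with 16
dictators and a 46-observer simulated cohort; parameter-recovery studies use
10 optimizer restarts, and grid-observer runs use the default 15-cell axes.
Every stochastic stage draws from R's global RNG, so a single `set.seed()`
(or the acceptance script's `--seed`) makes a whole study byte-reproducible.
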