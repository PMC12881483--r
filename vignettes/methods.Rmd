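---
title: "Modelling two-step task decisions for self and others: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling two-step task decisions for self and others: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific model implemented by `twostepddm`,
the assumptions behind it, and the design decisions taken where the
procedure was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The task

The two-step task pairs a first-stage choice between two spaceships with a
deterministic transition to one of two planets, each paying a drifting
reward. Two first-stage states exist, each showing a different pair of
spaceships, and within each pair the two spaceships cover both planets.
Sessions have 4 blocks of 60 trials (240 total); two blocks pay the
participant (self) and two pay an anonymous other, with the recipient cued
per block. Rewards follow two independent Gaussian random walks (step SD
2) reflecting at 0 and 9, one initialised low (`[0, 4]`) and one high
(`[5, 9]`). First-stage responses are limited to 1500 ms; responses faster
than 200 ms or missing count as invalid. Rewards are only delivered when
the second-stage keypress lands.

Because transitions are deterministic, a learner holding a mental model of
the structure can steer to the currently better planet from either
first-stage state, while a model-free learner can only repeat rewarded
spaceship choices within a pair. The model-based signature in stay
behaviour is a main effect of the previous outcome; the model-free
signature is its interaction with first-stage-state repetition.

Design choices where the task description is open:

* **Reflection rule.** `x -> 2*hi - x` (or `2*lo - x`) applied until the
  value is inside the bounds; implemented in closed form by folding over
  the period `2*(hi - lo)`. This is the standard reflecting-walk
  construction.
* **Payoff continuity.** Walk values are kept continuous in `[0, 9]`; a
  `round_payoffs` switch exists but defaults off, since rounding is not
  part of the stated generating process.
* **Walk advance.** The walk advances every trial regardless of trial
  validity; the reward drawn on trial *t* is the walk value at index *t*.
* **Positions.** Left/right spaceship positions are randomised per trial;
  key identity (left/right) is derived from position.
* **Counterbalancing.** The two pre-determined scaffolds share first-stage
  states, positions and payoff trajectories exactly and swap the
  self/other block assignment; each simulated participant is randomly
  given one of the two.

## The RLDDM

First-stage choices and response times are modelled jointly. A model-free
learner updates state-action values by temporal differences with
prediction errors

* `delta1 = Q_MF(s2) - Q_MF(s1, a1)` and `delta2 = r - Q_MF(s2)`,
* `Q_MF(s1, a1) += alpha * delta1 + alpha * lambda * delta2`,
* `Q_MF(s2) += alpha * delta2`,

with the eligibility trace fixed at `lambda = 1` (with `delta1` computed
from pre-update values the chained update is then `alpha * (r - Q_MF(s1,
a1))`, which the tests verify algebraically). A model-based learner reads
values through the transition structure: `Q_MB(s1, a) = sum_s2 T(s2 | s1,
a) Q_MF(s2)`; second-stage model-based and model-free values coincide.
Stage-2 values start at 4.5, the midpoint of the outcome range; stage-1
values also start at 4.5 so the first prediction error is zero.

The per-action drift is
`v(a) = beta_MB * Q_MB(s1, a) + beta_MF * Q_MF(s1, a) + pi * ch(a) + rho * resp(a)`,
where `ch(a)` marks repetition of the previous trial's spaceship (only
possible when the first-stage state repeats, as different states show
different pairs) and `resp(a)` repetition of the previous key. Evidence
`x` accumulates as `dx = v dt + sigma dxi`, `sigma = 1`, from the
unbiased start `z = a/2` between boundaries 0 and `a`; the response time
is the first-passage time plus a non-decision time `t0`.

Seven parameters per recipient condition, fourteen free quantities per
participant: the Other-condition drift weights are parameterised as Self
plus an Other-Self difference, so the differences themselves are
estimated.

Conventions the equations do not fix:

* **Boundary mapping.** Action 0 (the lower spaceship index) maps to the
  upper boundary. Any fixed convention is equivalent given the signed
  drift difference.
* **Previous-trial indicators.** `ch`/`resp` refer to the global previous
  trial (the last trial with a response); they are zero on each block's
  first trial and after a missed trial.
* **Carryover.** Learner state resets at block starts (exposed as a
  switch, default on): a recipient switch plus self-paced break is a
  natural episode boundary, and only stage-2 initialisation is pinned
  down by the model description.
* **Invalid trials.** Trials without a response contribute neither
  likelihood nor learning. Responded-but-fast (< 200 ms) trials are
  excluded from the likelihood (they are discarded from analysis) but do
  update the learner and the stickiness indicators, since the choice and
  reward really happened. Trials whose second-stage keypress failed carry
  no registered reward and trigger no update.

## Likelihood and its numerics

The Wiener first-passage density is evaluated with the classic
small-time/large-time series, switching by the cheaper term count at
truncation tolerance `1e-7`. Densities are floored at `1e-300` before
logging; observations with `rt <= t0` receive the floored log-density,
which in optimisation pushes `t0` below the fastest valid response. The
tests verify the density integrates to 1 (tolerance `1e-3`), matches the
closed-form choice probability `P(upper) = 1/(1 + exp(-v a))` for the
unbiased start, and agrees with an independent Euler-Maruyama simulation
oracle (`dt = 1e-4`, 100 000 paths) in both choice probability and binned
RT mass. The forward sampler uses the same Euler-Maruyama scheme at
`dt = 1e-3` by default; its first-passage times carry an upward
discretisation bias below about 2% at that step, which is immaterial for
the synthetic cohorts and is avoided in oracle comparisons by using
`dt = 1e-4`.

## MAP fitting

The posterior adds the log-priors: standard normals on the Self drift
weights and both stickiness parameters, `Normal(0, 0.5)` on the two
differences, `Beta(2, 2)` on learning rates, `Gamma(1.5, 0.75)` on the
boundary and `Gamma(0.8, 0.2)` on `t0`. The Gamma hyperparameters are
read as **shape-scale** (prior means 1.125 and 0.16 s): the shape-rate
reading would put the `t0` prior mean at 4 s, far outside its `[0.001,
1]` s search box, so it cannot be the intended one; the parameterisation
remains a flag on `prior_spec()`.

Optimisation is an elitist steady-state genetic algorithm over the
boxes (`[-3, 3]` weights/stickiness, `[-1, 1]` differences, `[0.00001,
0.99999]` learning rates, `[0.3, 3]` boundary, `[0.001, 1]` s `t0`):
population 200, 100 parents kept per generation, 100 generations,
offspring by uniform crossover with per-gene Gaussian mutation
(probability 0.1, SD 10% of the box width), clipped to the boxes; 10
restarts from different seeded populations, best restart retained.
Selection scheme, crossover and mutation details are not pinned down by
the procedure description; these defaults are common GA practice, and the
elitist design makes the best-so-far trajectory non-decreasing and
longer runs with the same seed strictly continuations — both properties
are tested. Likelihood evaluation is vectorised over the population in
compiled code.

## The synthetic cohort

No public dataset exists for this task variant, so the package generates
its own cohorts. Two modes:

* **Recovery mode** draws each parameter independently from the uniform
  ranges of the recovery study: `U(-0.5, 1)` for the weights, `U(-1,
  0.5)` for the differences, `U(0, 1)` for learning rates, `U(-1.2,
  1.2)` for stickiness, `U(0.9, 2)` for the boundary, `U(0.02, 0.55)` s
  for `t0`.
* **Planted mode** (default 92 agents, the sample size at which a
  one-sided paired *t*-test reaches about 90% power for a *d* = 0.3
  effect) centres parameters on realistic group values for this paradigm
  (Self model-based weight 0.37 +- 0.16, learning rate 0.65, boundary
  1.4, `t0` 0.28 s +- 0.07) and plants three effects, chosen once: a
  mean Other-Self model-based-weight gap of -0.13, a mean Other-Self
  non-decision-time gap of -0.04 s, and an SVO correlation of -0.5 with
  the Self-Other weight gap. The weight gap is partially driven by the
  `t0` gap with slope 1.15 per second, making the two gaps correlate at
  about 0.38, so the mediation stage has a true signal whose indirect
  share is roughly a third of the total effect. A
  Gaussian copula ties SVO (truncated Normal, mean 25, SD 15 degrees,
  over the instrument range) to the gap so every marginal stays inside
  its admissible range. Agents miss 2% of first-stage responses and fail
  2% of second-stage keypresses, exercising the validity handling.

What the generator does **not** emulate: post-experiment beliefs about
the recipient, within-session fatigue or drift in parameters, sequential
dependencies beyond first-order stickiness, and any relation between SVO
and the parameter *levels*. Passing tests therefore show that the
pipeline recovers effects of the planted kind at realistic noise levels,
not that human data contain such effects.

The exclusion pipeline applies two quantitative rules: more than 20%
invalid trials, and random responding. The random-responder null
simulates 1000 uniform-choice agents and takes the 5th percentile of
their per-block negative log-likelihoods under a reference model. A
fair-coin reference makes every random agent's block score exactly
`60 * ln 2 = 41.6`; published thresholds for this criterion sit a
little *below* that value, which implies a fitted reference, so the
default here scores each block's choices under per-first-stage-state
Bernoulli maximum-likelihood probabilities, whose mild overfitting
(about half a chi-square with 2 df) lands the 5th percentile near
38.6 — exactly that region. Both references are available. An agent is
flagged when it exceeds the threshold in all blocks of both conditions,
the strictest reading of random responding throughout.

## Stay-probability regressions

Stay rows are built within blocks from consecutive valid trial pairs;
previous outcome enters standardised (z-scored in the model matrix;
standardisation only rescales its coefficients), first-stage similarity is
coded 1/0 and recipient +-0.5/-0.5. The hierarchical logistic model
`stay ~ po * fs * so + (po * fs * so | id)` (optionally crossed with
z-scored SVO in the fixed part) is estimated two ways:

* **`method = "mcmc"`**: JAGS, independent random slopes with
  half-Cauchy(2.5) SD priors and Normal(0, 5) coefficient priors (the
  "weakly informative defaults" of this implementation, recorded in the
  output), 4 chains x 2500 iterations, 500 warm-up.
* **`method = "laplace"`**: a Gaussian posterior approximation centred on
  the penalised-likelihood estimate of the matching `lme4` model with
  independent random slopes. This is the fast route used inside the
  posterior-predictive and muting loops, the same role variational
  approximations usually play in such replicate loops; posterior means
  and HDIs are taken from the
  Gaussian, and participant-level coefficients are the conditional
  means. The tests check that the two routes agree in sign on planted
  data.

Random slopes are modelled as independent (no correlation matrix) in
both routes, trading a small amount of flexibility for large speed and
stability gains at these data sizes.

## Individual differences

SVO angles use the standard slider convention,
`atan((mean_other - 50) / (mean_self - 50))`, over the six primary
items, whose payoff grids are instrument constants embedded in
`svo_items()`. (Some textual descriptions of the instrument invert the
numerator and denominator; the standard convention — other-centred
numerator, both anchors at 50 — is the one implemented.) Brute-force
enumeration over all `9^6` response combinations
reproduces the instrument's extreme angles of -16.26 and 61.39 degrees.

Mediation (condition -> non-decision time -> model-based weight) is
estimated on stacked long-format data, two rows per participant with the
condition effect-coded; paths by linear regression, the indirect effect
as the product of paths, and percentile bootstrap CIs over 10 000
resamples by default. Row-level resampling matches the convention of
common mediation toolboxes; participant-level resampling is available
as an option. SVO can be partialled from every path. Partial
correlations are residual-on-residual Pearson correlations with
degrees-of-freedom-corrected tests.

## Validation studies and problem sizes

Three studies close the loop:

* **Parameter recovery**: uniform-range agents, simulate, refit, report
  per-parameter Spearman correlations and recovered-estimate
  intercorrelations. The full design uses 100 agents at the full GA
  budget; the test suite and acceptance script run a 20-agent smoke
  version at the full restart budget (about 2-3 minutes), sized so the
  suite stays fast while rank correlations remain interpretable.
* **Posterior predictive**: replicate cohorts simulated from fitted (or
  generating) parameters; per-agent reward correlations, value-difference
  profiles of choice share and median RT, and replicate regression
  coefficients.
* **Muting**: self-other gaps in the model-based weight, the learning
  rate, or both are set to zero before simulating; the shrinkage of the
  `po:so` coefficient relative to the unmuted baseline attributes the
  behavioural signature to the muted parameters. The acceptance-scale
  runs use 40-agent cohorts and 6-10 replicates per configuration.

The end-to-end planted-effect check fits all 92 agents of a planted
cohort (2 GA restarts per agent, about 2.5 minutes per replicate), runs
the regression, mediation and SVO stages, and scores the three planted
signs. Five seeded replicates are used at this scale; the pre-registered
decision rule is that at least 4 of 5 replicates must show all three
signs, the exact binomial test of a 95% sign rate at this replicate
count.

## Known limitations

* MAP point estimates only — hierarchical shrinkage and full RLDDM
  posteriors are out of scope by design.
* The GA is a stochastic optimiser; with 2 restarts (the end-to-end
  studies) occasional local optima add estimation noise, which the
  planted-effect checks absorb by working at the cohort level.
* The Laplace route understates posterior tail asymmetry relative to
  MCMC; it is used where only posterior means and signs are consumed.
* Euler-Maruyama sampling carries a small positive RT bias at the
  default step; exact-series sampling was not needed at the accuracy
  the studies require.
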