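---
title: "Methods: the breadth-depth sampling task, its ideal observer, and the behavioural models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the breadth-depth sampling task, its ideal observer, and the behavioural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breadthdepth)
```

## The task and its generative model

A decision maker receives a finite budget of `C` samples (the *capacity*)
and faces many alternatives (suppliers) whose qualities are unknown. Each
alternative's quality `p_i` is an independent draw from a Beta(α, β) prior
that defines the *environment*: `poor` (α = 1/3, β = 1; prior mean 0.25),
`neutral` (3, 3; mean 0.50) and `rich` (1, 1/3; mean 0.75). The decision
maker allocates the `C` samples freely over alternatives — many
alternatives shallowly (*breadth*) or few deeply (*depth*) — then observes
one Bernoulli(`p_i`) outcome per sample, so alternative `i` with `n_i`
samples yields a Binomial(`n_i`, `p_i`) count of good outcomes. Finally one
*sampled* alternative is purchased in bulk: the reward is
Binomial(100, `p_chosen`) good units. Qualities are redrawn independently
every trial, so trials are exchangeable within an environment.

Four canonical designs cross a narrow (2–10 samples, 10 alternatives) or
wide ({2, 4, 8, 16, 32}, 32 alternatives) capacity range with a
within-subject (all three environments in blocks) or between-subject (one
environment) schedule, always 8 repetitions per capacity per block — 216,
72, 120 and 40 trials per participant for W10, B10, W32 and B32. Within a
block, capacities are presented in a uniformly shuffled order; the design
tables do not constrain that order further, so no constraint (e.g. against
immediate repeats) is imposed.

## The ideal observer

After `k` good outcomes in `n` samples the posterior mean quality is

$$V^{norm} = \frac{k + \alpha}{n + \alpha + \beta},$$

and before the outcomes arrive `k` follows the Beta–Binomial distribution.
An allocation is summarised by its integer partition
$\{n_1, \dots, n_m\}$ of `C`; its value is the expected *maximum* posterior
mean over the parts, since the best sampled alternative is purchased. The
package computes this exactly: each part's posterior mean is a discrete
variable on $(k+\alpha)/(n_i+\alpha+\beta)$, parts are independent, so
$P(\max \le v)$ is the product of the parts' CDFs on the merged support,
and the expectation is read off the resulting distribution. The optimal
policy enumerates every partition of `C` with at most as many parts as
there are alternatives (8349 partitions at C = 32) and keeps the argmax;
`m_opt` is its number of parts.

Numerical choices:

* support values from different parts are merged after rounding to 1e-12,
  so ties coming from equal rationals collapse before the CDF product;
* partitions whose expected values agree within 1e-12 are tied; ties are
  broken toward fewer parts, then the lexicographically largest
  non-increasing partition, giving a reproducible `m_opt` near the many
  near-ties this objective produces;
* a single-part allocation is a martingale case: its expected value equals
  the prior mean exactly, which the tests verify to 1e-10 for n up to 64;
* expected reward is non-decreasing in capacity (an extra sample never
  hurts), also verified across C = 2..32.

Monte-Carlo evaluation of a partition's value
(`monte_carlo_expected_value()`) is retained purely as an independent
cross-check oracle; the policy itself is exact, deterministic and fast.

One consequence of exact computation is worth stating. In the poor
environment the pure-breadth allocation {1, 1, 1, 1, 1, 1} at C = 6 beats
the best alternative partition {2, 1, 1, 1, 1} by only 0.0042 in expected
value, and the first capacity where the optimal allocation departs from
pure breadth is C = 7. Simulation-based computations of the same policy
with limited Monte-Carlo samples can easily place that transition one
capacity earlier, because the margin is an order of magnitude smaller than
typical simulation noise at a few thousand draws. The package reports the
exact answer.

Two final-choice rules are provided over the sampled alternatives only
(unsampled ones are never choosable): the normative rule (argmax of
$V^{norm}$, prior-aware) and the proportional rule (argmax of $k_i/n_i$,
prior-free). Both return the full tie set.

## Behavioural model families and their likelihoods

Six families predict the mean number of alternatives sampled as a function
of capacity: depth (M = 2), pure breadth (M = C), free-slope linear
(M = dC), square root (M = √C), free power law (M = C^w) and the optimal
family (M = M_opt(C) from the exact policy). Two noise models link the
prediction to the observed integer M:

* **Gaussian**: M is normal with s.d. σ = a + bC; each trial contributes
  the standard log-density −½log 2π − log σ − r²/(2σ²). Parameter pairs
  giving σ ≤ 0 at any observed capacity are rejected outright. The
  published description of this likelihood and of the (a, b) grids is
  internally inconsistent (it would allow σ ≤ 0 and an empty slope grid),
  so the package uses the standard normal log-density and symmetric grids
  a ∈ [−3, 3], b ∈ [−1, 1] in steps of 0.05, both overridable.
* **Binomial**: M ~ Binomial(n, p) with n = round(M(C)/p) clamped to at
  least 1, so E[M] ≈ M(C) up to rounding. A trial with M > n is an
  impossible event and contributes −∞; this impossibility is informative
  and deliberately not clamped away.

The mean offset μ is exposed but defaults to 0 for both noise models: no
grid for it is published and the binomial construction already centres the
noise on the model mean. Grids: p from 0.01 to 1 in steps of 0.01, w from
0.05 to 1.1 in steps of 0.05; the slope d of the linear family has no
published grid, so it reuses the w grid (0.05–1.1, step 0.05) — at d = 1
the linear family nests pure breadth, which is the behaviour the family is
meant to bracket. Fitting is exhaustive grid search; argmax ties go to the
smallest parameter vector in lexicographic order.

Model comparison uses fourfold cross-validation: trial folds are
*stratified by capacity* (each fold sees every capacity, so M(C) is never
extrapolated; whether the original folds were stratified is not stated),
fitted on 75% and scored on the held-out 25%, and the CVLL is the mean
over folds with finite test likelihood. A fold can be invalidated by the
binomial impossible-event rule; invalid folds are counted and dropped, and
only a dataset where *every* fold is invalid is an error. AIC
(2k − 2 log L on the full data, k counting family plus noise parameters)
is reported alongside.

## Descriptive analyses

* `power_fit()` summarises a strategy by the fixed-intercept power-law
  exponent, the zero-intercept least-squares slope of log M on log C. The
  fit uses trial-level points by default (the aggregation level of the
  original fits is ambiguous; capacity means can be supplied instead by
  pre-aggregating). Adjusted R² uses 1 − (1 − R²)(n − 1)/(n − k − 1).
* `allocation_sd()` measures allocation homogeneity as the sample s.d.
  (n − 1 denominator) of the per-alternative counts; a single-part
  allocation returns 0 by convention (such pure-depth trials are excluded
  from homogeneity comparisons anyway). Comparisons against the optimal
  partition (`homogeneity_vs_optimal()`, `outcome_vs_optimal()`) use only
  trials where the optimal policy is not pure breadth (M_opt < C), because
  at pure-breadth capacities the observed s.d. can only exceed the optimal
  0 and the comparison would be one-sided by construction.
* `classify_sequence()` labels allocation orders: depth-focused when every
  alternative's samples are contiguous, breadth-focused when the first M
  samples hit M distinct alternatives, mixed otherwise; trials with M = 1
  or M = C are excluded. For 1 < M < C a sequence can in edge cases
  satisfy both patterns (e.g. contiguous runs whose first M entries are
  distinct); depth-focused wins those ties, which matches the definition
  that prioritises samples-per-alternative.
* `resampling_stats()` median-splits the previous trial's reward within
  capacity × environment, ties going to the low bin (deterministic), and
  reports the probability of resampling the previously chosen alternative
  and the fraction of capacity it receives.
* `choice_agreement()` counts a choice as agreeing with a rule whenever it
  lies in the rule's argmax set. On trials disagreeing with the
  proportional rule, the reported sample-count difference compares the
  chosen alternative with the argmax member holding the most samples when
  the argmax is tied — the conservative comparison.

## The synthetic-agent generator

`generate_dataset()` stands in for trial tables from real experiments. An
agent draws M around C^w under the same binomial or Gaussian noise the
models assume, splits capacity homogeneously (parts differ by at most 1),
by the constrained-optimal partition, or as a uniform random composition,
orders samples depth-focused, breadth-focused or at random, and chooses by
the normative or proportional rule with a lapse probability ε (uniform
choice among sampled alternatives; the default agent has ε = 0). A
`resample_bias` parameter optionally forces the previously chosen
alternative back into the sampled set after an above-chance reward,
emulating weak reward-driven resampling; it defaults to 0.

M draws are clamped to [1, min(C, n_alternatives)], which biases the mean
at extreme w; the generator records the clamped fraction per agent so
recovery analyses can condition on it. Defaults follow the canonical study
conditions: designs W10/B10/W32/B32 with their capacity sets and 8
repetitions, the three Beta environments, and binomial allocation noise
p = 0.9 around w = 0.75 — a mid-range trade-off exponent with realistic
noise. The generator is stationary: no learning within blocks, no
carry-over between blocks, no reaction times or motor costs. Passing tests
on synthetic data therefore demonstrate that the pipeline recovers what it
assumes, not that real data satisfy those assumptions.

For the recovery study the free-power condition is w = 0.75 with binomial
p = 0.9 (50 agents, design W10). The pure-breadth condition is the
deterministic pure-breadth agent (M = C on every trial): pure breadth is a
deterministic strategy, and under binomial allocation noise around M = C
the linear family at slopes near 1 represents the same mean structure, so
no selector could attribute such data to one family at a high rate —
family identification is only a well-posed question for the noiseless
generator.

## Problem sizes and runtimes

The test suite generates all fixtures in code. The heavier checks use: the
exact optimal curves for C = 2..32 with 32 alternatives in all three
environments; 20 random partitions compared against 10⁵-draw Monte-Carlo
estimates; and 50 synthetic agents per recovery condition on the W10
design (216 trials each), fitted over all six families with binomial
noise. The whole suite runs in about three minutes on one core; the
optimal-policy computation itself takes a few seconds per environment.

## Known limitations

* The exact policy's near-ties mean `m_opt` at some capacities depends on
  the documented tie-break; the expected value does not.
* The binomial likelihood inherits a rounding kink from n = round(M(C)/p),
  so the fitted p grid occasionally prefers a neighbour of the generating
  value.
* The generator does not emulate block-order contamination, within-block
  learning, or motor biases; analyses of those phenomena accept real trial
  tables through the CSV schema but are validated only on the stationary
  generator.
* Gaussian-noise fits are supported throughout but the binomial noise
  model is the better-behaved default for integer M.
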