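---
title: "Moments of healthy longevity: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moments of healthy longevity: model, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthyLongevity)
```

## The model

Health expectancy calculations usually stop at an expectation: the mean
number of years a person of a given age can expect to live in good health.
This package treats healthy longevity as what it actually is — a random
variable over the life course — and computes its full complement of
statistics: mean, variance, standard deviation, coefficient of variation,
and skewness, for every starting age or stage.

The life course is a discrete-time absorbing Markov chain. The transient
states $1,\dots,\omega$ are living age classes (or stages); the absorbing
states $1,\dots,\alpha$ are death, possibly classified by cause. With the
transient states first, the transition matrix in column-to-row orientation
is

$$
P = \begin{pmatrix} U & 0 \\ M & I_\alpha \end{pmatrix},
$$

where $U$ ($\omega \times \omega$) holds transitions among the living —
for an age-classified model, survival probabilities $p_j$ on the
subdiagonal, optionally an age-invariant $p_\omega$ in the corner to make
the last class open-ended — and $M$ ($\alpha \times \omega$) holds the
death probabilities. Every column of $P$ sums to one; `assembleP()`
enforces this at $10^{-12}$. The fundamental matrix
$N = (I-U)^{-1}$ gives expected occupancy times and, through

$$
\eta_1^T = \mathbf 1^T N,\qquad
\eta_2^T = \eta_1^T (2N - I),\qquad
\eta_3^T = \eta_1^T (6N^2 - 6N + I),
$$

the raw moments of remaining longevity. We verified this third-moment
coefficient pattern independently against exhaustive trajectory
enumeration on small chains, since misprints in such formulas are common.

A health outcome enters as a *reward*: a random variable $r_{ij}$
collected on each transition from state $j$ to state $i$, with raw moments
stored in matrices $R_k$. Rewards accumulate until death and never after.
The moments of the lifetime accumulated reward $\tilde\rho_k$ (one entry
per starting class) follow from a single general recursion,

$$
\tilde\rho_m = N^T Z (P \circ R_m)^T \mathbf 1
 + \sum_{k=1}^{m-1} \binom{m}{k} N^T (U \circ \tilde R_{m-k})^T \tilde\rho_k,
$$

with $Z = [\,I \mid 0\,]$ the transient-state selector and
$\tilde R_k = Z R_k Z^T$. The package implements **only** this recursion
(`accumulateMoments()`); the familiar order-1 to order-3 formulas exist in
the test suite as independent oracles, so there are no divergent code
paths. Summary statistics then follow from the moment vectors in
`lifetimeStatistics()`.

## Reward conventions

**Binary outcomes (prevalence data).** A year lived in class $j$ counts as
a year of the condition with probability $v_j$ (a Bernoulli reward, all of
whose raw moments equal $v_j$). The year of death is credited a fraction
of the period — one half by default, the usual life-table convention; the
`deathCredit` argument exposes it. Two readings of the death credit's
higher moments are supported and always logged in the output metadata:

* `paper_literal` (default): $R_3 = R_2 = R_1$ — the death entry is
  $v_j/2$ in every order. This is itself a legitimate random reward: one
  full year granted with probability $v_j/2$.
* `moment_consistent`: the death reward is $1/2$ year with probability
  $v_j$, so its $k$th raw moment is $v_j (1/2)^k$.

The two differ only in the second and third moments of the death-year
credit and converge as the death credit tends to 0 or 1. Because the
published construction can be read either way, the mode is an explicit
parameter rather than a silent choice, and every statistics file records
which was used.

**Categorical and ordinal outcomes.** Grouped conditions are binary
outcomes whose prevalence is the sum of the component prevalences
(`combinePrevalence()`); with $n$ outcomes there are $2^n-2$ nonempty
proper groupings (`countGroupings()`), and an ordinal scale admits $n-1$
order-preserving cuts (`ordinalBinarySplits()`).

**Interval-scale outcomes.** A quantitative measure (grip strength, blood
pressure, ...) has no prevalence; instead the first three empirical raw
moments per age class are taken from microdata
(`momentsFromMicrodata()`), and a year lived in class $j$ contributes a
reward with those moments (`intervalRewards()`). All moments are about
zero. Accumulated units are outcome-years (e.g. grip-years).

**Variance decomposition.** Fixing every reward at its mean
($R_k \mapsto R_1^{\circ k}$, `fixedRewards()`) removes the within-year
health lottery while preserving the mean; the variance that remains is
attributable to the life-course trajectory alone. `decomposeVariance()`
reports total, among-trajectory, and within-trajectory (by subtraction,
so the parts add up exactly).

**Sullivan consistency.** The mean of the binary-reward model reproduces
the classical prevalence-weighted person-years sum
$HE(x) = \sum_{j\ge x} L_j v_j$ exactly when
$L_j = N_{jx}\,(p_j + (1-p_j)\,c)$ with $c$ the same death credit — for
$c = 1/2$ this is the familiar $L_j = (l_j + l_{j+1})/2$ convention. The
package pins this construction in `occupancyPersonYears()` rather than
leaving the $L_j$ convention implicit; the equivalence is exact, not
approximate, under that matching.

## DALYs

Disability-adjusted life years combine two reward types on a two-cause
chain (absorbing state 1 = death from the focal cause, 2 = all other
causes):

* *Years of life lost* (YLL): the transition from age $j$ into absorbing
  state 1 is rewarded with the remaining longevity under a standard
  (reference) mortality schedule — not just its expectation but its full
  moments $\eta_k$, taken at the matched age class $j$ of death. The
  standard schedule is the investigator's choice; the focal population's
  own schedule is an internally consistent default. Focal and standard
  grids are required to be identical (no implicit regridding).
* *Years lived with disability* (YLD): each survival transition out of
  class $j$ is rewarded with the severity weight $s_j \in [0,1]$ with
  probability $v_j$ (the prevalence of disability from the focal cause),
  so its $k$th moment is $s_j^k v_j$.

Each transition carries exactly one reward type, so no cross-moments
arise in the default configuration. A half-period disability credit in
the year of death is available (`disabilityCreditAtDeath = TRUE`), in
which case the cause-1 death reward becomes a sum of independent YLL and
credit components and its moments follow from the binomial expansion;
the default is off, matching the plain construction in which disability
attaches to survival transitions only. The mean is additive:
mean DALY = YLL mean + YLD mean, and both components are reported in the
result metadata. No age-weighting or time-discounting is applied.

The printed matrix forms of the DALY reward construction were not fully
legible in our source material; the implementation follows the verbal
definition above and is validated against exhaustive enumeration of all
(trajectory × death cause × disability outcome) combinations on small
chains, at $10^{-12}$.

## Reference implementations

Two independent oracles guard the analytic recursion:

* `enumerateExact()` enumerates every (path × reward realisation) pair
  with its exact probability on chains that absorb in bounded steps, and
  must agree with `accumulateMoments()` to $10^{-12}$ wherever both are
  defined. This is the package's core correctness property.
* `simulateRewards()` draws full individual life courses with sampled
  rewards under a single seeded generator; empirical moments converge to
  the exact ones (checked at $n = 10^5$ within four standard errors).

Reward samplers are explicit discrete distributions per transition and
are checked for moment-compatibility with the matrices they mirror
(`samplerMoments()`). Interval-scale outcomes specify moments only, not a
distribution, so their stochastic validation uses discrete samplers whose
moments match.

## The synthetic cohort

`generateSyntheticCohort()` emulates the inputs of a survey-plus-life-table
analysis of ageing Europeans — the setting the method is designed for —
without requiring restricted microdata:

* ages 50–90 in one-year classes, the last class truncating the analysis
  at 90 (survival 0), as prevalence estimates beyond 90 are erratic in
  real surveys;
* Gompertz mortality, baseline hazard $0.004$ at age 50 doubling roughly
  every 8 years ($b = 0.09$) — a contemporary European male level;
* ADL-free (activities-of-daily-living) prevalence declining
  logistically from about 0.93 at 50 toward 0.42 at 90;
* grip-strength-like microdata: mean 45 kg at 50 declining 0.45 kg/year,
  constant CV 0.2, mild negative skew (−0.3) generated by a reflected
  standardised gamma, 60 observations per age class.

These values were fixed once as field-plausible magnitudes. The generator
reproduces the qualitative patterns the method is known for: healthy
expectancy below total expectancy everywhere, SD of remaining healthy
life declining with age, CV near 0.3–0.5 and rising with age, and
negative skewness induced by the truncated life course. What it does
*not* emulate: survey weights, nonresponse, measurement error in
dynamometry, cohort effects, or heterogeneity beyond age — so passing
tests demonstrate correctness of the computation, not unbiasedness of any
real-world estimate built on survey prevalences.

## Numerical choices

* $N$ comes from a linear solve, not an explicit inverse; the contract is
  a residual below $10^{-10}$, and non-absorbing chains (spectral radius
  of $U \ge 1$) are rejected up front.
* Variance entries in $(-10^{-9}, 0)$ — floating-point cancellation in
  $\rho_2 - \rho_1^2$ — are clamped to zero with a warning; anything more
  negative is an error, as it indicates inconsistent inputs rather than
  rounding.
* CV is `NA` where the mean is zero; skewness is `NA` where the variance
  is numerically zero (below $10^{-12}$), which also covers
  near-degenerate open-ended tail classes, instead of emitting ±Inf.
* Statistics are reported for every transient starting state, not a
  single radix age.
* Truncation at an age (e.g. 90) is expressed in the schedule itself —
  final survival 0, not open-ended — so no separate truncation flag
  exists in the math.
* Problem sizes in the test suite: exhaustive enumeration runs on chains
  with $\omega \le 3$ (where the outcome space is small enough to be
  exact), Monte Carlo checks use $10^5$ replicates on the 41-class
  cohort; both were chosen to make the 4-standard-error bands tight
  enough to be informative.

## Limitations

Prevalence-based models do not track individual transitions between
health states; incidence-based multistate extensions are outside this
package's scope, as are survey preprocessing, parameter-uncertainty
propagation, disability-weight estimation, and analytic sensitivity
(matrix-calculus) machinery. The variance reported here is individual
stochasticity — the spread generated by applying identical probabilities
to everyone — and must not be read as parameter uncertainty or as
population heterogeneity in underlying risks.
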