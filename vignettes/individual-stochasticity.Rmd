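---
title: "Individual stochasticity from matrix population models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual stochasticity from matrix population models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochlife)
```

## The model

A matrix population model describes a life cycle by a transition matrix
$\mathbf{U}$ — entry $(i, j)$ is the probability that a stage-$j$ individual
survives one projection interval and is then in stage $i$ — and a fertility
matrix $\mathbf{F}$ of mean offspring counts. The model assumes that every
individual in a stage experiences the same rates (no heterogeneity), that
rates are constant in time, and that individual fates are independent. All
variation in outcomes computed here is therefore *individual stochasticity*:
variance created by probabilistic transitions alone.

Embedding $\mathbf{U}$ in an absorbing Markov chain

$$\mathbf{P} = \begin{pmatrix}\mathbf{U} & \mathbf{0}\\ \mathbf{M} & \mathbf{I}\end{pmatrix},
\qquad \mathbf{M} = \mathbf{1}^\top - \mathbf{1}^\top\mathbf{U},$$

gives longevity as the time to absorption. The fundamental matrix
$\mathbf{N} = (\mathbf{I}-\mathbf{U})^{-1}$ collects expected stage
occupancies, and the standard recursions give raw moments of longevity
($\eta_1^\top = \mathbf{1}^\top\mathbf{N}$,
$\eta_2^\top = \eta_1^\top(2\mathbf{N}-\mathbf{I})$,
$\eta_3^\top = \eta_1^\top(6\mathbf{N}^2-6\mathbf{N}+\mathbf{I})$,
$\eta_4^\top = \eta_1^\top(24\mathbf{N}^3-36\mathbf{N}^2+14\mathbf{N}-\mathbf{I})$).
Lifetime reproductive output treats reproduction as a random reward on every
transition: stage $j$ contributes a Poisson draw with mean
$\lambda_j = \sum_i F_{ij}$ (offspring types summed), and the moments of the
accumulated reward follow from a binomial-expansion recursion through
$\mathbf{N}^\top$. Skewness and excess kurtosis are derived from raw moments
via central-moment identities; kurtosis is always reported in excess of the
normal distribution's 3.

## Conventions, pinned

Three conventions are genuinely free and had to be pinned; the simulator
(`simulate_cohort()`) uses the identical clock so that oracle comparisons are
convention-consistent.

* **The death step counts.** Longevity of a one-stage chain with per-step
  death probability $q$ is geometric on $\{1, 2, \dots\}$; mean longevity
  equals the column sum of $\mathbf{N}$.
* **Rewards attach to every transition out of a living stage, including the
  dying one** — an individual reproduces during its final interval. This
  choice is pinned by the classical accumulation identity
  $E[\mathrm{LRO}] = \mathbf{f}^\top\mathbf{N}\,\mathbf{e}_1$
  (with $f_j = \sum_i F_{ij}$), which it reproduces exactly; the test suite
  demonstrates that the oracle detects the alternative convention as a
  $|z| \gg 4$ failure.
* **A newborn has age 0**, and offspring produced during the interval entered
  at age $t$ are recorded at age $t$. Under this convention the two-stage
  fixed-age semelparous life cycle has generation time 1. The `age_origin`
  configuration flag switches both the analytic formulas and the simulator to
  the end-of-interval (+1) convention together; the SD of offspring ages, and
  hence the parity CV denominatorwise, is unaffected except through the mean.

Age at maturity is the age at *first entry* into a reproductive stage
(fertility column sum strictly positive — no tolerance), counted including
the entering step, and its statistics are conditional on ever maturing: the
reproductive set is made absorbing, the chain is Doob-conditioned on
absorption there rather than in death
($u^c_{ij} = u_{ij} b_i / b_j$ with $b$ the success probabilities), and the
longevity machinery is applied to the conditioned chain. Unconditional
moments would be dominated by the individuals that die first, which is not
what a maturation schedule means.

## Screening and comparative parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_stages` | 5 | smallest admissible model dimension |
| `cond_threshold` | 1000 | drop models with $\kappa_2(\mathbf{I}-\mathbf{U})$ above this: near-singular systems make $\mathbf{N}$ unreliable (a near-immortal life cycle) |
| `outlier_c` | 5 | upper outlier limit $Q_3 + 2c(Q_3 - Q_2)$ applied to LRO mean, variance and kurtosis |
| `quantile_type` | 7 | linear interpolation between order statistics, shared by every quantile computation |
| `outlier_grouping` | `per_kingdom` | quartiles computed within kingdom (animals and plants are analyzed as separate subsets); `pooled` available |
| `age_origin` | `zero` | offspring-age clock, see above |

Decisions where practice varies: the condition number uses the 2-norm
(SVD-based, the strictest common default; the 1-norm is available). Note
that a $1\times 1$ model can never be dropped by this filter — the condition
number of any $1\times 1$ matrix is 1 — which is consistent: the filter
guards the *linear solve*, not small mortality per se. Outlier screening
removes a row only when a statistic *strictly* exceeds its limit, so
degenerate all-equal samples remove nothing. The log-transform policy for
correlation/PCA excludes the columns that can be zero or negative (longevity
skewness and kurtosis, SD and CV of age at maturity, plus LRO kurtosis in
the animal group); logs are natural, which affects neither correlations nor
standardized PCA. PCA is the eigendecomposition of the correlation matrix on
complete cases (no imputation); loadings are signed so each component's
largest-magnitude loading is positive, since PCA signs are arbitrary;
zero-variance outcome columns (a strictly age-classified ensemble has a
deterministic age at maturity) are dropped with a recorded note rather than
poisoning the correlation matrix.

The variance decomposition weights populations equally — database entries
are exchangeable samples, not census-weighted units — which makes
$V_{total} = V_{within} + V_{between}$ an exact mixture identity when
$V_{between}$ is the divide-by-$n$ variance of the means; the intraclass
coefficient is $K = V_b/(V_b + V_w)$.

## The synthetic-data generator

`generate_ensemble()` emulates the two broad classes in comparative MPM
databases: *animal-like* age-classified (Leslie) models of dimension 5–69
(survival on the subdiagonal, death after the final class, reproduction from
a maturity age onward) and *plant-like* stage-classified models of dimension
5–26 (stasis on the diagonal, growth below, shrinkage above, elevated
seedling mortality, reproduction from the later stages into stage 1). An
ensemble draws one archetype and then varies populations around it: survival
shifted on the logit scale, dimension jittered, and the net reproductive
rate $R_0$ scaled on the log scale, all with spread `between_sd` (shifts
truncated at $2\sigma$ — populations of a species differ in rates, not in
orders of magnitude). Setting `between_sd = 0` collapses the ensemble to
identical copies, the planted null under which the intraclass coefficient
must vanish.

Two calibration choices matter and are deliberate:

* **Ensembles sit near demographic replacement.** Fertilities are rescaled
  so each population's $R_0$ is lognormal around its archetype's value
  (drawn between 0.5 and 3). Published populations persist, so their mean
  LRO hovers near 1; this anchors the generated trait distributions at
  realistic magnitudes (median LRO mean ≈ 1, plant OFS medians in the
  tens-to-hundreds, animal OFS medians around 5).
* **Presets stay inside the moment-estimable regime.** Life cycles that
  combine enormous per-stage fecundity with minuscule establishment generate
  LRO kurtosis of $10^5$ and beyond; such models are exactly what the
  quartile outlier screen exists to remove, and their 4th moments cannot be
  checked against any feasible simulated cohort (the estimator is dominated
  by individuals that occur a handful of times in $10^5$ draws). The presets
  are therefore calibrated to the central mass of screened comparative data,
  not to its pathological tail.

`generate_planted_traits()` synthesizes trait tables with three planted
orthogonal factors (life-cycle length; LRO/longevity uncertainty;
reproductive timing) for testing PCA recovery. Factor scores are whitened
in-sample — otherwise chance correlations between factors of similar
strength rotate the leading eigenvectors inside their shared subspace — and
the factor strengths (SDs 3, 1.8, 1.1 against noise SD 0.3) are spaced so
the three components are identifiable at a few hundred rows.

What the generator does *not* emulate: phylogenetic and geographic
structure, correlated metadata quirks of real databases, multiple offspring
types with distinct demographies, clonality, two-sex dynamics, and
environmental stochasticity. Passing tests on synthetic ensembles therefore
validate the *mathematics and conventions*, not the biology of any
particular database subset.

## The simulation oracle and its standard errors

`simulate_cohort()` follows each of $n$ individuals step by step (Poisson
offspring at the current age, then a multinomial transition including the
death mass) and records longevity, LRO, offspring-age sums and maturity age.
`oracle_compare()` z-scores every analytic statistic against its simulated
counterpart and passes at $|z| \le 4$.

The standard errors are *exact*, computed from the model rather than the
sample: raw moments of longevity to order 8 via the binomial-moment identity
$E\binom{T}{k} = \mathbf{1}^\top\mathbf{U}^{k-1}\mathbf{N}^k\mathbf{e}$,
raw moments of LRO to order 8 via the reward recursion, and the closed-form
covariance of the per-individual offspring-age sums
$(\sum_t t k_t, \sum_t t^2 k_t, \sum_t k_t)$ for the generation-time and
parity ratios, all pushed through the delta method. The reason is not
elegance: for heavy-tailed outcomes a cohort that misses its rare tail
underestimates a skewness or kurtosis *and* its bootstrap standard error
together, producing confident-looking false alarms; SEs computed from the
model's own 8th moments keep the z-tests calibrated. Every closed form used
here is itself verified in the test suite against truncated-series brute
force at $10^{-10}$ tolerances. With several hundred simultaneous z-tests,
the suite retests a lone failing statistic once on an independent larger
cohort: estimator-skew flukes do not recur, while a genuine convention error
grows with $\sqrt{n}$ and fails both times (demonstrated by the
withheld-death-reward sensitivity check).

## Numerical choices

Column sums of $\mathbf{U}$ may exceed 1 by at most $10^{-8}$; anything
larger is an error unless survival-excess rescaling is explicitly requested
(proportional rescaling to 1, recorded as a flag). The fundamental matrix is
computed by a dense solve guarded by an exact condition-number estimate
(hard failure above $10^{12}$, far looser than the screening filter).
Variances arising from moment cancellation are clipped to zero silently
below $10^{-12}$ (relative), with a warning up to $10^{-9}$, and are hard
errors beyond that; CV, OFS, skewness and kurtosis are reported as missing
when their denominators vanish. Trait tables and model files print numbers
with 17 significant digits so JSON round-trips are bit-exact and CSV
round-trips are exact to one ulp.

## Problem sizes used by the tests

The suite runs round-trip properties over hundreds of random models,
stochastic-matrix properties over 1000 random chains, the $R_0$ identity
over 1000 random models, oracle equivalence over 20 models per generator
preset at $10^5$ individuals each, the mixture identity over a 10-population
ensemble ($2\times10^4$ pooled, $10^5$ per population for the planted null),
outlier-screen recovery on an 80-model ensemble, and PCA recovery on 500
planted trait rows. These sizes give sub-percent Monte Carlo resolution on
first and second moments while keeping the full suite under a minute of
simulation time.

## Known limitations

* Models whose LRO distribution is dominated by ultra-rare events (analytic
  kurtosis $\gtrsim 10^4$) are outside the regime where simulation can
  confirm 3rd/4th moments; the analytics still apply, but their tail output
  should be interpreted as model-implied, not simulation-verified.
* The condition-number filter cannot flag a $1\times1$ near-immortal model
  (its condition number is identically 1); such models are implausible
  inputs and are caught by the minimum-stage rule in the pipeline.
* Multiple offspring types are summed before analysis; type-resolved reward
  vectors and clonal reproduction are out of scope.
* The eligibility screen honors metadata flags present in the input; it
  cannot reconstruct judgment calls (what counts as "natural") made by
  database curators.
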