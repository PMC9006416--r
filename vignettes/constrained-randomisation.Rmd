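---
title: "Covariate constrained randomisation for parallel cluster randomised trials: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate constrained randomisation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccrsim)
```

## The design problem

Cluster randomised trials (CRTs) typically randomise few units — often ten
to thirty clusters. With so few units, simple randomisation can by chance
produce arms that differ badly on known cluster-level prognostic factors,
and stratified randomisation fails because most strata are empty or hold a
single cluster. The packaged ten-emergency-department table illustrates
this: three binary covariates define eight strata, only two of which hold
more than one cluster (`form_strata(ed_covariates())`).

Covariate constrained randomisation addresses this globally rather than
stratum by stratum. The *randomisation space* of a `2K`-cluster, 1:1 trial
is the set of all `choose(2K, K)` equal splits (an allocation and its
arm-swapped mirror are distinct members). Each scheme is scored for
balance, the best-balanced fraction is kept as the *candidate set*, and the
trial's allocation is drawn uniformly from it. A candidate fraction of 1 is
simple randomisation. `ccrsim` simulates this whole pipeline — covariates,
randomisation, outcomes, analysis — to estimate the power and type I error
consequences of the design choices.

## The balance metric

Balance is scored with the Raab–Butcher metric

$$B = \sum_{c=1}^{C} \omega_c\,(\bar z_{1c} - \bar z_{0c})^2,$$

the weighted sum over the `C` balanced covariates of the squared difference
in arm means, with weights `omega_c` the inverse variance of the covariate's
cluster values. Smaller is better; `B = 0` exactly when the arms have equal
means on every covariate, and `B` is invariant to swapping arm labels.

Numerical conventions, all deterministic and tested against brute-force
oracles:

* **Variance divisor.** The weights use the sample variance (divisor
  `2K - 1`) by default; the population divisor is available
  (`covariate_weights(..., divisor = "population")`). Since the choice
  rescales every weight by the same factor, candidate sets are identical
  under either convention.
* **Candidate-set size.** `round(fraction * n)` with half away from zero,
  minimum one scheme. Decile fractions of decile-divisible spaces are then
  exact: 10% of the 12,870 schemes of a 16-cluster trial is 1,287; 10% of
  the 70 schemes of an 8-cluster trial is 7; 10% of the 252 schemes of the
  ten-cluster example is 25.
* **Ties.** Binary covariates give `B` finitely many values, so ties at the
  cut are common. Schemes are ordered by `(score, lexicographic assignment
  vector)`, making every candidate set a deterministic function of the
  covariate table. The set is defined by scheme *count*, not by a score
  quantile (for the example table the two definitions give numerically
  indistinguishable operating characteristics).
* **Enumeration threshold.** Spaces with at most 20,000 schemes are
  enumerated completely (`utils::combn`); larger spaces are sampled.
  Sampling draws scheme *ranks* uniformly without replacement and unranks
  them through the combinatorial number system, so the capped space is an
  exactly uniform, duplicate-free sample of the full space — no
  rejection/deduplication loop, and exact for spaces up to $2^{53}$
  schemes.

## The data-generating model

Outcomes for individual `i` in cluster `j` follow

$$Y_{ij} = z_j^\top \gamma + \theta X_j + \alpha_j + \varepsilon_{ij},
\qquad \alpha_j \sim N(0, \sigma_b^2),\quad
\varepsilon_{ij} \sim N(0, \sigma_e^2),$$

with cluster-level binary covariates `z_j`, treatment indicator `X_j`, and
the intra-cluster correlation parameterised as
$\rho = \sigma_b^2 / (\sigma_b^2 + \sigma_e^2)$, i.e.
$\sigma_b^2 = \sigma_e^2 \rho/(1-\rho)$ with $\sigma_e^2 = 1$.

Defaults mirror the reference study conditions: clusters of `M = 300`
individuals; 5, 9 or 13 clusters per arm; `rho` in 0.001–0.1; four
independent Bernoulli(0.3) covariates, each with prognostic coefficient
`gamma = 2`; treatment effects 0 (size) or 0.5 / 0.25 / 0.2 (power, scaled
down for the larger trials so power stays below 100%). `scenario_grid()`
builds the full factorial grids; every generating covariate is prognostic
regardless of how many are balanced (`C`) or adjusted (`A`), and when
`C, A < L` the *first* columns are used, so the balanced set nests in the
adjusted set.

What the generator emulates — and does not. It reproduces cross-sectional
two-arm parallel CRTs with equal cluster sizes, exchangeable within-cluster
correlation, Gaussian outcomes, and binary cluster-level covariates acting
linearly. It does not emulate unequal or informative cluster sizes,
individual-level or continuous covariates, non-Gaussian outcomes, or
secular trends, so passing tests certify the method's operating
characteristics under the model, not under arbitrary real data.

## Analysis: REML with Satterthwaite degrees of freedom

Each simulated trial is analysed with a random-intercept linear mixed model
(fixed effects: intercept, treatment, the `A` adjusted covariates), fitted
by restricted maximum likelihood with $\sigma_b^2 \ge 0$ enforced, and the
treatment effect tested by $F = (\hat\theta/\mathrm{se})^2$ on
$(1, \nu)$ degrees of freedom with the Satterthwaite approximation

$$\nu = \frac{2\,[\widehat{\mathrm{Var}}(\hat\theta)]^2}
            {\widehat{\mathrm{Var}}[\widehat{\mathrm{Var}}(\hat\theta)]},$$

the denominator obtained by the delta method: the gradient of
$\mathrm{Var}(\hat\theta)$ with respect to $(\sigma_b^2, \sigma_e^2)$
combined with the inverse *expected* REML information of the variance
components. Implementation choices:

* **Reduction to cluster level.** With cluster-level covariates the
  restricted likelihood depends on the data only through cluster means,
  cluster sizes and the pooled within-cluster sum of squares, so all
  fitting is `O(J)`–`O(J^2)` in the number of clusters.
* **Balanced closed form.** With equal cluster sizes the restricted
  likelihood separates and the ANOVA estimators
  $\hat\sigma_e^2 = \mathrm{SSW}/(N-J)$,
  $\hat\sigma_b^2 + \hat\sigma_e^2/M = \mathrm{RSS}_{\bar y}/(J-p)$ are the
  exact REML solution; the fit is closed form and the delta-method `nu`
  reduces *exactly* to the cluster-level residual degrees of freedom
  `2K - 2 - A`. This makes `fit_cluster_means()` — ordinary least squares
  on the cluster means via `stats::lm()` — an algebraically exact oracle
  for the mixed model on balanced data, and the package's central
  correctness test.
* **Unbalanced data** use the profiled criterion over
  $\log(\sigma_b^2/\sigma_e^2)$ (`stats::optimize`, tolerance `1e-9`,
  boundary checked against the $\sigma_b^2 = 0$ criterion value). Estimates
  agree with `lme4` to optimiser precision. Away from balance the
  Satterthwaite convention matters slightly: `ccrsim` uses the expected
  information, implementations based on a numerically differentiated
  restricted likelihood use the observed one; the two differ by a few
  percent in `nu` for mildly unbalanced data and coincide at balance.
* **Boundary fits.** When $\hat\sigma_b^2 = 0$ the model degenerates to
  pooled ordinary least squares; the fit is retained with `nu = N - p` and
  flagged (`boundary = TRUE`). Dropping such replicates would bias
  rejection rates; retaining them is also the mechanism that makes the
  test conservative at very small intra-cluster correlations.
* **Identifiability.** If the selected allocation is exactly collinear with
  an adjusted covariate (possible only for covariates splitting the
  clusters `K:K`), the treatment effect is unidentifiable and the fit
  raises a classed singular-design error. The Monte Carlo engine records
  such replicates as failed. This is not hypothetical: in the
  ten-emergency-department table the mental-health-team indicator splits
  the clusters 5:5, the two allocations identical to it (or its mirror) lie
  *inside* the worst-10% candidate set, and about 8% of worst-10% draws are
  therefore unanalysable under full adjustment — an under-appreciated
  hazard of deliberately badly balanced allocations.

## The Monte Carlo engine

Each replicate draws a covariate table (afresh by default), builds and
scores the randomisation space, cuts the candidate set, selects a scheme,
generates outcomes, fits the adjusted model and records rejection at
two-sided 5%. Design choices:

* **Covariate redraw.** By default a fresh covariate table is drawn every
  replicate, so a scenario's power is averaged over covariate
  configurations; `covariate_mode = "fixed"` (required for randomising a
  real table) conditions on one table. The choice matters: conditional
  best-minus-worst gaps vary substantially across covariate draws.
* **Degenerate tables** (zero-variance or rank-deficient balanced/adjusted
  columns) are redrawn with a tally — at ten clusters with Bernoulli(0.3)
  covariates this is common enough to matter.
* **Random streams.** A scenario seed derives one substream seed per
  replicate, so results are bit-reproducible and independent of execution
  order and worker count.
* **Failed replicates** are excluded from the denominator and counted;
  `estimate_operating_characteristics()` refuses scenarios with more than
  0.1% failures, while `compare_candidate_sets()` reports per-setting
  failure counts (the worst-10% identifiability hazard above makes this
  unavoidable for the example table).
* **Common random numbers.** `compare_candidate_sets()` shares the
  covariate table, the sampled space and the outcome noise across the
  settings being compared, changing no marginal power but sharpening the
  power *differences*; `power_difference()` reports both the paired and the
  independent-runs standard error.

## Problem sizes used for verification

The package's own test suite and acceptance script run desk-scale versions
of the full study: candidate-set combinatorics and balance scoring are
checked exhaustively on spaces up to 12 clusters against brute-force
oracles; REML/cluster-means equivalence is exact on every balanced dataset
tried; operating characteristics use 2,000–10,000 replicates (Monte Carlo
standard errors of 0.5–1.6 percentage points on power differences) rather
than the 20,000 of a full production run, with 3-standard-error criteria.
`mc_se(0.05, 20000)` confirms the production-scale precision of about
0.002 for the type I error. The 26-cluster comparison (ICC 0.05, effect
0.2, all four covariates balanced and adjusted) yields a best-10% minus
worst-10% gain of about 15 percentage points and a best-10% minus simple
gain of about 5 points at these scales; for the fixed ten-department table
(ICC 0.1, effect 0.5) the corresponding gains are about 29 and 11 points —
large, because with only ten clusters the treatment-covariate collinearity
penalty of a badly balanced allocation is severe. An independent analytic
route (noncentral-F power of the cluster-means model, averaged over each
candidate set) reproduces the fixed-table figures to within Monte Carlo
error, so they are properties of the stated configuration, not simulation
artefacts.

## Known limitations

Only 1:1 allocation, equal cluster sizes, continuous outcomes and binary
cluster-level covariates are supported. The B metric extends naturally to
continuous covariates, but weights and degenerate-column handling would
need revisiting. Whether a candidate set leaves some cluster pairs always
co-assigned (allocation predictability) is not diagnosed. Sequentially
recruited clusters, stepped-wedge and crossover designs are out of scope.
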