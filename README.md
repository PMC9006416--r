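# ccrsim

Covariate constrained randomisation and Monte Carlo power evaluation for
two-arm parallel cluster randomised trials (CRTs) with continuous outcomes
and binary cluster-level covariates.

CRTs randomise few units, so chance covariate imbalance between arms is a
real hazard, and stratified randomisation collapses when a handful of
binary covariates define mostly-empty strata. Covariate constrained
randomisation scores every equal split of the `2K` clusters with the
Raab–Butcher balance metric

$$B = \sum_{c} \omega_c\,(\bar z_{1c} - \bar z_{0c})^2,
\qquad \omega_c = 1/\mathrm{Var}(z_c),$$

keeps the best-balanced fraction of the randomisation space as the
*candidate set*, and draws the trial's allocation uniformly from it.
`ccrsim` is for trial statisticians who need to (a) actually randomise a
trial this way and (b) quantify, by simulation, what the constraint buys
in power — and costs in type I error — under the linear mixed
data-generating model

$$Y_{ij} = z_j^\top\gamma + \theta X_j + \alpha_j + \varepsilon_{ij},
\qquad \rho = \sigma_b^2/(\sigma_b^2 + \sigma_e^2),$$

with each simulated trial analysed by a restricted-maximum-likelihood
random-intercept model and an F-test on Satterthwaite degrees of freedom
(small-sample corrected).

The package covers: complete enumeration or exact uniform sampling (cap
20,000) of the randomisation space; balance scoring and deterministic
best/worst candidate sets; outcome simulation; a fast closed-form REML fit
with delta-method Satterthwaite degrees of freedom (plus an exact
cluster-means oracle for verification); and a Monte Carlo engine with
per-replicate substreams, common-random-number comparisons of candidate-set
settings, and factorial scenario grids.

## Worked example: the ten-emergency-department trial

Ten emergency departments are to be randomised 1:1 to an acute
mental-healthcare bundle or standard care, with three binary cluster-level
covariates known up front (packaged as `ed_covariates()`).

```r
library(ccrsim)
res <- cmd_randomise(example = TRUE, fraction = 0.1, side = "best", seed = 2026)
#> Randomisation space: 252 schemes (complete)
#> Candidate set: best 10% = 25 schemes; B range [0.144, 0.144]
#> Selected allocation (B = 0.144 ):
#>   intervention: 1, 4, 7, 8, 9
#>   control:      2, 3, 5, 6, 10
#>
#> Strata a stratified randomisation would need:
#>  patient_volume mh_team urgent_followup n_clusters
#>               1       1               1          1
#>               1       1               0          2
#>               1       0               1          1
#>               1       0               0          0
#>               0       1               1          1
#>               0       1               0          1
#>               0       0               1          1
#>               0       0               0          3
#> (2 of 8 strata contain more than one cluster)
```

Reading: the full space has `choose(10, 5) = 252` allocations; the best
decile (25 schemes, all tied at the minimal balance score B = 0.144) is the
candidate set, and one member is selected at random. The strata table shows
why stratification is hopeless here — six of the eight strata hold at most
one cluster.

Was constraining worth it? Compare candidate-set settings under common
random numbers, with the department table fixed, an intra-cluster
correlation of 0.1, a standardised treatment effect of 0.5 and prognostic
coefficient 2 per covariate, all three covariates balanced and adjusted:

```r
cfg <- scenario_config(k_per_arm = 5, icc = 0.1, theta = 0.5,
                       covariates = ed_covariates(), covariate_mode = "fixed",
                       n_balanced = 3, n_adjusted = 3, n_reps = 2000, seed = 1)
comp <- compare_candidate_sets(cfg)
comp
#> Candidate-set comparison (common random numbers)
#>  fraction  side  power    mc_se n_used n_failed
#>       0.1  best 0.4785 0.011170   2000        0
#>       1.0   all 0.3516 0.010709   1988       12
#>       0.1 worst 0.1705 0.008762   1842      158

power_difference(comp, 1, 2)
#>    diff_pp se_paired_pp se_independent_pp
#> 1 12.68903     1.365267          1.547408
```

Reading: randomising within the best decile gives 47.9% power versus 35.2%
averaged over simple randomisation (a gain of 12.7 percentage points,
paired MC standard error 1.4) and versus 17.1% for the worst decile. The
`n_failed` column is itself a finding: 158 of 2,000 worst-decile replicates
selected one of the two allocations exactly collinear with the
`mh_team` covariate, leaving the treatment effect unidentifiable under full
adjustment — deliberately badly balanced allocations can be unanalysable,
not just inefficient.

A shell front end wraps the same functions
(`Rscript inst/cli/ccrsim.R randomise --example --fraction 0.1 --side best`,
`... power --config inst/extdata/motivating_example.yaml --reps 2000 --out out/`),
and `scenario_grid()` + `run_grid()` sweep the full factorial simulation
designs. See the vignette in `vignettes/constrained-randomisation.Rmd` for
the model, algorithms and design decisions.

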