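test_that("scenario configuration validates its invariants", {
  expect_error(scenario_config(k_per_arm = 9, icc = 0.05, theta = 0,
                               n_balanced = 5),
               class = "ccrsim_invalid_input")
  expect_error(scenario_config(k_per_arm = 9, icc = 0.05, theta = 0,
                               candidate_fraction = 0.5,
                               candidate_side = "all"),
               class = "ccrsim_invalid_fraction")
  expect_error(scenario_config(k_per_arm = 5, icc = 0.05, theta = 0,
                               covariate_mode = "fixed"),
               class = "ccrsim_invalid_input")
  cfg <- scenario_config(k_per_arm = 9, icc = 0.05, theta = 0.5)
  expect_equal(cfg$candidate_side, "all")
  expect_equal(cfg$gamma, rep(2, 4))
  # fixed tables set the generating covariate count
  cfg2 <- scenario_config(k_per_arm = 5, icc = 0.1, theta = 0.5,
                          covariates = ed_covariates(),
                          covariate_mode = "fixed", n_balanced = 3,
                          n_adjusted = 3)
  expect_equal(cfg2$n_covariates_model, 3L)
})

test_that("replicates are reproducible and carry the audit fields", {
  cfg <- scenario_config(k_per_arm = 5, icc = 0.05, theta = 0.5,
                         candidate_fraction = 0.1, candidate_side = "best",
                         n_reps = 100, seed = 3)
  r1 <- run_replicate(cfg, seed = 77)
  r2 <- run_replicate(cfg, seed = 77)
  expect_identical(r1, r2)
  expect_named(r1, c("reject", "p_value", "theta_hat", "satt_df", "balance",
                     "boundary", "converged", "redraws", "failed"))
  expect_false(r1$failed)
  expect_gte(r1$balance, 0)
})

test_that("operating-characteristic estimates are seed-deterministic", {
  cfg <- scenario_config(k_per_arm = 5, icc = 0.1, theta = 0.5,
                         cluster_size = 20, n_reps = 150, seed = 11,
                         candidate_fraction = 0.2, candidate_side = "best")
  s1 <- estimate_operating_characteristics(cfg)
  s2 <- estimate_operating_characteristics(cfg)
  expect_equal(s1$rejection_proportion, s2$rejection_proportion)
  expect_equal(s1$n_effective + s1$n_failed, cfg$n_reps)
  expect_equal(s1$mc_se,
               sqrt(s1$rejection_proportion * (1 - s1$rejection_proportion) /
                      s1$n_effective))
})

test_that("the Monte Carlo standard error follows binomial scaling", {
  expect_equal(mc_se(0.05, 20000), sqrt(0.05 * 0.95 / 20000))
  expect_equal(mc_se(0, 500), 0)
  expect_equal(mc_se(1, 500), 0)
  expect_equal(mc_se(0.3, 2000) / mc_se(0.3, 4000), sqrt(2))
})

test_that("simple randomisation with a non-prognostic covariate matches analytic power", {
  # with gamma = 0 and no adjustment every equal split has the same
  # non-centrality, so the cluster-means F test has closed-form power
  theta <- 0.35
  icc <- 0.1
  J <- 10; M <- 100
  tau <- icc / (1 - icc) + 1 / M
  ncp <- theta^2 / (tau * 4 / J)
  analytic <- stats::pf(stats::qf(0.95, 1, J - 2), 1, J - 2, ncp,
                        lower.tail = FALSE)
  cfg <- scenario_config(k_per_arm = J / 2, icc = icc, theta = theta,
                         cluster_size = M, n_covariates_model = 1,
                         gamma = 0, n_adjusted = 0, n_reps = 1200,
                         seed = 19, analysis = "cluster_means")
  s <- estimate_operating_characteristics(cfg)
  expect_lt(abs(s$rejection_proportion - analytic), 3 * s$mc_se)
})

test_that("REML and cluster-means analyses give identical rejection decisions", {
  base <- list(k_per_arm = 5, icc = 0.1, theta = 0.5, cluster_size = 30,
               n_reps = 150, seed = 23, candidate_fraction = 0.2,
               candidate_side = "best")
  s_reml <- estimate_operating_characteristics(
    do.call(scenario_config, c(base, analysis = "reml")))
  s_cm <- estimate_operating_characteristics(
    do.call(scenario_config, c(base, analysis = "cluster_means")))
  expect_equal(s_reml$rejection_proportion, s_cm$rejection_proportion)
})

test_that("candidate-set comparisons share replicates and report paired contrasts", {
  cfg <- scenario_config(k_per_arm = 5, icc = 0.1, theta = 0.5,
                         cluster_size = 20, n_reps = 200, seed = 31)
  comp <- compare_candidate_sets(
    cfg, settings = data.frame(fraction = c(0.1, 0.1, 1),
                               side = c("best", "best", "all")))
  expect_equal(dim(comp$rejections), c(200L, 3L))
  d_self <- power_difference(comp, 1, 1)
  expect_equal(d_self$diff_pp, 0)
  expect_equal(d_self$se_paired_pp, 0)
  d <- power_difference(comp, 1, 3)
  expect_lte(d$se_paired_pp, d$se_independent_pp + 1e-9)
  # marginal powers are reproducible
  comp2 <- compare_candidate_sets(
    cfg, settings = data.frame(fraction = c(0.1, 0.1, 1),
                               side = c("best", "best", "all")))
  expect_equal(comp$settings$power, comp2$settings$power)
})

test_that("allocations collinear with an adjusted covariate become failed replicates", {
  # in the fixed emergency-department table the two allocations identical to
  # the mental-health-team indicator (or its mirror) sit in the worst-10%
  # set; adjusting for that covariate makes the effect unidentifiable there
  cfg <- scenario_config(k_per_arm = 5, icc = 0.1, theta = 0.5,
                         cluster_size = 10,
                         covariates = ed_covariates(),
                         covariate_mode = "fixed",
                         n_balanced = 3, n_adjusted = 3, n_reps = 300,
                         seed = 37)
  comp <- compare_candidate_sets(
    cfg, settings = data.frame(fraction = c(0.1, 0.1),
                               side = c("best", "worst")))
  expect_equal(comp$settings$n_failed[1], 0)        # best set is identifiable
  expect_gt(comp$settings$n_failed[2], 0)           # worst set is not, ~8%
  expect_lt(comp$settings$n_failed[2], 0.25 * 300)
})

test_that("grid sweeps return one summary row per cell and respect worker counts", {
  expect_equal(nrow(run_grid(data.frame())), 0)
  # unadjusted analysis keeps every allocation identifiable at 10 clusters
  grid <- data.frame(k_per_arm = 5, cluster_size = 10, icc = 0.1,
                     theta = c(0, 1), n_covariates_model = 2, gamma = 2,
                     covariate_prob = 0.3, n_balanced = 2,
                     candidate_fraction = c(0.2, 1),
                     candidate_side = c("best", "all"), n_adjusted = 0)
  r1 <- run_grid(grid, n_reps = 120, seed = 41)
  expect_equal(nrow(r1), 2)
  expect_true(all(c("rejection_proportion", "mc_se", "n_effective",
                    "n_failed") %in% names(r1)))
  expect_gt(r1$rejection_proportion[2], r1$rejection_proportion[1])
  r2 <- run_grid(grid, n_reps = 120, seed = 41, workers = 2)
  expect_equal(r1, r2)
})
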