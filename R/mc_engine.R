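#' Configure one simulation scenario
#'
#' Bundles every knob of one Monte Carlo cell: the design (clusters per arm,
#' cluster size), the generating model (ICC, treatment effect, number and
#' strength of prognostic covariates), the randomisation (how many
#' covariates are balanced, candidate-set fraction and side, scheme cap) and
#' the analysis (how many covariates are adjusted). Defaults follow the
#' package's reference simulation study: clusters of 300, Bernoulli(0.3)
#' covariates with prognostic coefficient 2, a 20,000-scheme cap, two-sided
#' 5% tests and 20,000 replicates.
#'
#' When `n_balanced` or `n_adjusted` is smaller than the number of
#' generating covariates, the first columns (in covariate order) are the
#' ones balanced/adjusted, so the balanced set is nested in the adjusted set
#' whenever `n_balanced <= n_adjusted`.
#'
#' @param k_per_arm Clusters per arm (K); the trial randomises `2 * K`.
#' @param icc Intra-cluster correlation of the generating model.
#' @param theta Treatment effect (0 for type I error scenarios).
#' @param cluster_size Individuals per cluster (default 300).
#' @param n_covariates_model Number of covariates in the generating model, L.
#' @param gamma Prognostic coefficient(s), recycled to length L (default 2).
#' @param covariate_prob Bernoulli probability of the covariates (default 0.3).
#' @param n_balanced Number of covariates balanced in the randomisation, C
#'   (first C columns). Ignored under simple randomisation.
#' @param candidate_fraction Candidate-set fraction in (0, 1]; 1 is simple
#'   randomisation.
#' @param candidate_side `"best"`, `"worst"` or `"all"` (the latter only with
#'   fraction 1).
#' @param n_adjusted Number of covariates adjusted in the analysis, A (first
#'   A columns; 0 for an unadjusted analysis).
#' @param n_reps Monte Carlo replicates (default 20,000).
#' @param seed Scenario seed; every replicate derives its own substream.
#' @param covariate_mode `"redraw"` (a fresh covariate table every replicate,
#'   the default, which averages over covariate configurations) or `"fixed"`
#'   (use `covariates` in every replicate, as when randomising a real trial).
#' @param covariates Covariate table, required when `covariate_mode = "fixed"`.
#' @param alpha Two-sided rejection threshold (default 0.05).
#' @param scheme_cap Randomisation-space cap: enumerate completely when the
#'   space has at most this many schemes, otherwise sample this many
#'   (default 20,000).
#' @param analysis `"reml"` (mixed model with Satterthwaite df, default) or
#'   `"cluster_means"` (the exactly equivalent cluster-level OLS for these
#'   balanced designs).
#' @param max_redraws Retry limit for degenerate covariate tables (a
#'   zero-variance or rank-deficient set of balanced/adjusted columns is
#'   redrawn; default 1000).
#' @return A `scenario_config` list.
#' @examples
#' cfg <- scenario_config(k_per_arm = 9, icc = 0.05, theta = 0.5,
#'                        candidate_fraction = 0.1, candidate_side = "best",
#'                        n_reps = 200, seed = 7)
#' @export
scenario_config <- function(k_per_arm, icc, theta,
                            cluster_size = 300,
                            n_covariates_model = 4L,
                            gamma = 2,
                            covariate_prob = 0.3,
                            n_balanced = n_covariates_model,
                            candidate_fraction = 1,
                            candidate_side = c("all", "best", "worst"),
                            n_adjusted = n_covariates_model,
                            n_reps = 20000L,
                            seed = 1L,
                            covariate_mode = c("redraw", "fixed"),
                            covariates = NULL,
                            alpha = 0.05,
                            scheme_cap = 20000L,
                            analysis = c("reml", "cluster_means"),
                            max_redraws = 1000L) {
  candidate_side <- match.arg(candidate_side)
  covariate_mode <- match.arg(covariate_mode)
  analysis <- match.arg(analysis)
  k_per_arm <- as.integer(k_per_arm)
  if (k_per_arm < 2L) {
    ccrsim_error("`k_per_arm` must be >= 2", "ccrsim_invalid_design")
  }
  if (covariate_mode == "fixed") {
    if (is.null(covariates)) {
      ccrsim_error("covariate_mode = \"fixed\" requires a `covariates` table",
                   "ccrsim_invalid_input")
    }
    covariates <- as_covariate_table(covariates)
    if (nrow(covariates) != 2L * k_per_arm) {
      ccrsim_error("fixed covariate table must have one row per cluster",
                   "ccrsim_invalid_input")
    }
    n_covariates_model <- ncol(covariates)
  }
  n_covariates_model <- as.integer(n_covariates_model)
  if (length(gamma) == 1L) gamma <- rep(gamma, n_covariates_model)
  if (length(gamma) != n_covariates_model) {
    ccrsim_error("`gamma` must have one coefficient per generating covariate",
                 "ccrsim_invalid_input")
  }
  if (n_balanced > n_covariates_model || n_adjusted > n_covariates_model) {
    ccrsim_error("`n_balanced` and `n_adjusted` cannot exceed the number of generating covariates",
                 "ccrsim_invalid_input")
  }
  if (candidate_fraction < 1 && candidate_side == "all") {
    ccrsim_error("candidate_side = \"all\" requires candidate_fraction = 1",
                 "ccrsim_invalid_fraction")
  }
  if (candidate_fraction == 1) candidate_side <- "all"
  if (candidate_fraction < 1 && n_balanced < 1L) {
    ccrsim_error("constrained randomisation needs `n_balanced` >= 1",
                 "ccrsim_invalid_input")
  }
  structure(
    list(k_per_arm = k_per_arm, cluster_size = as.integer(cluster_size),
         icc = icc, theta = theta,
         n_covariates_model = n_covariates_model, gamma = gamma,
         covariate_prob = covariate_prob,
         n_balanced = as.integer(n_balanced),
         candidate_fraction = candidate_fraction,
         candidate_side = candidate_side,
         n_adjusted = as.integer(n_adjusted),
         n_reps = as.integer(n_reps), seed = as.integer(seed),
         covariate_mode = covariate_mode, covariates = covariates,
         alpha = alpha, scheme_cap = as.integer(scheme_cap),
         analysis = analysis, max_redraws = as.integer(max_redraws)),
    class = "scenario_config")
}

config_params <- function(config) {
  outcome_params(gamma = config$gamma, theta = config$theta,
                 icc = config$icc,
                 n_covariates = config$n_covariates_model,
                 cluster_size = config$cluster_size,
                 covariate_prob = config$covariate_prob)
}

# Columns whose degeneracy would break the replicate: balanced columns need
# non-zero variance (for the weights), adjusted columns must form a
# full-rank cluster-level design with the intercept.
covariates_usable <- function(z, config) {
  used <- seq_len(max(config$n_balanced, config$n_adjusted))
  if (!length(used)) return(TRUE)
  v <- apply(z[, used, drop = FALSE], 2L, stats::var)
  if (any(v <= 0)) return(FALSE)
  if (config$n_adjusted > 0L) {
    Xa <- cbind(1, z[, seq_len(config$n_adjusted), drop = FALSE])
    if (qr(Xa)$rank < ncol(Xa)) return(FALSE)
  }
  TRUE
}

# Per-scenario immutable preparation: a cached enumerated scheme matrix when
# the space is small enough, and (for fixed covariate tables) the scored
# space and candidate set, which never change across replicates.
prep_scenario <- function(config) {
  prep <- list(constrained = config$candidate_fraction < 1)
  if (!prep$constrained) return(prep)
  n_cl <- 2L * config$k_per_arm
  prep$enumerable <- choose(n_cl, config$k_per_arm) <= config$scheme_cap
  if (prep$enumerable) {
    prep$schemes <- enumerate_schemes(n_cl, max_schemes = config$scheme_cap)$schemes
  }
  if (config$covariate_mode == "fixed" && prep$enumerable) {
    zc <- config$covariates[, seq_len(config$n_balanced), drop = FALSE]
    sp <- score_space(new_randomisation_space(prep$schemes, TRUE), zc)
    prep$fixed_candidate <- build_candidate_set(sp, config$candidate_fraction,
                                                config$candidate_side)
  }
  prep
}

draw_covariates_for <- function(config) {
  if (config$covariate_mode == "fixed") {
    return(list(z = config$covariates, redraws = 0L))
  }
  n_cl <- 2L * config$k_per_arm
  redraws <- 0L
  repeat {
    z <- generate_covariates(n_cl, config$n_covariates_model,
                             config$covariate_prob)
    if (covariates_usable(z, config)) return(list(z = z, redraws = redraws))
    redraws <- redraws + 1L
    if (redraws >= config$max_redraws) {
      ccrsim_error("covariate redraw limit reached without a usable table",
                   "ccrsim_degenerate_covariate")
    }
  }
}

draw_allocation <- function(config, prep, z) {
  n_cl <- 2L * config$k_per_arm
  if (!prep$constrained) {
    assignment <- integer(n_cl)
    assignment[sample.int(n_cl, config$k_per_arm)] <- 1L
    return(list(assignment = assignment, score = NA_real_))
  }
  cs <- prep$fixed_candidate
  if (is.null(cs)) {
    schemes <- if (isTRUE(prep$enumerable)) prep$schemes else
      sample_schemes(n_cl, cap = config$scheme_cap)$schemes
    sp <- new_randomisation_space(schemes, isTRUE(prep$enumerable))
    zc <- z[, seq_len(config$n_balanced), drop = FALSE]
    sp <- score_space(sp, zc)
    cs <- build_candidate_set(sp, config$candidate_fraction,
                              config$candidate_side)
  }
  select_scheme(cs)
}

fit_for <- function(config, dat) {
  adjust <- if (config$n_adjusted > 0L) {
    paste0("z", seq_len(config$n_adjusted))
  }
  if (config$covariate_mode == "fixed") {
    adjust <- colnames(config$covariates)[seq_len(config$n_adjusted)]
    if (config$n_adjusted == 0L) adjust <- NULL
  }
  if (config$analysis == "reml") {
    fit_lmm_reml(dat, adjust = adjust, check = FALSE)
  } else {
    fit_cluster_means(dat, adjust = adjust, check = FALSE)
  }
}

replicate_once <- function(config, prep) {
  cov <- draw_covariates_for(config)
  sel <- draw_allocation(config, prep, cov$z)
  dat <- generate_outcomes(cov$z, sel$assignment, config_params(config))
  fit <- fit_for(config, dat)
  list(reject = fit$p_value < config$alpha,
       p_value = fit$p_value, theta_hat = fit$theta_hat,
       satt_df = fit$satt_df, balance = sel$score,
       boundary = isTRUE(fit$boundary), converged = isTRUE(fit$converged),
       redraws = cov$redraws, failed = FALSE)
}

failed_record <- function(reason) {
  list(reject = NA, p_value = NA_real_, theta_hat = NA_real_,
       satt_df = NA_real_, balance = NA_real_, boundary = NA,
       converged = NA, redraws = NA_integer_, failed = TRUE,
       reason = reason)
}

#' Run one Monte Carlo replicate
#'
#' Executes the full per-replicate pipeline: draw (or reuse) the covariate
#' table, build and score the randomisation space, form the candidate set,
#' select a scheme, generate outcomes with every generating covariate
#' prognostic, fit the adjusted analysis, and record whether the treatment
#' effect was detected. Replicates whose cluster-level design turns out
#' singular (the selected allocation collinear with an adjusted covariate)
#' are returned as failed records rather than errors.
#'
#' @param config A [scenario_config()].
#' @param seed Optional replicate seed (`set.seed` is called when supplied).
#' @return List with `reject`, `p_value`, `theta_hat`, `satt_df`, the
#'   selected scheme's `balance` score, `boundary`/`converged` flags, the
#'   number of covariate `redraws`, and `failed`.
#' @export
run_replicate <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  prep <- prep_scenario(config)
  tryCatch(replicate_once(config, prep),
           ccrsim_singular_design = function(e) failed_record(conditionMessage(e)),
           ccrsim_degenerate_covariate = function(e) failed_record(conditionMessage(e)))
}

#' Monte Carlo standard error of a rejection proportion
#'
#' @param p Estimated proportion.
#' @param n Number of replicates.
#' @return `sqrt(p * (1 - p) / n)`.
#' @examples
#' mc_se(0.05, 20000)  # approximately 0.002
#' @export
mc_se <- function(p, n) sqrt(p * (1 - p) / n)

#' Estimate power or type I error for one scenario
#'
#' Runs `n_reps` independent replicates (each on its own derived random
#' substream) and aggregates the rejection proportion: Monte Carlo power
#' when `theta != 0`, type I error when `theta = 0`. Replicates that fail
#' (singular design or covariate redraw exhaustion) are excluded from the
#' denominator and counted; more than 0.1% failures aborts with
#' diagnostics.
#'
#' @param config A [scenario_config()].
#' @param progress Print a progress line every `progress` replicates
#'   (0 = silent, the default).
#' @return An `mc_summary`: `rejection_proportion`, `mc_se`, `n_effective`,
#'   `n_failed`, counts of boundary fits and covariate redraws, and the
#'   scenario configuration.
#' @export
estimate_operating_characteristics <- function(config, progress = 0) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$n_reps < 100L) {
    ccrsim_error("`n_reps` must be at least 100", "ccrsim_invalid_input")
  }
  seeds <- derive_seeds(config$seed, config$n_reps)
  prep <- prep_scenario(config)
  rejects <- logical(config$n_reps)
  failed <- logical(config$n_reps)
  boundary <- 0L
  redraws <- 0L
  for (i in seq_len(config$n_reps)) {
    set.seed(seeds[i])
    rec <- tryCatch(
      replicate_once(config, prep),
      ccrsim_singular_design = function(e) failed_record(conditionMessage(e)),
      ccrsim_degenerate_covariate = function(e) failed_record(conditionMessage(e)))
    if (rec$failed) {
      failed[i] <- TRUE
    } else {
      rejects[i] <- rec$reject
      boundary <- boundary + rec$boundary
      redraws <- redraws + rec$redraws
    }
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("scenario seed %d: replicate %d/%d", config$seed, i,
                      config$n_reps))
    }
  }
  n_failed <- sum(failed)
  n_eff <- config$n_reps - n_failed
  if (n_failed > 0.001 * config$n_reps) {
    ccrsim_error(sprintf(
      "%d of %d replicates failed (singular design or degenerate covariates); the scenario is not cleanly estimable",
      n_failed, config$n_reps), "ccrsim_too_many_failures")
  }
  p_hat <- sum(rejects[!failed]) / n_eff
  structure(
    list(rejection_proportion = p_hat, mc_se = mc_se(p_hat, n_eff),
         n_effective = n_eff, n_failed = n_failed,
         n_boundary = boundary, n_covariate_redraws = redraws,
         config = config),
    class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  kind <- if (x$config$theta == 0) "type I error" else "power"
  cat(sprintf("Monte Carlo %s: %.4f (MC se %.4f) from %s replicates\n",
              kind, x$rejection_proportion, x$mc_se,
              format(x$n_effective, big.mark = ",")))
  if (x$n_failed > 0) cat(sprintf("  failed replicates: %d\n", x$n_failed))
  if (x$n_boundary > 0) {
    cat(sprintf("  boundary variance fits: %d\n", x$n_boundary))
  }
  invisible(x)
}

#' Compare candidate-set settings under common random numbers
#'
#' Estimates the power (or type I error) of several candidate-set settings
#' of the same scenario on a shared per-replicate schedule: each replicate
#' draws one covariate table, one randomisation space and one set of outcome
#' noise, then every setting selects its own allocation and the treatment
#' effect is tested. Sharing the draws leaves each setting's marginal power
#' unchanged while sharpening the contrasts between settings.
#'
#' @param config A [scenario_config()]; its own candidate settings are
#'   ignored in favour of `settings`.
#' @param settings Data frame with columns `fraction` and `side`, one row
#'   per candidate-set setting. Defaults to best 10%, simple randomisation,
#'   and worst 10%.
#' @return A `candidate_comparison`: per-setting powers with Monte Carlo
#'   standard errors, plus the rejection matrix for paired contrasts (see
#'   [power_difference()]).
#' @export
compare_candidate_sets <- function(config,
                                   settings = data.frame(
                                     fraction = c(0.1, 1, 0.1),
                                     side = c("best", "all", "worst"))) {
  stopifnot(inherits(config, "scenario_config"))
  if (!all(c("fraction", "side") %in% names(settings))) {
    ccrsim_error("`settings` needs columns `fraction` and `side`",
                 "ccrsim_invalid_input")
  }
  n_set <- nrow(settings)
  any_constrained <- any(settings$fraction < 1)
  if (any_constrained && config$n_balanced < 1L) {
    ccrsim_error("constrained settings need `n_balanced` >= 1",
                 "ccrsim_invalid_input")
  }
  n_cl <- 2L * config$k_per_arm
  params <- config_params(config)
  enumerable <- choose(n_cl, config$k_per_arm) <= config$scheme_cap
  enum_schemes <- if (any_constrained && enumerable) {
    enumerate_schemes(n_cl, max_schemes = config$scheme_cap)$schemes
  }
  fixed_candidates <- NULL
  if (any_constrained && config$covariate_mode == "fixed" && enumerable) {
    zc <- config$covariates[, seq_len(config$n_balanced), drop = FALSE]
    sp <- score_space(new_randomisation_space(enum_schemes, TRUE), zc)
    fixed_candidates <- lapply(seq_len(n_set), function(s) {
      if (settings$fraction[s] < 1) {
        build_candidate_set(sp, settings$fraction[s],
                            as.character(settings$side[s]))
      }
    })
  }
  seeds <- derive_seeds(config$seed, config$n_reps)
  rej <- matrix(NA, config$n_reps, n_set)
  for (i in seq_len(config$n_reps)) {
    set.seed(seeds[i])
    cov <- tryCatch(draw_covariates_for(config),
                    ccrsim_degenerate_covariate = function(e) NULL)
    if (is.null(cov)) next
    z <- cov$z
    candidates <- fixed_candidates
    if (any_constrained && is.null(candidates)) {
      schemes <- if (enumerable) enum_schemes else
        sample_schemes(n_cl, cap = config$scheme_cap)$schemes
      sp <- score_space(new_randomisation_space(schemes, enumerable),
                        z[, seq_len(config$n_balanced), drop = FALSE])
      candidates <- lapply(seq_len(n_set), function(s) {
        if (settings$fraction[s] < 1) {
          build_candidate_set(sp, settings$fraction[s],
                              as.character(settings$side[s]))
        }
      })
    }
    assignments <- lapply(seq_len(n_set), function(s) {
      if (settings$fraction[s] < 1) {
        select_scheme(candidates[[s]])$assignment
      } else {
        a <- integer(n_cl)
        a[sample.int(n_cl, config$k_per_arm)] <- 1L
        a
      }
    })
    noise <- draw_trial_noise(params, n_cl)
    for (s in seq_len(n_set)) {
      dat <- generate_outcomes(z, assignments[[s]], params, noise = noise)
      fit <- tryCatch(fit_for(config, dat),
                      ccrsim_singular_design = function(e) NULL)
      if (!is.null(fit)) rej[i, s] <- fit$p_value < config$alpha
    }
  }
  n_used <- colSums(!is.na(rej))
  power <- colSums(rej, na.rm = TRUE) / n_used
  out <- data.frame(fraction = settings$fraction,
                    side = as.character(settings$side),
                    power = power, mc_se = mc_se(power, n_used),
                    n_used = n_used,
                    n_failed = config$n_reps - n_used)
  structure(list(settings = out, rejections = rej, config = config),
            class = "candidate_comparison")
}

#' Power difference between two candidate-set settings
#'
#' Difference in rejection proportions, in percentage points, between two
#' settings of a [compare_candidate_sets()] run, with two standard errors:
#' the paired one (exploiting the shared random numbers) and the
#' independent-runs one `sqrt(se_a^2 + se_b^2)` for comparison with studies
#' that estimated each setting separately.
#'
#' @param comparison A `candidate_comparison`.
#' @param a,b Row indices of the two settings (difference is `a - b`).
#' @return One-row data frame: `diff_pp`, `se_paired_pp`, `se_independent_pp`.
#' @export
power_difference <- function(comparison, a, b) {
  stopifnot(inherits(comparison, "candidate_comparison"))
  r <- comparison$rejections
  d <- r[, a] - r[, b]
  ok <- !is.na(d)
  s <- comparison$settings
  data.frame(
    diff_pp = 100 * (s$power[a] - s$power[b]),
    se_paired_pp = 100 * stats::sd(d[ok]) / sqrt(sum(ok)),
    se_independent_pp = 100 * sqrt(s$mc_se[a]^2 + s$mc_se[b]^2))
}

#' @export
print.candidate_comparison <- function(x, ...) {
  cat("Candidate-set comparison (common random numbers)\n")
  print(x$settings, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Sweep a grid of scenarios
#'
#' Runs [estimate_operating_characteristics()] for every row of a scenario
#' grid (see [scenario_grid()]) and binds the summaries into a long results
#' table. Each row gets its own seed derived from `seed`, so results are
#' reproducible and independent of the number of workers.
#'
#' @param grid Data frame of scenario cells; columns matching
#'   [scenario_config()] arguments are used, others are ignored.
#' @param n_reps Replicates per cell.
#' @param seed Grid seed.
#' @param workers Parallel workers (forked via [parallel::mclapply()]; 1 =
#'   serial).
#' @param analysis Analysis route passed to every cell.
#' @return Data frame: one row per cell with its configuration, the
#'   rejection proportion, Monte Carlo standard error and failure counts.
#' @export
run_grid <- function(grid, n_reps = 20000L, seed = 1L, workers = 1L,
                     analysis = c("reml", "cluster_means")) {
  analysis <- match.arg(analysis)
  if (nrow(grid) == 0L) {
    return(data.frame())
  }
  arg_names <- intersect(
    names(grid),
    c("k_per_arm", "cluster_size", "icc", "theta", "n_covariates_model",
      "gamma", "covariate_prob", "n_balanced", "candidate_fraction",
      "candidate_side", "n_adjusted", "alpha", "scheme_cap"))
  seeds <- derive_seeds(seed, nrow(grid))
  one_cell <- function(i) {
    args <- as.list(grid[i, arg_names, drop = FALSE])
    args$candidate_side <- as.character(args$candidate_side)
    args$n_reps <- n_reps
    args$seed <- seeds[i]
    args$analysis <- analysis
    cfg <- do.call(scenario_config, args)
    s <- estimate_operating_characteristics(cfg)
    cbind(grid[i, , drop = FALSE],
          data.frame(seed = seeds[i],
                     rejection_proportion = s$rejection_proportion,
                     mc_se = s$mc_se, n_effective = s$n_effective,
                     n_failed = s$n_failed, n_boundary = s$n_boundary))
  }
  rows <- if (workers > 1L) {
    parallel::mclapply(seq_len(nrow(grid)), one_cell, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(grid)), one_cell)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
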