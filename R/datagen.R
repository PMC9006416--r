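#' Outcome model parameters
#'
#' Bundles the parameters of the individual-level data-generating model
#' \deqn{Y_{ij} = z_j^T \gamma + \theta X_j + \alpha_j + \varepsilon_{ij},}
#' where \eqn{z_j} are the cluster-level covariates, \eqn{X_j} the treatment
#' indicator, \eqn{\alpha_j \sim N(0, \sigma_b^2)} the random cluster effect
#' and \eqn{\varepsilon_{ij} \sim N(0, \sigma_e^2)} the residual. The
#' between-cluster variance is derived from the intra-cluster correlation as
#' \eqn{\sigma_b^2 = \sigma_e^2\,\rho / (1 - \rho)}, so that
#' \eqn{\rho = \sigma_b^2 / (\sigma_b^2 + \sigma_e^2)}.
#'
#' @param gamma Prognostic coefficients of the cluster-level covariates
#'   (outcome units); recycled to `n_covariates` when scalar.
#' @param theta Treatment effect (outcome units; standardised when
#'   `sigma_e_sq = 1`).
#' @param icc Intra-cluster correlation \eqn{\rho}, in \[0, 1).
#' @param n_covariates Number of covariates in the generating model; defaults
#'   to `length(gamma)`.
#' @param sigma_e_sq Residual variance (default 1).
#' @param cluster_size Individuals per cluster, `M` (default 300).
#' @param covariate_prob Bernoulli probability for covariate generation
#'   (default 0.3).
#' @return An `outcome_params` list, including the derived `sigma_b_sq`.
#' @examples
#' outcome_params(gamma = 2, theta = 0.5, icc = 0.05, n_covariates = 4)
#' @export
outcome_params <- function(gamma, theta, icc, n_covariates = length(gamma),
                           sigma_e_sq = 1, cluster_size = 300,
                           covariate_prob = 0.3) {
  if (!is.finite(icc) || icc < 0 || icc >= 1) {
    ccrsim_error("`icc` must lie in [0, 1)", "ccrsim_invalid_input")
  }
  if (sigma_e_sq <= 0) {
    ccrsim_error("`sigma_e_sq` must be positive", "ccrsim_invalid_input")
  }
  if (length(gamma) == 1L) gamma <- rep(gamma, n_covariates)
  if (length(gamma) != n_covariates) {
    ccrsim_error("`gamma` must have one coefficient per generating covariate",
                 "ccrsim_invalid_input")
  }
  structure(
    list(gamma = gamma, theta = theta, icc = icc,
         sigma_e_sq = sigma_e_sq,
         sigma_b_sq = sigma_e_sq * icc / (1 - icc),
         cluster_size = as.integer(cluster_size),
         covariate_prob = covariate_prob),
    class = "outcome_params")
}

#' Generate binary cluster-level covariates
#'
#' Independent Bernoulli(`prob`) draws, one value per cluster and covariate.
#'
#' @param n_clusters Number of clusters (rows).
#' @param n_covariates Number of covariates (columns).
#' @param prob Success probability (default 0.3).
#' @return Covariate matrix with columns `z1, z2, ...`.
#' @export
generate_covariates <- function(n_clusters, n_covariates, prob = 0.3) {
  if (prob <= 0 || prob >= 1) {
    ccrsim_error("`prob` must lie in (0, 1)", "ccrsim_invalid_input")
  }
  matrix(stats::rbinom(n_clusters * n_covariates, 1L, prob),
         nrow = n_clusters, ncol = n_covariates,
         dimnames = list(NULL, paste0("z", seq_len(n_covariates))))
}

# Random draws shared by all allocations compared under common random
# numbers: one cluster effect per cluster and one residual per individual.
draw_trial_noise <- function(params, n_clusters) {
  list(alpha = stats::rnorm(n_clusters, 0, sqrt(params$sigma_b_sq)),
       eps = stats::rnorm(n_clusters * params$cluster_size, 0,
                          sqrt(params$sigma_e_sq)))
}

#' Simulate individual-level trial data
#'
#' Draws one random effect per cluster and one residual per individual, then
#' assembles the outcome under the linear model in [outcome_params()]. All
#' covariates in `covariates` are prognostic (with coefficients
#' `params$gamma`), regardless of how many are later balanced or adjusted.
#'
#' @param covariates Covariate table, one row per cluster.
#' @param assignment 0/1 allocation vector (1 = intervention), one entry per
#'   cluster.
#' @param params An [outcome_params()] object.
#' @param noise Optional list with `alpha` (length `n_clusters`) and `eps`
#'   (length `n_clusters * cluster_size`) to reuse pre-drawn noise, e.g. for
#'   common-random-number comparisons. Drawn internally when `NULL`.
#' @return Data frame with one row per individual: `cluster`, `individual`,
#'   `treatment`, the covariate columns (constant within cluster) and
#'   `outcome`.
#' @examples
#' set.seed(1)
#' z <- generate_covariates(6, 2)
#' p <- outcome_params(gamma = 2, theta = 0.5, icc = 0.05,
#'                     n_covariates = 2, cluster_size = 10)
#' head(generate_outcomes(z, c(1, 0, 1, 0, 1, 0), p))
#' @export
generate_outcomes <- function(covariates, assignment, params, noise = NULL) {
  z <- as_covariate_table(covariates)
  J <- nrow(z)
  if (length(assignment) != J) {
    ccrsim_error("assignment length must equal the number of clusters",
                 "ccrsim_invalid_input")
  }
  if (length(params$gamma) != ncol(z)) {
    ccrsim_error("length(gamma) must equal the number of covariate columns",
                 "ccrsim_invalid_input")
  }
  M <- params$cluster_size
  if (is.null(noise)) noise <- draw_trial_noise(params, J)
  mu_j <- drop(z %*% params$gamma) + params$theta * assignment + noise$alpha
  out <- data.frame(
    cluster = rep(seq_len(J), each = M),
    individual = rep(seq_len(M), times = J),
    treatment = rep(as.integer(assignment), each = M))
  zz <- z[rep(seq_len(J), each = M), , drop = FALSE]
  rownames(zz) <- NULL
  out <- cbind(out, zz)
  out$outcome <- rep(mu_j, each = M) + noise$eps
  out
}

#' Covariates of the ten emergency departments in the worked example
#'
#' The illustrative trial randomises ten emergency departments 1:1 to an
#' acute mental-healthcare bundle or standard care, with three binary
#' cluster-level covariates recorded before randomisation: large annual
#' patient volume, presence of a dedicated mental health team, and direct
#' access to urgent mental-health follow-up (yes = 1). The same table is
#' shipped as `inst/extdata/ed_covariates.csv`.
#'
#' @return A 10 x 3 covariate matrix with cluster identifiers as row names.
#' @examples
#' colSums(ed_covariates())
#' @export
ed_covariates <- function() {
  z <- matrix(
    c(1, 1, 1,
      0, 0, 0,
      1, 1, 0,
      1, 1, 0,
      0, 1, 1,
      1, 0, 1,
      0, 0, 1,
      0, 0, 0,
      0, 0, 0,
      0, 1, 0),
    nrow = 10, ncol = 3, byrow = TRUE,
    dimnames = list(as.character(1:10),
                    c("patient_volume", "mh_team", "urgent_followup")))
  z
}

#' Factorial scenario grids for the simulation study
#'
#' Builds the full factorial grid of simulation cells as a data frame, one
#' row per cell, whose columns match the arguments of [scenario_config()].
#'
#' The `"primary"` grid crosses 5, 9 or 13 clusters per arm with
#' intra-cluster correlations 0.001-0.1, null and non-null treatment
#' effects, 1-4 of the four generating covariates balanced, candidate sets
#' from the worst 10-90% through simple randomisation to the best 90-10%,
#' and 1-4 covariates adjusted. Non-null effects are 0.5, except 0.2 with 13
#' clusters per arm and 0.25 with 9 clusters per arm at ICC of 0.01 or less,
#' sizes chosen so power stays below 100%. The `"secondary"` grid fixes 9
#' clusters per arm, ICC 0.05 and simple randomisation, and varies the
#' number (4, 8 or 12) and prognostic strength (0.25, 0.5, 1.0) of the
#' generating covariates with 1-L covariates adjusted.
#'
#' @param objective `"primary"` or `"secondary"`.
#' @return Data frame of scenario cells.
#' @seealso [run_grid()]
#' @export
scenario_grid <- function(objective = c("primary", "secondary")) {
  objective <- match.arg(objective)
  if (objective == "primary") {
    cand <- rbind(
      data.frame(candidate_fraction = seq(0.1, 0.9, by = 0.1),
                 candidate_side = "worst"),
      data.frame(candidate_fraction = 1, candidate_side = "all"),
      data.frame(candidate_fraction = seq(0.9, 0.1, by = -0.1),
                 candidate_side = "best"))
    base <- expand.grid(
      k_per_arm = c(5L, 9L, 13L),
      icc = c(0.001, 0.01, 0.05, 0.1),
      null_effect = c(TRUE, FALSE),
      n_balanced = 1:4,
      cand = seq_len(nrow(cand)),
      n_adjusted = 1:4,
      KEEP.OUT.ATTRS = FALSE)
    theta_alt <- ifelse(base$k_per_arm == 13L, 0.2,
                        ifelse(base$k_per_arm == 9L & base$icc <= 0.01,
                               0.25, 0.5))
    out <- data.frame(
      k_per_arm = base$k_per_arm,
      cluster_size = 300L,
      icc = base$icc,
      theta = ifelse(base$null_effect, 0, theta_alt),
      n_covariates_model = 4L,
      gamma = 2,
      covariate_prob = 0.3,
      n_balanced = base$n_balanced,
      candidate_fraction = cand$candidate_fraction[base$cand],
      candidate_side = cand$candidate_side[base$cand],
      n_adjusted = base$n_adjusted)
  } else {
    cells <- do.call(rbind, lapply(c(4L, 8L, 12L), function(L) {
      g <- expand.grid(gamma = c(0.25, 0.5, 1.0), theta = c(0, 0.5),
                       n_adjusted = seq_len(L), KEEP.OUT.ATTRS = FALSE)
      g$n_covariates_model <- L
      g
    }))
    out <- data.frame(
      k_per_arm = 9L,
      cluster_size = 300L,
      icc = 0.05,
      theta = cells$theta,
      n_covariates_model = cells$n_covariates_model,
      gamma = cells$gamma,
      covariate_prob = 0.3,
      n_balanced = 0L,
      candidate_fraction = 1,
      candidate_side = "all",
      n_adjusted = cells$n_adjusted)
  }
  rownames(out) <- NULL
  out
}
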