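# Independent oracle implementations and small data builders used across the
# test files. The oracles deliberately avoid the package's own code paths.

# Naive balance score: per-covariate loop over arm means.
bf_balance_score <- function(z, assignment, w) {
  total <- 0
  for (cc in seq_len(ncol(z))) {
    d <- mean(z[assignment == 1, cc]) - mean(z[assignment == 0, cc])
    total <- total + w[cc] * d^2
  }
  total
}

# Naive candidate set: score every scheme, sort, slice.
bf_best_set <- function(schemes, scores, fraction) {
  size <- max(1L, floor(fraction * nrow(schemes) + 0.5))
  key <- apply(schemes, 1L, paste0, collapse = "")
  ord <- order(scores, key)
  schemes[ord[seq_len(size)], , drop = FALSE]
}

# Covariate table guaranteed usable: non-degenerate columns and (when the
# cluster count allows it) full rank together with the intercept and an
# alternating allocation.
draw_usable_covariates <- function(n_clusters, n_covariates, prob = 0.3) {
  a <- rep(c(1L, 0L), n_clusters / 2)
  need_rank <- min(n_covariates + 2L, n_clusters)
  repeat {
    z <- generate_covariates(n_clusters, n_covariates, prob)
    ok <- all(apply(z, 2L, stats::var) > 0) &&
      qr(cbind(1, a, z))$rank >= need_rank
    if (ok) return(z)
  }
}

# One balanced simulated trial with an alternating allocation.
make_balanced_trial <- function(n_clusters = 10, cluster_size = 30,
                                n_covariates = 3, icc = 0.1, theta = 0.5,
                                gamma = 2) {
  z <- draw_usable_covariates(n_clusters, n_covariates)
  a <- rep(c(1L, 0L), n_clusters / 2)
  p <- outcome_params(gamma = gamma, theta = theta, icc = icc,
                      n_covariates = n_covariates,
                      cluster_size = cluster_size)
  list(data = generate_outcomes(z, a, p), covariates = z, assignment = a,
       params = p)
}

# Method-of-moments ICC estimate from one simulated trial (one-way ANOVA).
anova_icc <- function(data) {
  M <- max(data$individual)
  cm <- tapply(data$outcome, data$cluster, mean)
  J <- length(cm)
  msb <- M * stats::var(cm)
  msw <- sum((data$outcome - rep(cm, each = M))^2) / (nrow(data) - J)
  (msb - msw) / (msb + (M - 1) * msw)
}
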