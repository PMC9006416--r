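#' @title Random-intercept REML analysis with Satterthwaite degrees of freedom
#' @description
#' The trial analysis is a linear mixed model with a random cluster
#' intercept, fixed effects for treatment and the adjusted cluster-level
#' covariates, fitted by restricted maximum likelihood. The treatment effect
#' is tested with an F statistic on 1 and \eqn{\nu} degrees of freedom,
#' where \eqn{\nu} is the Satterthwaite approximation
#' \eqn{\nu = 2 \widehat{Var}(\hat\theta)^2 / \widehat{Var}(\widehat{Var}(\hat\theta))},
#' the inner variance obtained by the delta method from the expected REML
#' information of the variance components. With few clusters this correction
#' is what keeps the test near its nominal size.
#' @name lmm-analysis
NULL

# Collapse individual-level data to cluster-level sufficient statistics.
# With cluster-level covariates the restricted likelihood depends on the
# data only through the cluster means, cluster sizes and the pooled
# within-cluster sum of squares.
reduce_trial <- function(data, adjust = NULL, check = TRUE) {
  need <- c("outcome", "cluster", "treatment", adjust)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    ccrsim_error(paste0("missing column(s): ", paste(miss, collapse = ", ")),
                 "ccrsim_invalid_input")
  }
  f <- factor(data$cluster, levels = unique(data$cluster))
  gi <- as.integer(f)
  J <- nlevels(f)
  m <- tabulate(gi, J)
  y <- data$outcome
  ybar <- rowsum(y, gi)[, 1L] / m
  ssw <- sum(y^2) - sum(m * ybar^2)
  firsts <- which(!duplicated(gi))
  X <- cbind(`(Intercept)` = 1, treatment = data$treatment[firsts])
  if (length(adjust)) {
    Z <- as.matrix(data[firsts, adjust, drop = FALSE])
    storage.mode(Z) <- "numeric"
    X <- cbind(X, Z)
  }
  if (check) {
    for (col in c("treatment", adjust)) {
      v <- data[[col]]
      vbar <- rowsum(v, gi)[, 1L] / m
      if (sum(v^2) - sum(m * vbar^2) > 1e-8 * max(1, sum(v^2))) {
        ccrsim_error(sprintf("column '%s' varies within clusters; only cluster-level terms are supported",
                             col),
                     "ccrsim_invalid_input")
      }
    }
  }
  list(m = m, ybar = unname(ybar), ssw = ssw, X = X,
       N = length(y), J = J, p = ncol(X), adjust = adjust,
       cluster_levels = levels(f))
}

# Profiled -2 restricted log-likelihood (up to a constant) at variance ratio
# lambda = sigma_b^2 / sigma_e^2, using the cluster-level reduction.
reml_criterion <- function(lambda, r) {
  v <- 1 / r$m + lambda
  sw <- 1 / sqrt(v)
  qq <- qr(r$X * sw)
  rss <- sum(qr.resid(qq, r$ybar * sw)^2)
  s2 <- (r$ssw + rss) / (r$N - r$p)
  (r$N - r$p) * log(s2) + sum(log(v)) +
    2 * sum(log(abs(diag(qr.R(qq)))))
}

# Satterthwaite df for the treatment coefficient by the delta method with
# the expected REML information of (sigma_b^2, sigma_e^2). All quantities
# are cluster-level, so cost is O(J^2).
satt_df_delta <- function(sigma_b_sq, sigma_e_sq, m, X, N,
                          theta_index = 2L) {
  a <- sigma_e_sq / m + sigma_b_sq        # Var of cluster means
  J <- length(a)
  Xa <- X / a
  W <- crossprod(X, Xa)                    # X' A^-1 X
  Winv <- solve(W)
  g <- Winv[theta_index, theta_index]      # Var(theta_hat)
  # gradient of g wrt (sigma_b^2, sigma_e^2)
  Gb <- crossprod(Xa)                      # X' A^-2 X
  Ge <- crossprod(Xa, Xa / m)              # X' A^-2 diag(1/m) X
  gb <- (Winv %*% Gb %*% Winv)[theta_index, theta_index]
  ge <- (Winv %*% Ge %*% Winv)[theta_index, theta_index]
  # expected REML information: mean part uses the projection
  # P = A^-1 - A^-1 X W^-1 X' A^-1; the within-cluster part adds
  # (N - J) / (2 sigma_e^4) to the residual-variance entry
  P <- diag(1 / a, nrow = J) - Xa %*% Winv %*% t(Xa)
  PP <- P %*% P
  Ibb <- 0.5 * sum(diag(PP))
  Ibe <- 0.5 * sum(diag(PP) / m)
  Q <- P * rep(1 / m, each = J)            # P %*% diag(1/m)
  Iee <- 0.5 * sum(Q * t(Q)) + (N - J) / (2 * sigma_e_sq^2)
  info <- matrix(c(Ibb, Ibe, Ibe, Iee), 2L, 2L)
  grad <- c(gb, ge)
  denom <- drop(crossprod(grad, solve(info, grad)))
  2 * g^2 / denom
}

assemble_fit <- function(r, beta, vcov_beta, sigma_b_sq, sigma_e_sq,
                         satt_df, boundary, converged,
                         class = "lmm_fit") {
  theta_hat <- unname(beta[2L])
  se_theta <- sqrt(vcov_beta[2L, 2L])
  f_stat <- (theta_hat / se_theta)^2
  structure(
    list(coefficients = beta,
         theta_hat = theta_hat, se_theta = se_theta,
         sigma_b_sq_hat = sigma_b_sq, sigma_e_sq_hat = sigma_e_sq,
         satt_df = satt_df, f_stat = f_stat,
         p_value = stats::pf(f_stat, 1, satt_df, lower.tail = FALSE),
         converged = converged, boundary = boundary,
         vcov = vcov_beta,
         n_clusters = r$J, n_obs = r$N, adjust = r$adjust,
         internals = r[c("m", "ybar", "ssw", "X", "N", "J", "p")]),
    class = class)
}

# sigma_b^2 = 0 boundary fit: ordinary least squares on individuals
# (equivalently cluster means weighted by cluster size), residual df N - p.
fit_boundary <- function(r) {
  sw <- sqrt(r$m)
  qq <- qr(r$X * sw)
  beta <- qr.coef(qq, r$ybar * sw)
  rss <- r$ssw + sum(qr.resid(qq, r$ybar * sw)^2)
  sigma_e_sq <- rss / (r$N - r$p)
  vcov_beta <- sigma_e_sq * chol2inv(qr.R(qq))
  assemble_fit(r, beta, vcov_beta, 0, sigma_e_sq,
               satt_df = r$N - r$p, boundary = TRUE, converged = TRUE)
}

fit_at_lambda <- function(r, lambda) {
  v <- 1 / r$m + lambda
  sw <- 1 / sqrt(v)
  qq <- qr(r$X * sw)
  beta <- qr.coef(qq, r$ybar * sw)
  rss <- sum(qr.resid(qq, r$ybar * sw)^2)
  sigma_e_sq <- (r$ssw + rss) / (r$N - r$p)
  sigma_b_sq <- lambda * sigma_e_sq
  vcov_beta <- sigma_e_sq * chol2inv(qr.R(qq))
  df <- satt_df_delta(sigma_b_sq, sigma_e_sq, r$m, r$X, r$N)
  assemble_fit(r, beta, vcov_beta, sigma_b_sq, sigma_e_sq,
               satt_df = df, boundary = FALSE, converged = TRUE)
}

# Closed-form REML for equal cluster sizes: the restricted likelihood
# separates, giving the ANOVA estimators sigma_e^2 = SSW / (N - J) and
# sigma_b^2 + sigma_e^2 / M = RSS_means / (J - p), subject to sigma_b^2 >= 0.
fit_balanced <- function(r) {
  M <- r$m[1L]
  qq <- qr(r$X)
  beta <- qr.coef(qq, r$ybar)
  rss_b <- sum(qr.resid(qq, r$ybar)^2)
  sigma_e_sq <- r$ssw / (r$N - r$J)
  s_b <- rss_b / (r$J - r$p)
  sigma_b_sq <- s_b - sigma_e_sq / M
  if (!is.finite(sigma_b_sq) || sigma_b_sq <= 0) return(fit_boundary(r))
  vcov_beta <- s_b * chol2inv(qr.R(qq))
  df <- satt_df_delta(sigma_b_sq, sigma_e_sq, r$m, r$X, r$N)
  assemble_fit(r, beta, vcov_beta, sigma_b_sq, sigma_e_sq,
               satt_df = df, boundary = FALSE, converged = TRUE)
}

fit_profiled <- function(r, tol = 1e-9) {
  op <- stats::optimize(function(psi) reml_criterion(exp(psi), r),
                        interval = c(log(1e-10), log(1e6)), tol = tol)
  f0 <- reml_criterion(0, r)
  if (f0 <= op$objective + 1e-8) return(fit_boundary(r))
  fit_at_lambda(r, exp(op$minimum))
}

#' Fit the random-intercept linear mixed model by REML
#'
#' Estimates the variance components \eqn{(\sigma_b^2, \sigma_e^2)} by
#' restricted maximum likelihood with \eqn{\sigma_b^2} constrained to be
#' non-negative, computes the generalised-least-squares fixed effects at the
#' estimates, and attaches the Satterthwaite degrees of freedom and F-test
#' for the treatment effect.
#'
#' For equal cluster sizes the restricted likelihood separates and the
#' ANOVA estimators are the exact REML solution, so the fit is closed form;
#' otherwise the profiled criterion is optimised numerically over
#' \eqn{\log(\sigma_b^2/\sigma_e^2)}. When the between-cluster variance
#' estimate hits the boundary at zero the fit degenerates to ordinary least
#' squares with residual degrees of freedom `N - p` and is flagged via
#' `boundary = TRUE`; such fits are retained, since dropping them would bias
#' Monte Carlo rejection rates.
#'
#' @param data Individual-level data frame with columns `outcome`, `cluster`,
#'   `treatment` and any covariates (see [generate_outcomes()]).
#' @param adjust Character vector naming the cluster-level covariate columns
#'   to adjust for (may be `NULL` for an unadjusted analysis).
#' @param check Verify that treatment and adjusted covariates are constant
#'   within clusters (default `TRUE`; skip for speed in tight loops where
#'   constancy holds by construction).
#' @return An `lmm_fit` with fixed-effect estimates, `theta_hat`,
#'   `se_theta`, variance components, `satt_df`, `f_stat`, `p_value`,
#'   `converged` and `boundary` flags.
#' @examples
#' set.seed(42)
#' z <- generate_covariates(10, 3)
#' p <- outcome_params(gamma = 2, theta = 0.5, icc = 0.1,
#'                     n_covariates = 3, cluster_size = 50)
#' d <- generate_outcomes(z, rep(c(1, 0), 5), p)
#' fit <- fit_lmm_reml(d, adjust = c("z1", "z2", "z3"))
#' treatment_test(fit)
#' @export
fit_lmm_reml <- function(data, adjust = NULL, check = TRUE) {
  r <- reduce_trial(data, adjust, check = check)
  if (r$J < 4L) {
    ccrsim_error("at least four clusters are required", "ccrsim_invalid_design")
  }
  if (qr(r$X)$rank < r$p) {
    ccrsim_error("cluster-level design is rank deficient (an adjusted covariate is collinear with treatment or another covariate)",
                 "ccrsim_singular_design")
  }
  if (all(r$m == r$m[1L])) fit_balanced(r) else fit_profiled(r)
}

#' Satterthwaite degrees of freedom of a fitted model
#'
#' Recomputes \eqn{\nu} from the stored cluster-level quantities of an
#' `lmm_fit`: the delta-method variance of \eqn{\widehat{Var}(\hat\theta)}
#' uses the gradient with respect to the variance components combined with
#' the inverse expected REML information. For balanced designs with
#' cluster-level covariates this reduces exactly to the cluster-level
#' residual degrees of freedom, `n_clusters - 2 - A`. Boundary fits
#' (\eqn{\hat\sigma_b^2 = 0}) use the degenerate pooled model's `N - p`.
#'
#' @param fit An `lmm_fit` from [fit_lmm_reml()].
#' @return The degrees of freedom, a positive scalar.
#' @export
satterthwaite_df <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  r <- fit$internals
  if (fit$boundary) return(r$N - r$p)
  satt_df_delta(fit$sigma_b_sq_hat, fit$sigma_e_sq_hat, r$m, r$X, r$N)
}

#' F-test of the treatment effect
#'
#' The squared Wald statistic \eqn{F = (\hat\theta / se)^2} referred to an F
#' distribution on 1 and \eqn{\nu} (Satterthwaite) degrees of freedom;
#' identical to the two-sided t-test with \eqn{\nu} degrees of freedom.
#'
#' @param fit An `lmm_fit` or `cluster_means_fit`.
#' @return List with `f_stat`, `df` (numerator and denominator), `p_value`.
#' @export
treatment_test <- function(fit) {
  stopifnot(inherits(fit, c("lmm_fit", "cluster_means_fit")))
  list(f_stat = fit$f_stat, df = c(1, fit$satt_df), p_value = fit$p_value)
}

#' Cluster-means analysis (independent oracle for balanced designs)
#'
#' Ordinary least squares of the cluster means on intercept, treatment and
#' the adjusted cluster-level covariates, fitted with [stats::lm()]. With
#' equal cluster sizes this reproduces the mixed model's treatment estimate,
#' standard error and degrees of freedom exactly (when the between-cluster
#' variance estimate is interior), which makes it the package's independent
#' verification route for [fit_lmm_reml()].
#'
#' @inheritParams fit_lmm_reml
#' @return A `cluster_means_fit` with `theta_hat`, `se_theta`,
#'   `satt_df = n_clusters - 2 - A`, `f_stat` and `p_value`.
#' @export
fit_cluster_means <- function(data, adjust = NULL, check = TRUE) {
  r <- reduce_trial(data, adjust, check = check)
  if (!all(r$m == r$m[1L])) {
    ccrsim_error("cluster-means analysis requires equal cluster sizes",
                 "ccrsim_unequal_clusters")
  }
  if (qr(r$X)$rank < r$p) {
    ccrsim_error("cluster-level design is rank deficient",
                 "ccrsim_singular_design")
  }
  df <- data.frame(ybar = r$ybar, r$X[, -1L, drop = FALSE],
                   check.names = FALSE)
  mod <- stats::lm(ybar ~ ., data = df)
  sm <- summary(mod)$coefficients
  beta <- stats::coef(mod)
  theta_hat <- unname(beta["treatment"])
  se_theta <- unname(sm["treatment", "Std. Error"])
  f_stat <- (theta_hat / se_theta)^2
  nu <- r$J - r$p
  structure(
    list(coefficients = beta, theta_hat = theta_hat, se_theta = se_theta,
         satt_df = nu, f_stat = f_stat,
         p_value = stats::pf(f_stat, 1, nu, lower.tail = FALSE),
         sigma_b_sq_hat = NA_real_, sigma_e_sq_hat = NA_real_,
         converged = TRUE, boundary = FALSE,
         n_clusters = r$J, n_obs = r$N, adjust = r$adjust, lm = mod),
    class = "cluster_means_fit")
}

#' Flatten a fit to a one-row record
#'
#' Key estimates and flags as a single-row data frame, suitable for a
#' CSV audit trail of Monte Carlo replicates.
#'
#' @param fit An `lmm_fit` or `cluster_means_fit`.
#' @return One-row data frame.
#' @export
fit_record <- function(fit) {
  data.frame(theta_hat = fit$theta_hat, se_theta = fit$se_theta,
             sigma_b_sq = fit$sigma_b_sq_hat, sigma_e_sq = fit$sigma_e_sq_hat,
             satt_df = fit$satt_df, f_stat = fit$f_stat,
             p_value = fit$p_value,
             converged = fit$converged, boundary = fit$boundary)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept LMM (REML): %d clusters, %d observations\n",
    x$n_clusters, x$n_obs))
  cat(sprintf("  theta = %.4f (se %.4f), F(1, %.2f) = %.3f, p = %.4g\n",
              x$theta_hat, x$se_theta, x$satt_df, x$f_stat, x$p_value))
  cat(sprintf("  sigma_b^2 = %.4g%s, sigma_e^2 = %.4g\n",
              x$sigma_b_sq_hat, if (x$boundary) " (boundary)" else "",
              x$sigma_e_sq_hat))
  invisible(x)
}

#' @export
print.cluster_means_fit <- function(x, ...) {
  cat(sprintf("Cluster-means OLS: %d clusters\n", x$n_clusters))
  cat(sprintf("  theta = %.4f (se %.4f), F(1, %d) = %.3f, p = %.4g\n",
              x$theta_hat, x$se_theta, x$satt_df, x$f_stat, x$p_value))
  invisible(x)
}
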