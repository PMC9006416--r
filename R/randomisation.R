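#' @title Randomisation spaces, balance scoring and candidate sets
#' @description
#' The randomisation space of a two-arm parallel cluster trial with `2K`
#' clusters and 1:1 allocation is the set of `choose(2K, K)` assignment
#' vectors. An allocation and its mirror (arm labels swapped) are distinct
#' members of the space; both carry the same balance score. Covariate
#' constrained randomisation scores every scheme with the Raab-Butcher
#' B metric, keeps the best- (or worst-) balanced fraction as the candidate
#' set, and draws the trial's allocation uniformly from it.
#' @name randomisation-space
NULL

new_randomisation_space <- function(schemes, complete, scores = NULL,
                                    weights = NULL) {
  structure(
    list(schemes = schemes, complete = complete, scores = scores,
         weights = weights),
    class = "randomisation_space")
}

check_n_clusters <- function(n_clusters) {
  if (length(n_clusters) != 1L || !is.finite(n_clusters) ||
      n_clusters != as.integer(n_clusters)) {
    ccrsim_error("`n_clusters` must be a single integer", "ccrsim_invalid_design")
  }
  if (n_clusters %% 2L != 0L || n_clusters < 4L) {
    ccrsim_error("`n_clusters` must be even and >= 4 for 1:1 allocation",
                 "ccrsim_invalid_design")
  }
  as.integer(n_clusters)
}

#' Enumerate the complete randomisation space
#'
#' Generates every equal-split assignment of `n_clusters` clusters to two
#' arms. A scheme and its mirror image are both included. For spaces larger
#' than `max_schemes` the function refuses and directs the caller to
#' [sample_schemes()].
#'
#' @param n_clusters Even number of clusters (total across both arms).
#' @param max_schemes Largest space size that will be enumerated in full
#'   (default 20,000, the cap used throughout the package).
#' @return A `randomisation_space`: a list with `schemes` (0/1 matrix, one
#'   row per scheme), `complete = TRUE`, and `scores`/`weights` slots filled
#'   by [score_space()].
#' @examples
#' sp <- enumerate_schemes(6)
#' nrow(sp$schemes)  # choose(6, 3) = 20
#' @seealso [sample_schemes()], [score_space()], [build_candidate_set()]
#' @export
enumerate_schemes <- function(n_clusters, max_schemes = 20000) {
  n_clusters <- check_n_clusters(n_clusters)
  k <- n_clusters %/% 2L
  n_total <- choose(n_clusters, k)
  if (n_total > max_schemes) {
    ccrsim_error(
      sprintf(paste0("complete randomisation space has %s schemes ",
                     "(> %s); use sample_schemes() to draw a capped sample"),
              format(n_total, big.mark = ","),
              format(max_schemes, big.mark = ",")),
      "ccrsim_space_too_large")
  }
  combs <- utils::combn(n_clusters, k)
  n <- ncol(combs)
  schemes <- matrix(0L, n, n_clusters)
  schemes[cbind(rep(seq_len(n), each = k), as.vector(combs))] <- 1L
  new_randomisation_space(schemes, complete = TRUE)
}

# Map 0-based ranks in the lexicographic order of k-subsets of 1..n to 0/1
# assignment matrices (combinatorial number system). Vectorised over ranks:
# one pass over the n positions. Exact for spaces up to 2^53 schemes.
unrank_combinations <- function(ranks, n, k) {
  B <- length(ranks)
  m <- matrix(0L, B, n)
  r <- as.numeric(ranks)
  krem <- rep(k, B)
  for (v in seq_len(n)) {
    cnt <- choose(n - v, krem - 1L)   # zero once krem is exhausted
    take <- r < cnt
    m[take, v] <- 1L
    krem <- krem - take
    r <- r - cnt * !take
  }
  m
}

#' Sample a capped randomisation space
#'
#' Draws up to `cap` pairwise-distinct equal-split schemes uniformly without
#' replacement. When the complete space has `cap` or fewer schemes it is
#' enumerated instead (and flagged complete). Used for trials whose space is
#' too large to enumerate; the default cap of 20,000 keeps constrained
#' randomisation computationally feasible at any number of clusters.
#'
#' @inheritParams enumerate_schemes
#' @param cap Maximum number of distinct schemes to return.
#' @return A `randomisation_space`; `complete` is `FALSE` when the space was
#'   truncated.
#' @examples
#' set.seed(1)
#' sp <- sample_schemes(26, cap = 1000)
#' sp$complete  # FALSE: choose(26, 13) is about 10.4 million
#' @export
sample_schemes <- function(n_clusters, cap = 20000) {
  n_clusters <- check_n_clusters(n_clusters)
  if (cap < 1) ccrsim_error("`cap` must be >= 1", "ccrsim_invalid_input")
  k <- n_clusters %/% 2L
  n_total <- choose(n_clusters, k)
  if (n_total <= cap) {
    return(enumerate_schemes(n_clusters, max_schemes = cap))
  }
  target <- as.integer(cap)
  if (n_total <= 2^53) {
    # draw scheme ranks uniformly without replacement, then unrank: exactly
    # `cap` pairwise-distinct schemes, uniform over the full space
    ranks <- sample.int(n_total, target) - 1
    return(new_randomisation_space(
      unrank_combinations(ranks, n_clusters, k), complete = FALSE))
  }
  # spaces beyond 2^53 schemes exceed exact double-precision ranks: draw
  # random splits and deduplicate (collisions are then vanishingly rare)
  acc <- matrix(0L, 0L, n_clusters)
  while (nrow(acc) < target) {
    need <- target - nrow(acc)
    idx <- vapply(seq_len(need), function(i) sample.int(n_clusters, k),
                  integer(k))
    batch <- matrix(0L, need, n_clusters)
    batch[cbind(rep(seq_len(need), each = k), as.vector(idx))] <- 1L
    acc <- rbind(acc, batch)
    acc <- acc[!duplicated(scheme_keys(acc)), , drop = FALSE]
  }
  new_randomisation_space(acc, complete = FALSE)
}

#' Score allocation balance with the B metric
#'
#' The Raab-Butcher balance score of an allocation is the weighted sum over
#' covariates of the squared difference in arm means,
#' \deqn{B = \sum_c \omega_c (\bar z_{1c} - \bar z_{0c})^2,}
#' where \eqn{\bar z_{1c}} and \eqn{\bar z_{0c}} are the means of covariate
#' `c` over intervention and control clusters. Smaller is better balanced;
#' `B = 0` exactly when both arms have identical covariate means. The score
#' is invariant under swapping the arm labels.
#'
#' @param covariates Covariate table, one row per cluster.
#' @param scheme A 0/1 assignment vector (1 = intervention), or a matrix of
#'   such vectors, one scheme per row.
#' @param weights Positive per-covariate weights; defaults to
#'   [covariate_weights()] of `covariates`.
#' @return Numeric vector of non-negative scores, one per scheme.
#' @examples
#' z <- cbind(z1 = c(1, 1, 0, 0))
#' balance_score(z, c(1, 1, 0, 0))  # maximally imbalanced
#' balance_score(z, c(1, 0, 1, 0))  # perfectly balanced
#' @export
balance_score <- function(covariates, scheme,
                          weights = covariate_weights(covariates)) {
  z <- as_covariate_table(covariates)
  if (is.null(dim(scheme))) scheme <- matrix(scheme, nrow = 1L)
  if (ncol(scheme) != nrow(z)) {
    ccrsim_error("scheme length must equal the number of clusters",
                 "ccrsim_invalid_input")
  }
  if (length(weights) != ncol(z)) {
    ccrsim_error("need one weight per covariate", "ccrsim_invalid_input")
  }
  k1 <- rowSums(scheme)
  if (any(k1 != nrow(z) / 2)) {
    ccrsim_error("every scheme must assign exactly half the clusters to each arm",
                 "ccrsim_invalid_input")
  }
  K <- nrow(z) / 2
  t1 <- scheme %*% z                         # covariate sums in arm 1
  diff <- (2 * t1 - rep(colSums(z), each = nrow(scheme))) / K
  as.vector(diff^2 %*% weights)
}

#' Attach balance scores to a randomisation space
#'
#' @param space A `randomisation_space` from [enumerate_schemes()] or
#'   [sample_schemes()].
#' @param covariates Covariate table for the clusters being randomised (only
#'   the covariates to be balanced).
#' @param weights Per-covariate weights; defaults to inverse variances.
#' @return The space with `scores` and `weights` filled in.
#' @export
score_space <- function(space, covariates,
                        weights = covariate_weights(covariates)) {
  stopifnot(inherits(space, "randomisation_space"))
  space$scores <- balance_score(covariates, space$schemes, weights)
  space$weights <- weights
  # deterministic ordering (score, then lexicographic assignment vector),
  # cached so repeated candidate-set cuts reuse it
  space$order <- order(space$scores, scheme_keys(space$schemes))
  space
}

#' Form a best- or worst-balanced candidate set
#'
#' Sorts the schemes by balance score (ascending; ties broken by the
#' lexicographic order of the assignment vector so the set is deterministic)
#' and keeps the leading (`side = "best"`) or trailing (`side = "worst"`)
#' `round(fraction * n)` schemes, never fewer than one. A fraction of 1
#' returns the whole space: randomising within it is simple randomisation.
#' The set size uses half-away-from-zero rounding, so decile fractions of
#' decile-divisible spaces are exact.
#'
#' @param space A scored `randomisation_space` (see [score_space()]).
#' @param fraction Fraction of the space to keep, in (0, 1].
#' @param side `"best"` (smallest scores), `"worst"` (largest), or `"all"`
#'   (only valid with `fraction = 1`).
#' @return A `candidate_set`: schemes and scores (ascending), the fraction,
#'   side, and the size of the space it was cut from.
#' @export
build_candidate_set <- function(space, fraction,
                                side = c("best", "worst", "all")) {
  side <- match.arg(side)
  stopifnot(inherits(space, "randomisation_space"))
  if (is.null(space$scores)) {
    ccrsim_error("space must be scored first (see score_space())",
                 "ccrsim_invalid_input")
  }
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    ccrsim_error("`fraction` must lie in (0, 1]", "ccrsim_invalid_fraction")
  }
  if (side == "all" && fraction < 1) {
    ccrsim_error("side = \"all\" requires fraction = 1", "ccrsim_invalid_fraction")
  }
  n <- nrow(space$schemes)
  size <- max(1L, as.integer(round_half_up(fraction * n)))
  ord <- space$order %||% order(space$scores, scheme_keys(space$schemes))
  if (fraction == 1) {
    side <- "all"
    idx <- ord
  } else if (side == "best") {
    idx <- ord[seq_len(size)]
  } else {
    idx <- ord[seq.int(n - size + 1L, n)]
  }
  structure(
    list(schemes = space$schemes[idx, , drop = FALSE],
         scores = space$scores[idx],
         fraction = fraction, side = side,
         space_size = n, complete = space$complete),
    class = "candidate_set")
}

#' Select the trial's allocation from a candidate set
#'
#' Draws one scheme uniformly at random from the candidate set. With
#' `fraction = 1` this is simple randomisation.
#'
#' @param candidates A `candidate_set` from [build_candidate_set()].
#' @return A list with `assignment` (0/1 vector, 1 = intervention) and
#'   `score` (its B metric value).
#' @export
select_scheme <- function(candidates) {
  stopifnot(inherits(candidates, "candidate_set"))
  n <- nrow(candidates$schemes)
  if (n < 1L) ccrsim_error("empty candidate set", "ccrsim_invalid_fraction")
  i <- sample.int(n, 1L)
  list(assignment = candidates$schemes[i, ], score = candidates$scores[i])
}

#' Export a candidate set as CSV
#'
#' Writes one row per scheme (assignment vector columns plus the balance
#' score), sorted ascending by score.
#'
#' @param candidates A `candidate_set`.
#' @param path Output CSV path.
#' @param cluster_ids Optional cluster labels used as column names.
#' @return The path, invisibly.
#' @export
write_candidate_set <- function(candidates, path, cluster_ids = NULL) {
  stopifnot(inherits(candidates, "candidate_set"))
  m <- candidates$schemes
  colnames(m) <- cluster_ids %||% paste0("cluster_", seq_len(ncol(m)))
  out <- data.frame(m, check.names = FALSE)
  out$balance_score <- candidates$scores
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.randomisation_space <- function(x, ...) {
  cat(sprintf("Randomisation space: %s schemes for %d clusters (%s)%s\n",
              format(nrow(x$schemes), big.mark = ","), ncol(x$schemes),
              if (x$complete) "complete" else "capped sample",
              if (is.null(x$scores)) ", unscored" else ", scored"))
  invisible(x)
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(
    "Candidate set: %s of %s schemes (%s %d%%); B in [%.4g, %.4g]\n",
    format(nrow(x$schemes), big.mark = ","),
    format(x$space_size, big.mark = ","),
    x$side, round(100 * x$fraction),
    min(x$scores), max(x$scores)))
  invisible(x)
}
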