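test_that("complete enumeration has choose(2K, K) distinct schemes, mirrors included", {
  for (n in c(4L, 10L, 16L)) {
    sp <- enumerate_schemes(n)
    expect_true(sp$complete)
    expect_equal(nrow(sp$schemes), choose(n, n / 2))
    expect_equal(unname(rowSums(sp$schemes)), rep(n / 2, nrow(sp$schemes)))
    keys <- apply(sp$schemes, 1L, paste0, collapse = "")
    expect_equal(anyDuplicated(keys), 0L)
    # a scheme and its arm-swapped mirror are both members
    expect_true(all(apply(1L - sp$schemes, 1L, paste0, collapse = "") %in% keys))
  }
  expect_error(enumerate_schemes(7), class = "ccrsim_invalid_design")
  expect_error(enumerate_schemes(2), class = "ccrsim_invalid_design")
  expect_error(enumerate_schemes(26), regexp = "sample_schemes",
               class = "ccrsim_space_too_large")
})

test_that("capped sampling is uniform-without-replacement, distinct and reproducible", {
  # space smaller than the cap: falls back to complete enumeration
  sp <- sample_schemes(8, cap = 20000)
  expect_true(sp$complete)
  expect_equal(nrow(sp$schemes), 70)

  set.seed(42)
  s1 <- sample_schemes(26, cap = 2000)
  expect_false(s1$complete)
  expect_equal(nrow(s1$schemes), 2000)
  expect_equal(unname(rowSums(s1$schemes)), rep(13, 2000))
  expect_equal(anyDuplicated(apply(s1$schemes, 1L, paste0, collapse = "")), 0L)
  set.seed(42)
  s2 <- sample_schemes(26, cap = 2000)
  expect_identical(s1$schemes, s2$schemes)
})

test_that("rank unranking reproduces the lexicographic combination order", {
  for (nk in list(c(6L, 3L), c(9L, 4L))) {
    n <- nk[1]; k <- nk[2]
    combs <- t(utils::combn(n, k))
    ref <- matrix(0L, nrow(combs), n)
    ref[cbind(rep(seq_len(nrow(combs)), each = k), as.vector(t(combs)))] <- 1L
    got <- ccrsim:::unrank_combinations(0:(choose(n, k) - 1), n, k)
    expect_identical(got, ref)
  }
})

test_that("covariate weights are inverse variances and flag degenerate columns", {
  z <- cbind(z1 = c(0, 1, 0, 1), z2 = c(1, 0, 1, 0))
  w <- covariate_weights(z)
  expect_equal(unname(w[1]), 1 / var(c(0, 1, 0, 1)))  # sample divisor: 1/(1/3)
  expect_equal(unname(w[1]), unname(w[2]))            # identical spread, equal weight
  wp <- covariate_weights(z, divisor = "population")
  expect_equal(unname(wp[1]), 1 / (var(c(0, 1, 0, 1)) * 3 / 4))
  zbad <- cbind(z1 = c(0, 1, 0, 1), flat = c(1, 1, 1, 1))
  expect_error(covariate_weights(zbad), regexp = "flat",
               class = "ccrsim_degenerate_covariate")
})

test_that("B metric matches hand evaluation and the brute-force oracle", {
  z <- cbind(z1 = c(1, 1, 0, 0))
  w <- covariate_weights(z)
  # splitting the two z=1 clusters against the two z=0 clusters maximises B
  expect_equal(balance_score(z, c(1, 1, 0, 0), w), unname(w[1]))
  sp <- enumerate_schemes(4)
  scores <- balance_score(z, sp$schemes, w)
  expect_equal(max(scores), unname(w[1]))
  expect_equal(scores[apply(sp$schemes, 1, paste0, collapse = "") == "1100"],
               max(scores))

  # random spaces up to 12 clusters: vectorised scores equal the naive loop,
  # mirrors score identically, and B = 0 iff all arm means are equal
  set.seed(7)
  for (n in c(4L, 6L, 8L, 12L)) {
    z <- draw_usable_covariates(n, 3L)
    w <- covariate_weights(z)
    sp <- enumerate_schemes(n)
    scores <- balance_score(z, sp$schemes, w)
    bf <- apply(sp$schemes, 1L, function(a) bf_balance_score(z, a, w))
    expect_equal(scores, bf, tolerance = 1e-12)
    mirror <- balance_score(z, 1L - sp$schemes, w)
    expect_equal(scores, mirror, tolerance = 1e-12)
    equal_means <- apply(sp$schemes, 1L, function(a) {
      all(abs(colMeans(z[a == 1, , drop = FALSE]) -
                colMeans(z[a == 0, , drop = FALSE])) < 1e-12)
    })
    expect_equal(scores == 0, equal_means)
  }
})

test_that("candidate sets slice the sorted space with exact decile counts", {
  z16 <- draw_usable_covariates(16L, 4L)
  sp <- score_space(enumerate_schemes(16), z16)
  best <- build_candidate_set(sp, 0.1, "best")
  expect_equal(nrow(best$schemes), 1287)           # 10% of 12,870
  expect_true(max(best$scores) <= min(sp$scores[-sp$order[1:1287]]))

  sp8 <- score_space(enumerate_schemes(8), draw_usable_covariates(8L, 4L))
  expect_equal(nrow(build_candidate_set(sp8, 0.1, "best")$schemes), 7)

  all_cs <- build_candidate_set(sp8, 1, "all")
  expect_equal(nrow(all_cs$schemes), 70)
  expect_equal(all_cs$side, "all")

  # brute-force sort-and-slice oracle agreement on small spaces
  set.seed(11)
  for (n in c(6L, 10L, 12L)) {
    z <- draw_usable_covariates(n, 2L)
    sp <- score_space(enumerate_schemes(n), z)
    for (fr in c(0.1, 0.25, 0.5)) {
      got <- build_candidate_set(sp, fr, "best")$schemes
      expect_identical(unname(got), unname(bf_best_set(sp$schemes, sp$scores, fr)))
    }
    # best-p and worst-(1-p) partition the space when the cut separates
    # distinct scores
    for (fr in c(0.3, 0.5)) {
      nb <- nrow(build_candidate_set(sp, fr, "best")$schemes)
      nw <- nrow(build_candidate_set(sp, 1 - fr, "worst")$schemes)
      expect_equal(nb + nw, nrow(sp$schemes))
    }
  }
  expect_error(build_candidate_set(sp, 0, "best"),
               class = "ccrsim_invalid_fraction")
  expect_error(build_candidate_set(enumerate_schemes(6), 0.5, "best"),
               class = "ccrsim_invalid_input")
})

test_that("scheme selection is uniform over the candidate set and reproducible", {
  z <- draw_usable_covariates(8L, 2L)
  sp <- score_space(enumerate_schemes(8), z)
  cs <- build_candidate_set(sp, 0.1, "best")   # 7 schemes
  expect_equal(nrow(cs$schemes), 7)

  set.seed(5)
  a1 <- select_scheme(cs)
  set.seed(5)
  a2 <- select_scheme(cs)
  expect_identical(a1, a2)
  expect_equal(sum(a1$assignment), 4)

  singleton <- build_candidate_set(sp, 1 / nrow(sp$schemes), "best")
  expect_equal(nrow(singleton$schemes), 1)
  expect_identical(select_scheme(singleton)$assignment,
                   singleton$schemes[1, ])

  set.seed(99)
  draws <- replicate(14000, which(apply(
    cs$schemes == rep(select_scheme(cs)$assignment,
                      each = nrow(cs$schemes)), 1, all)))
  tab <- tabulate(draws, 7)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("strata tabulation covers all 2^C patterns in fixed order", {
  strata <- form_strata(ed_covariates())
  expect_equal(nrow(strata), 8)
  expect_equal(strata$n_clusters, c(1, 2, 1, 0, 1, 1, 1, 3))
  expect_equal(sum(strata$n_clusters), 10)
  expect_equal(sum(strata$n_clusters > 1), 2)
  # first pattern all-yes, last all-no
  expect_equal(unlist(strata[1, 1:3], use.names = FALSE), c(1, 1, 1))
  expect_equal(unlist(strata[8, 1:3], use.names = FALSE), c(0, 0, 0))

  two <- form_strata(matrix(c(0, 1), ncol = 1, dimnames = list(NULL, "z1")))
  expect_equal(two$n_clusters, c(1, 1))
})

test_that("candidate sets round-trip through CSV export", {
  z <- draw_usable_covariates(6L, 2L)
  sp <- score_space(enumerate_schemes(6), z)
  cs <- build_candidate_set(sp, 0.2, "best")
  path <- withr::local_tempfile(fileext = ".csv")
  write_candidate_set(cs, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(cs$schemes))
  expect_equal(back$balance_score, cs$scores)
  expect_false(is.unsorted(back$balance_score))
})
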