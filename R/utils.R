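# Internal helpers shared across modules.

# Half-away-from-zero rounding (for candidate-set sizes; round() in R rounds
# half to even, which would not reproduce decile set sizes exactly).
round_half_up <- function(x) floor(x + 0.5)

# Integer key identifying an assignment vector; cluster 1 is the most
# significant bit, so ordering by key is lexicographic on the vector.
# Exact for up to 52 clusters (doubles hold integers to 2^53); beyond that a
# string key is used.
scheme_keys <- function(schemes) {
  nc <- ncol(schemes)
  if (nc <= 52) {
    as.vector(schemes %*% 2^(nc - seq_len(nc)))
  } else {
    apply(schemes, 1L, paste0, collapse = "")
  }
}

# One substream seed per Monte Carlo replicate, all derived from a single
# scenario seed, so results are reproducible and independent of execution
# order.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

ccrsim_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ccrsim_error", "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
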