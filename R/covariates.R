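#' Coerce and validate a cluster-level covariate table
#'
#' A covariate table holds one row per cluster and one binary (0/1) column
#' per cluster-level covariate. Data frames are coerced to a numeric matrix;
#' row names (cluster identifiers) are preserved when present.
#'
#' @param x A matrix or data frame with one row per cluster and binary
#'   covariate columns.
#' @param require_even If `TRUE` (default), require an even number of rows
#'   (at least four), as needed for a 1:1 cluster allocation.
#' @return A numeric matrix with entries in \{0, 1\}.
#' @export
as_covariate_table <- function(x, require_even = TRUE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    ccrsim_error("covariate table must be a numeric matrix or data frame",
                 "ccrsim_invalid_input")
  }
  if (ncol(x) < 1L) {
    ccrsim_error("covariate table needs at least one covariate column",
                 "ccrsim_invalid_input")
  }
  if (!all(x %in% c(0, 1))) {
    ccrsim_error("covariate table entries must all be 0 or 1",
                 "ccrsim_invalid_input")
  }
  if (require_even && (nrow(x) < 4L || nrow(x) %% 2L != 0L)) {
    ccrsim_error("covariate table must have an even number of rows (>= 4) for 1:1 allocation",
                 "ccrsim_invalid_design")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("z", seq_len(ncol(x)))
  x
}

#' Inverse-variance weights for the balance metric
#'
#' Each covariate's weight is the inverse of the variance of its cluster
#' values, so covariates with little between-cluster spread contribute more
#' per unit of arm-mean difference. The sample variance (divisor `n - 1`) is
#' the default; the population divisor `n` is available for compatibility
#' with other software. Candidate-set membership is unaffected by the choice,
#' which rescales every weight by the same factor.
#'
#' @param covariates Covariate table (see [as_covariate_table()]).
#' @param divisor `"sample"` (divisor `n - 1`, default) or `"population"`
#'   (divisor `n`).
#' @return Named numeric vector of positive weights, one per covariate.
#' @examples
#' z <- cbind(z1 = c(0, 1, 0, 1), z2 = c(1, 1, 0, 0))
#' covariate_weights(z)
#' @export
covariate_weights <- function(covariates, divisor = c("sample", "population")) {
  divisor <- match.arg(divisor)
  z <- as_covariate_table(covariates, require_even = FALSE)
  v <- apply(z, 2L, stats::var)
  if (divisor == "population") v <- v * (nrow(z) - 1) / nrow(z)
  bad <- !is.finite(v) | v <= 0
  if (any(bad)) {
    ccrsim_error(
      paste0("zero-variance covariate column(s): ",
             paste(colnames(z)[bad], collapse = ", "),
             "; drop or redraw before computing balance weights"),
      "ccrsim_degenerate_covariate")
  }
  1 / v
}

#' Tabulate the strata a stratified randomisation would form
#'
#' Lists every possible combination of the binary covariates (all `2^C`
#' patterns, including empty ones) with the number of clusters falling in
#' each. Patterns are ordered with the first covariate varying slowest and
#' the value 1 listed before 0, so the first stratum is all-1 and the last is
#' all-0. Sparse strata are the usual argument against stratified
#' randomisation with several cluster-level covariates.
#'
#' @param covariates Covariate table (see [as_covariate_table()]).
#' @return Data frame with one row per stratum: the covariate pattern columns
#'   and `n_clusters`, the number of clusters with that pattern.
#' @examples
#' form_strata(ed_covariates())
#' @export
form_strata <- function(covariates) {
  z <- as_covariate_table(covariates, require_even = FALSE)
  C <- ncol(z)
  lev <- rep(list(c(1L, 0L)), C)
  names(lev) <- colnames(z)
  # expand.grid varies the first factor fastest; build reversed, then restore
  # column order so the first covariate varies slowest
  grid <- expand.grid(rev(lev), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_len(C)), drop = FALSE]
  pattern_key <- function(m) as.vector(as.matrix(m) %*% 2^(C - seq_len(C)))
  counts <- tabulate(match(pattern_key(z), pattern_key(grid)), nrow(grid))
  out <- cbind(grid, n_clusters = counts)
  rownames(out) <- NULL
  out
}

#' Read a cluster-level covariate table from CSV
#'
#' Expects a header row, a first column of cluster identifiers and binary
#' (0/1) covariate columns after it.
#'
#' @param path Path to the CSV file.
#' @return Covariate matrix with cluster identifiers as row names.
#' @export
read_covariate_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  if (ncol(raw) < 2L) {
    ccrsim_error("covariate CSV needs a cluster-id column plus >= 1 covariate column",
                 "ccrsim_invalid_input")
  }
  ids <- raw[[1L]]
  z <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(z) <- "numeric"
  rownames(z) <- as.character(ids)
  as_covariate_table(z, require_even = FALSE)
}
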