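# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a samples x features abundance matrix. Returns the matrix with
# dimnames guaranteed present.
check_view <- function(x, name = "view", require_nonneg = TRUE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric samples x features matrix", name))
  if (is.null(rownames(x)))
    rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- paste0("F", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop(sprintf("duplicate sample IDs in '%s'", name))
  if (anyDuplicated(colnames(x)))
    stop(sprintf("duplicate feature IDs in '%s'", name))
  if (require_nonneg && any(x < 0))
    stop(sprintf("negative values in '%s' (abundances must be >= 0)", name))
  x
}

# Close rows to unit sum. Rows summing to ~100 (percent scale) are
# renormalized with a notice.
close_rows <- function(x, notify = TRUE) {
  rs <- rowSums(x)
  if (any(rs <= 0)) stop("cannot close rows with non-positive sum")
  if (notify && all(abs(rs - 100) < 1)) {
    message("input rows sum to ~100 (percent scale); renormalizing to 1")
  }
  sweep(x, 1, rs, "/")
}

# Derive a child seed from a base seed and integer tags, kept within the
# 32-bit integer range.
child_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed)
  for (t in tags) s <- (s * 69069 + as.double(t) * 104729) %% 2147483647
  as.integer(s)
}

# Deterministic fold assignment: a permutation of 1..n cut into k folds of
# near-equal size. Depends only on (seed, n, k) so independently built
# schemes pair correctly.
fold_assignment <- function(n, k, seed) {
  if (k > n) stop(sprintf("cannot make %d folds from %d samples", k, n))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  idx <- sample.int(n)
  folds <- integer(n)
  folds[idx] <- rep_len(seq_len(k), n)
  folds
}

# Run an expression with a temporary RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
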