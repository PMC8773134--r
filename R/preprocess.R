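#' Multiplicative zero replacement for compositional data
#'
#' Replaces zeros in a relative-abundance table with a small value `delta`
#' and rescales the nonzero parts of each row multiplicatively so the row
#' still sums to one. This is the standard zero-imputation step required
#' before any log-ratio transform, since `log(0)` is undefined.
#'
#' For a row with `z` zero entries, each zero becomes `delta` and each
#' nonzero entry `x_i` becomes `x_i * (1 - z * delta)`, which preserves the
#' unit-sum closure exactly.
#'
#' @param view numeric samples x features matrix of relative abundances;
#'   rows must sum to ~1 (rows summing to ~100 are renormalized with a
#'   notice).
#' @param delta replacement value for zeros, or `"auto"` (default): `1/D^2`
#'   for `D` features, capped at half the smallest positive entry so the
#'   imputed value never exceeds observed abundances.
#' @return a matrix of the same shape with no zeros, rows summing to 1.
#' @examples
#' x <- rbind(a = c(0.5, 0.5, 0), b = c(0.2, 0.3, 0.5))
#' multiplicative_replacement(x, delta = 0.01)
#' @seealso [clr_transform()]
#' @export
multiplicative_replacement <- function(view, delta = "auto") {
  x <- check_view(view)
  rs <- rowSums(x)
  if (all(abs(rs - 100) < 1)) x <- close_rows(x)
  else if (any(abs(rowSums(x) - 1) > 1e-6)) {
    bad <- which(abs(rowSums(x) - 1) > 1e-6)
    if (any(rowSums(x)[bad] == 0))
      stop("row(s) of all zeros: composition undefined (",
           paste(rownames(x)[rowSums(x) == 0], collapse = ", "), ")")
    stop("rows must sum to ~1 (tolerance 1e-6); worst row: ",
         rownames(x)[which.max(abs(rowSums(x) - 1))])
  }
  if (any(rowSums(x) == 0))
    stop("row(s) of all zeros: composition undefined")

  pos <- x[x > 0]
  if (identical(delta, "auto")) {
    delta <- min(1 / ncol(x)^2, min(pos) / 2)
  } else {
    if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
      stop("'delta' must be a single positive number or \"auto\"")
    if (delta >= min(pos))
      stop(sprintf("delta (%g) must be smaller than the minimum positive value (%g)",
                   delta, min(pos)))
  }

  z <- rowSums(x == 0)
  if (all(z == 0)) return(x)
  if (any(z * delta >= 1))
    stop("delta too large: z * delta >= 1 for some row")
  out <- sweep(x, 1, 1 - z * delta, "*")
  out[x == 0] <- delta
  out
}

#' Centered log-ratio (CLR) transform
#'
#' Maps each compositional row `x` to `log(x) - mean(log(x))`, the standard
#' transform that takes a composition into unconstrained real coordinates.
#' Rows of the result sum to zero; the transform is invariant to row
#' rescaling, so it removes the unit-sum constraint without losing relative
#' information.
#'
#' @param view numeric samples x features matrix with strictly positive
#'   entries (run [multiplicative_replacement()] first if zeros are present).
#' @return a matrix of CLR coordinates, rows summing to 0 (within 1e-10).
#' @examples
#' x <- rbind(s1 = c(0.25, 0.25, 0.25, 0.25))
#' clr_transform(x)  # all zeros: symmetric composition
#' @export
clr_transform <- function(view) {
  x <- check_view(view, require_nonneg = FALSE)
  if (any(x <= 0))
    stop("CLR requires strictly positive values; run multiplicative_replacement() first")
  lx <- log(x)
  out <- lx - rowMeans(lx)
  out
}

#' One-hot encoding of subregion labels
#'
#' Builds an indicator block (one column per observed subregion level,
#' lexicographic column order) for use as extra, non-compositional design
#' columns.
#'
#' @param metadata a data frame with a `subregion` column, or a character
#'   vector / factor of labels. Sample IDs are taken from `sample_id` /
#'   rownames when available.
#' @return a samples x levels 0/1 matrix whose rows each sum to 1.
#' @export
encode_subregion <- function(metadata) {
  if (is.data.frame(metadata)) {
    if (!"subregion" %in% names(metadata))
      stop("metadata has no 'subregion' column")
    labels <- as.character(metadata$subregion)
    ids <- if ("sample_id" %in% names(metadata)) as.character(metadata$sample_id)
           else rownames(metadata)
  } else {
    labels <- as.character(metadata)
    ids <- names(metadata)
  }
  if (anyNA(labels) || any(labels == ""))
    stop("missing subregion label(s) at position(s): ",
         paste(head(which(is.na(labels) | labels == ""), 5), collapse = ", "))
  lev <- sort(unique(labels))
  if (length(lev) == 1L)
    warning("a single subregion level: the one-hot block is uninformative")
  m <- matrix(0L, nrow = length(labels), ncol = length(lev),
              dimnames = list(ids, paste0("subregion.", lev)))
  m[cbind(seq_along(labels), match(labels, lev))] <- 1L
  m
}

#' Assemble a model design matrix from CLR and extra blocks
#'
#' Column-binds a primary CLR matrix with extra blocks (a one-hot subregion
#' block, a second view's CLR matrix, ...). Indicator blocks are appended
#' as-is — they are covariates, not compositional parts, so they never enter
#' the log-ratio geometry. Block origins are recorded in the
#' `"origin"` attribute (one tag per column).
#'
#' @param primary samples x features numeric matrix (typically CLR output).
#' @param extras named list of additional blocks with identical sample IDs
#'   in identical order; names become origin tags.
#' @return the concatenated matrix with an `"origin"` character attribute.
#' @examples
#' clr <- clr_transform(multiplicative_replacement(
#'   rbind(s1 = c(.5, .5, 0), s2 = c(.2, .3, .5))))
#' oh <- encode_subregion(c(s1 = "EA", s2 = "NA"))
#' d <- assemble_design(clr, list(subregion = oh))
#' attr(d, "origin")
#' @export
assemble_design <- function(primary, extras = list()) {
  primary <- check_view(primary, require_nonneg = FALSE)
  origin <- rep("primary", ncol(primary))
  out <- primary
  for (nm in names(extras)) {
    blk <- check_view(extras[[nm]], name = nm, require_nonneg = FALSE)
    if (!identical(rownames(blk), rownames(out))) {
      only_a <- setdiff(rownames(out), rownames(blk))
      only_b <- setdiff(rownames(blk), rownames(out))
      stop(sprintf(
        "sample mismatch in block '%s': %d only in primary (%s...), %d only in block (%s...)",
        nm, length(only_a), paste(head(only_a, 3), collapse = ","),
        length(only_b), paste(head(only_b, 3), collapse = ",")))
    }
    dup <- intersect(colnames(blk), colnames(out))
    if (length(dup))
      colnames(blk) <- paste(nm, colnames(blk), sep = ".")
    out <- cbind(out, blk)
    origin <- c(origin, rep(nm, ncol(blk)))
  }
  attr(out, "origin") <- origin
  out
}
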