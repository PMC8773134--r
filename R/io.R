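#' Read a relative-abundance table from TSV
#'
#' Expects a tab-separated file with a header row of feature IDs and the
#' first column holding sample IDs (the usual export format of taxonomic
#' and pathway profilers). Rows summing to ~100 (percent scale) are
#' renormalized to 1 with a notice.
#'
#' @param path file path.
#' @return a validated samples x features numeric matrix.
#' @seealso [write_abundance_table()]
#' @export
read_abundance_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected a sample-ID column plus feature columns")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric values in column '%s'", names(df)[-1][bad]))
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %d (sample '%s'), feature '%s'",
                 idx[1], ids[idx[1]], colnames(m)[idx[2]]))
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at row %d (sample '%s'), feature '%s'",
                 idx[1], ids[idx[1]], colnames(m)[idx[2]]))
  }
  rownames(m) <- ids
  m <- check_view(m)
  rs <- rowSums(m)
  if (all(abs(rs - 100) < 1)) m <- close_rows(m)
  m
}

#' Write a relative-abundance table to TSV
#'
#' @param view samples x features numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(view, path) {
  view <- check_view(view)
  df <- data.frame(sample_id = rownames(view), view,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align abundance views and metadata on shared samples
#'
#' Establishes a canonical sample order (the metadata order restricted to
#' samples present in at least one view), drops samples absent from the
#' metadata, and records a per-view availability mask. Views are *not*
#' forced to a common intersection: late-fusion stacking can train per-view
#' stage-1 models on all samples a view has, and only the generalizer needs
#' the overlap.
#'
#' @param views named list of abundance matrices.
#' @param metadata data frame with a `sample_id` column.
#' @return a list with `views` (reordered, possibly different sample sets),
#'   `metadata` (canonical order), `mask` (samples x views logical matrix of
#'   availability) and `dropped` (IDs present in views but not in metadata).
#' @export
align_samples <- function(views, metadata) {
  stopifnot(is.list(views), length(views) >= 1, "sample_id" %in% names(metadata))
  views <- lapply(views, check_view)
  meta_ids <- as.character(metadata$sample_id)
  view_ids <- unique(unlist(lapply(views, rownames)))
  canonical <- meta_ids[meta_ids %in% view_ids]
  if (length(canonical) == 0)
    stop("no samples shared between metadata and any view")
  dropped <- setdiff(view_ids, meta_ids)
  if (length(dropped))
    message(sprintf("%d sample(s) present in views but missing from metadata were dropped: %s%s",
                    length(dropped), paste(head(dropped, 3), collapse = ", "),
                    if (length(dropped) > 3) ", ..." else ""))
  out_views <- lapply(views, function(v) {
    keep <- canonical[canonical %in% rownames(v)]
    v[keep, , drop = FALSE]
  })
  mask <- vapply(views, function(v) canonical %in% rownames(v),
                 logical(length(canonical)))
  rownames(mask) <- canonical
  list(views = out_views,
       metadata = metadata[match(canonical, meta_ids), , drop = FALSE],
       mask = mask,
       dropped = dropped)
}
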