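#' Cross-validated association between geography and age
#'
#' Mean repeated-CV R-squared of predicting age from geography indicator
#' columns alone. A high value means sampling geography is confounded with
#' age and would let an aging clock cheat off the sampling design rather
#' than the microbiome.
#'
#' @param onehot one-hot indicator matrix (e.g. from [encode_subregion()]).
#' @param ages numeric ages.
#' @param learner `"RF"` (random forest) or `"LR"` (linear regression).
#' @param scheme a [cv_scheme()]; default 10 x 5.
#' @param seed seed for the learner.
#' @return mean cross-validated R-squared (raw; may be negative under no
#'   association).
#' @export
assoc_region_age <- function(onehot, ages, learner = c("RF", "LR"),
                             scheme = cv_scheme(), seed = 1L) {
  learner <- match.arg(learner)
  onehot <- as.matrix(onehot)
  if (ncol(onehot) < 2)
    warning("fewer than 2 indicator columns: the association is degenerate")
  sc <- repeated_cv(learner_spec(learner, seed = seed), onehot, ages, scheme)
  attr(sc, "mean_r2")
}

#' Iterative subregion screening to decouple geography from age
#'
#' Drops subregion bins that are too small for stable estimates, then
#' repeatedly fits a random-forest age model on the one-hot subregion
#' encoding and removes the subregion with the highest (impurity) feature
#' importance — the bin contributing most to the geography-age association
#' — until the cross-validated association R-squared falls below
#' `threshold` or a single subregion remains.
#'
#' @param metadata data frame with `subregion` and `age` columns (plus
#'   `sample_id` if available).
#' @param min_bin_size bins with `<=` this many samples are dropped before
#'   the loop (default 200).
#' @param threshold stop once the association R-squared is below this
#'   (default 0.01).
#' @param scheme [cv_scheme()] used for each epoch's association estimate.
#' @param seed seed for forests and CV.
#' @return an object of class `"screen_result"`: list with `epochs` (data
#'   frame: `removed_subregion`, `importance_score`, `assoc_r2` measured
#'   before that removal), `retained_subregions`, `final_assoc_r2`,
#'   `retained_sample_ids`, `dropped_small_bins`.
#' @export
screen_subregions <- function(metadata, min_bin_size = 200, threshold = 0.01,
                              scheme = cv_scheme(), seed = 1L) {
  stopifnot(all(c("subregion", "age") %in% names(metadata)))
  ids <- if ("sample_id" %in% names(metadata)) as.character(metadata$sample_id)
         else as.character(seq_len(nrow(metadata)))
  md <- data.frame(sample_id = ids, subregion = as.character(metadata$subregion),
                   age = metadata$age, stringsAsFactors = FALSE)

  sizes <- table(md$subregion)
  small <- names(sizes)[sizes <= min_bin_size]
  if (length(small) == length(sizes))
    stop(sprintf("all subregion bins have <= %d samples", min_bin_size))
  md <- md[!md$subregion %in% small, , drop = FALSE]

  epochs <- data.frame(removed_subregion = character(0),
                       importance_score = numeric(0),
                       assoc_r2 = numeric(0), stringsAsFactors = FALSE)
  repeat {
    remaining <- sort(unique(md$subregion))
    oh <- encode_subregion(md$subregion)
    if (length(remaining) == 1L) {
      final_r2 <- NA_real_
      break
    }
    r2 <- assoc_region_age(oh, md$age, "RF", scheme, seed = child_seed(seed, nrow(epochs)))
    if (r2 < threshold) {
      final_r2 <- r2
      break
    }
    rf <- ranger::ranger(x = df_norm(oh), y = md$age, num.trees = 500,
                         importance = "impurity",
                         seed = child_seed(seed, 101L, nrow(epochs)),
                         num.threads = 1)
    imp <- rf$variable.importance
    # importance per subregion = its indicator column's impurity decrease,
    # normalized so the ranking is scale-free
    imp <- imp / sum(imp)
    worst <- remaining[which.max(imp)]
    epochs <- rbind(epochs, data.frame(removed_subregion = worst,
                                       importance_score = unname(max(imp)),
                                       assoc_r2 = r2,
                                       stringsAsFactors = FALSE))
    md <- md[md$subregion != worst, , drop = FALSE]
  }
  structure(list(epochs = epochs,
                 retained_subregions = sort(unique(md$subregion)),
                 final_assoc_r2 = final_r2,
                 retained_sample_ids = md$sample_id,
                 dropped_small_bins = small),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Subregion-age decoupling screen\n")
  if (length(x$dropped_small_bins))
    cat("  small bins dropped: ", paste(x$dropped_small_bins, collapse = ", "), "\n")
  if (nrow(x$epochs)) {
    cat(sprintf("  %d removal epoch(s):\n", nrow(x$epochs)))
    for (i in seq_len(nrow(x$epochs)))
      cat(sprintf("    %d. removed %s (importance %.3f, assoc R2 %.3f)\n",
                  i, x$epochs$removed_subregion[i],
                  x$epochs$importance_score[i], x$epochs$assoc_r2[i]))
  } else cat("  no removals needed\n")
  cat(sprintf("  retained: %s (%d samples); final assoc R2 = %s\n",
              paste(x$retained_subregions, collapse = ", "),
              length(x$retained_sample_ids),
              ifelse(is.na(x$final_assoc_r2), "NA (one bin left)",
                     sprintf("%.4f", x$final_assoc_r2))))
  invisible(x)
}
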