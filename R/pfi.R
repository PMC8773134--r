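#' Permutation feature importance on a frozen ensemble
#'
#' Measures each feature's contribution to the aging clock by randomly
#' shuffling that feature's column across the evaluation samples
#' (`n_shuffles` independent shuffles, default 50), re-running the frozen
#' ensemble, and recording the drop in R-squared relative to the
#' unshuffled baseline. Evaluation should use samples held out from
#' generalizer training so the deltas are not optimistic. Shuffling
#' operates on the model's input representation (post-CLR, post-selection
#' columns); one-hot covariate columns (origin tag other than
#' `"primary"`) are excluded unless `include_covariates = TRUE`.
#'
#' @param model an [agestack()] fit.
#' @param newdata matrix or named list of per-view design matrices
#'   (held-out samples).
#' @param y true ages for `newdata`.
#' @param n_shuffles shuffles per feature (>= 2; default 50).
#' @param seed seed for the shuffle stream.
#' @param include_covariates also permute non-primary (covariate) columns.
#' @return object of class `"pfi_result"`: list with `features` (data
#'   frame: `feature_id`, `view`, `mean_delta_r2`), `deltas` (features x
#'   shuffles matrix of R-squared reductions), `permuted_r2` (features x
#'   shuffles), `baseline_r2`, `n_shuffles`.
#' @export
permutation_importance <- function(model, newdata, y, n_shuffles = 50,
                                   seed = 1L, include_covariates = FALSE) {
  stopifnot(inherits(model, "agestack"))
  if (n_shuffles < 2) stop("n_shuffles must be >= 2 for significance testing")
  views <- as_view_list(newdata)
  need <- names(model$views)
  if (length(views) == 1L && length(need) == 1L) names(views) <- need
  common <- Reduce(intersect, lapply(views[need], rownames))
  # align rows to the evaluation set and columns to the training order
  views <- setNames(lapply(need, function(v) {
    fid <- model$views[[v]]$feature_ids
    if (!all(fid %in% colnames(views[[v]])))
      stop(sprintf("view '%s': newdata lacks training features", v))
    views[[v]][common, fid, drop = FALSE]
  }), need)
  stopifnot(length(common) == length(y))
  n <- length(common)

  baseline <- score_predictions(y, predict(model, views))[["r2"]]

  # all views replicated n_shuffles times: one batched prediction per
  # feature instead of one per shuffle
  rn <- paste0(rep(common, n_shuffles), ".", rep(seq_len(n_shuffles), each = n))
  rep_views <- lapply(views, function(vm) {
    big <- vm[rep(seq_len(n), n_shuffles), , drop = FALSE]
    rownames(big) <- rn
    big
  })

  feat_rows <- list(); delta_rows <- list(); perm_rows <- list()
  for (v in need) {
    origin <- model$views[[v]]$origin
    fids <- model$views[[v]]$feature_ids
    test_cols <- which(include_covariates | origin == "primary")
    for (jc in test_cols) {
      perm_r2 <- numeric(n_shuffles)
      col <- views[[v]][, jc]
      shuffles <- with_seed(child_seed(seed, match(v, need), jc),
                            replicate(n_shuffles, sample.int(n)))
      big_views <- rep_views
      big_views[[v]][, jc] <- col[as.vector(shuffles)]
      yhat <- predict(model, big_views)
      for (s in seq_len(n_shuffles))
        perm_r2[s] <- score_predictions(y, yhat[(s - 1) * n + seq_len(n)])[["r2"]]
      feat_rows[[length(feat_rows) + 1L]] <-
        data.frame(feature_id = fids[jc], view = v,
                   mean_delta_r2 = baseline - mean(perm_r2),
                   stringsAsFactors = FALSE)
      delta_rows[[length(delta_rows) + 1L]] <- baseline - perm_r2
      perm_rows[[length(perm_rows) + 1L]] <- perm_r2
    }
  }
  features <- do.call(rbind, feat_rows)
  deltas <- do.call(rbind, delta_rows)
  permuted <- do.call(rbind, perm_rows)
  rownames(deltas) <- rownames(permuted) <- features$feature_id
  structure(list(features = features, deltas = deltas,
                 permuted_r2 = permuted, baseline_r2 = baseline,
                 n_shuffles = n_shuffles),
            class = "pfi_result")
}

#' Significance-test and rank permutation importances
#'
#' For each feature, a two-sided Wilcoxon signed-rank test compares the
#' per-shuffle permuted R-squared values against the unshuffled baseline
#' (paired by shuffle against the constant baseline, i.e. a signed-rank
#' test of the deltas against zero). P-values are Bonferroni-corrected
#' jointly across all tested features of all views. Features whose
#' permutation *improves* the model (negative mean delta) are never
#' called significant. Significant features are biomarker candidates,
#' ranked by mean R-squared reduction.
#'
#' @param pfi a `"pfi_result"` from [permutation_importance()].
#' @param alpha family-wise significance level (default 0.05).
#' @return data frame with one row per feature: `feature_id`, `view`,
#'   `mean_delta_r2`, `p_value`, `p_adjusted`, `significant`, `rank`
#'   (1 = largest reduction), ordered by rank.
#' @export
test_biomarkers <- function(pfi, alpha = 0.05) {
  stopifnot(inherits(pfi, "pfi_result"))
  nf <- nrow(pfi$features)
  p <- vapply(seq_len(nf), function(i) {
    d <- pfi$deltas[i, ]
    if (all(d == 0)) return(1)
    nz <- sum(d != 0)
    suppressWarnings(
      wilcox.test(d, mu = 0, exact = nz <= 25, correct = TRUE)$p.value)
  }, numeric(1))
  out <- pfi$features
  out$p_value <- p
  out$p_adjusted <- pmin(1, p * nf)
  out$significant <- out$p_adjusted < alpha & out$mean_delta_r2 > 0
  out$rank <- rank(-out$mean_delta_r2, ties.method = "first")
  out[order(out$rank), , drop = FALSE]
}

#' Spearman association between a feature and age
#'
#' Tie-corrected Spearman rank correlation with an optional Bonferroni
#' multiplier across the reported biomarkers.
#'
#' @param feature_values numeric vector (e.g. a feature's relative
#'   abundance across samples), length >= 10.
#' @param ages ages for the same samples.
#' @param n_comparisons Bonferroni family size.
#' @return list with `rho`, `p_value`, `p_adjusted`; `rho` is `NA` for a
#'   constant feature.
#' @export
spearman_age_association <- function(feature_values, ages, n_comparisons = 1) {
  stopifnot(length(feature_values) == length(ages))
  if (length(ages) < 10) stop("need at least 10 samples")
  if (sd(feature_values) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, p_adjusted = NA_real_))
  ct <- suppressWarnings(
    cor.test(feature_values, ages, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       p_adjusted = min(1, ct$p.value * n_comparisons))
}

#' Full biomarker report for a fitted clock
#'
#' Combines [permutation_importance()], [test_biomarkers()] and per-
#' biomarker [spearman_age_association()] (computed on the original
#' relative abundances, Bonferroni across the tested features) into the
#' tabular report of the analysis.
#'
#' @param model an [agestack()] fit.
#' @param newdata held-out design matrices (model input representation).
#' @param abundances named list of the *untransformed* abundance views for
#'   the same samples (used for the Spearman annotation); defaults to
#'   `newdata`.
#' @param y held-out ages.
#' @param n_shuffles,seed passed to [permutation_importance()].
#' @return data frame: biomarker table with `rho` and `rho_p_adjusted`
#'   columns appended.
#' @export
biomarker_report <- function(model, newdata, y, abundances = NULL,
                             n_shuffles = 50, seed = 1L) {
  pfi <- permutation_importance(model, newdata, y, n_shuffles = n_shuffles,
                                seed = seed)
  tab <- test_biomarkers(pfi)
  if (is.null(abundances)) abundances <- newdata
  ab <- as_view_list(abundances)
  if (length(ab) == 1L && length(model$views) == 1L)
    names(ab) <- names(model$views)
  nf <- nrow(tab)
  tab$rho <- NA_real_; tab$rho_p_adjusted <- NA_real_
  for (i in seq_len(nf)) {
    v <- ab[[tab$view[i]]]
    if (is.null(v) || !tab$feature_id[i] %in% colnames(v)) next
    sp <- spearman_age_association(v[, tab$feature_id[i]], y,
                                   n_comparisons = nf)
    tab$rho[i] <- sp$rho
    tab$rho_p_adjusted[i] <- sp$p_adjusted
  }
  tab
}
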