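#' Repeated k-fold cross-validation scheme
#'
#' Fold assignments for repeat `r` are derived deterministically from
#' `seed` and `r`, and depend only on `(seed, n_folds, n)` — two schemes
#' built with the same parameters produce identical splits, which is what
#' makes paired model comparisons valid.
#'
#' @param n_repeats number of repeats (default 10).
#' @param n_folds folds per repeat (default 5).
#' @param seed base seed.
#' @return an object of class `"cv_scheme"`.
#' @export
cv_scheme <- function(n_repeats = 10, n_folds = 5, seed = 1L) {
  stopifnot(n_repeats >= 1, n_folds >= 2)
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

# fold labels (1..k) for every repeat; a list of integer vectors
cv_splits <- function(scheme, n) {
  if (scheme$n_folds > n)
    stop(sprintf("n_folds (%d) exceeds the number of samples (%d)",
                 scheme$n_folds, n))
  lapply(seq_len(scheme$n_repeats), function(r)
    fold_assignment(n, scheme$n_folds, child_seed(scheme$seed, r)))
}

#' Regression metrics: R-squared and mean absolute error
#'
#' `R2 = 1 - SS_res / SS_tot` with `SS_tot` computed about the mean of
#' `y_true` (on a held-out fold, the fold's own mean), and
#' `MAE = mean(|y - yhat|)` in years.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2).
#' @return named numeric vector `c(r2 = , mae = )`.
#' @export
score_predictions <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("need at least 2 observations")
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stop("constant y_true: R-squared undefined")
  c(r2 = 1 - sum((y_true - y_pred)^2) / sst,
    mae = mean(abs(y_true - y_pred)))
}

#' Repeated cross-validated scores for one learner
#'
#' Fits the learner on `k - 1` folds and scores it on the held-out fold,
#' for every fold of every repeat. All `n_repeats * n_folds` per-split
#' scores are returned; downstream comparisons pair splits, never just
#' means.
#'
#' @param spec a [learner_spec()] or [custom_learner()] handle.
#' @param X numeric design matrix.
#' @param y ages (years).
#' @param scheme a [cv_scheme()].
#' @return object of class `"cv_scores"`: a data frame with columns
#'   `repeat_`, `fold`, `r2`, `mae`, plus attributes `scheme`, `learner`,
#'   `mean_r2`, `mean_mae`.
#' @export
repeated_cv <- function(spec, X, y, scheme = cv_scheme()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  h <- make_learner(spec)
  splits <- cv_splits(scheme, nrow(X))
  rows <- list()
  for (r in seq_along(splits)) {
    folds <- splits[[r]]
    for (f in seq_len(scheme$n_folds)) {
      tr <- folds != f
      m <- h$fit(X[tr, , drop = FALSE], y[tr])
      yhat <- h$predict(m, X[!tr, , drop = FALSE])
      sc <- score_predictions(y[!tr], yhat)
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_ = r, fold = f, r2 = sc[["r2"]], mae = sc[["mae"]])
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("cv_scores", "data.frame"),
            scheme = scheme, learner = h$name,
            mean_r2 = mean(out$r2), mean_mae = mean(out$mae))
}

#' @export
print.cv_scores <- function(x, ...) {
  cat(sprintf("%s: %d splits (%d x %d CV): mean R2 = %.3f, mean MAE = %.2f y\n",
              attr(x, "learner") %||% "cv", nrow(x),
              attr(x, "scheme")$n_repeats, attr(x, "scheme")$n_folds,
              attr(x, "mean_r2"), attr(x, "mean_mae")))
  invisible(x)
}

#' Paired Wilcoxon comparison of two cross-validated score sets
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-split scores of
#' two models evaluated under the *same* CV scheme (identical splits make
#' the pairing valid), with a Bonferroni multiplier for families of
#' comparisons. Zero differences are discarded (signed-rank convention);
#' the exact distribution is used for up to 25 informative pairs, the
#' normal approximation above that.
#'
#' @param scores_a,scores_b `"cv_scores"` objects (or plain numeric vectors
#'   of paired per-split scores).
#' @param n_comparisons Bonferroni family size (adjusted p = min(1, p *
#'   n_comparisons)).
#' @param metric `"r2"` or `"mae"` when `"cv_scores"` objects are given.
#' @return list with `p_value`, `p_adjusted`, `statistic`,
#'   `mean_difference` (a - b).
#' @export
paired_cv_test <- function(scores_a, scores_b, n_comparisons = 1,
                           metric = c("r2", "mae")) {
  metric <- match.arg(metric)
  get_vec <- function(s) if (inherits(s, "cv_scores")) s[[metric]] else as.numeric(s)
  if (inherits(scores_a, "cv_scores") && inherits(scores_b, "cv_scores")) {
    sa <- attr(scores_a, "scheme"); sb <- attr(scores_b, "scheme")
    if (!identical(unclass(sa), unclass(sb)))
      stop("the two score sets were produced under different CV schemes")
  }
  a <- get_vec(scores_a); b <- get_vec(scores_b)
  if (length(a) != length(b)) stop("score lists have different lengths")
  d <- a - b
  nz <- sum(d != 0)
  if (nz == 0) {
    res <- list(p_value = 1, statistic = NA_real_)
  } else {
    wt <- suppressWarnings(
      wilcox.test(a, b, paired = TRUE, exact = nz <= 25, correct = TRUE))
    res <- list(p_value = wt$p.value, statistic = unname(wt$statistic))
  }
  res$p_adjusted <- min(1, res$p_value * n_comparisons)
  res$mean_difference <- mean(d)
  res
}
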