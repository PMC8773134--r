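# Feature scoring backends for select_features().

# univariate linear F statistic per feature (the f_regression score)
f_regression_scores <- function(X, y) {
  n <- nrow(X)
  r <- suppressWarnings(cor(X, y))
  r[is.na(r)] <- 0
  r2 <- r^2
  drop(r2 * (n - 2) / pmax(1 - r2, .Machine$double.eps))
}

# plug-in mutual information with equal-frequency binning of both variables
mi_scores <- function(X, y, n_bins = NULL) {
  n <- nrow(X)
  if (is.null(n_bins)) n_bins <- max(3L, min(10L, floor(sqrt(n / 5))))
  bin <- function(v) {
    if (length(unique(v)) <= 1) return(rep(1L, length(v)))
    br <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 3) return(as.integer(factor(v)))
    cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  by_ <- bin(y)
  apply(X, 2, function(col) {
    bx <- bin(col)
    if (length(unique(bx)) <= 1) return(0)
    tab <- table(bx, by_) / n
    px <- rowSums(tab); py <- colSums(tab)
    nz <- tab > 0
    sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
  })
}

model_importance_scores <- function(method, X, y, seed) {
  if (method == "RF") {
    rf <- ranger::ranger(x = df_norm(X), y = y, num.trees = 500,
                         importance = "impurity", seed = seed, num.threads = 1)
    return(setNames(unname(rf$variable.importance), colnames(X)))
  }
  h <- make_learner(learner_spec(method, seed = seed))
  m <- h$fit(X, y)
  imp <- xgboost::xgb.importance(model = m)
  out <- setNames(numeric(ncol(X)), colnames(X))
  out[imp$Feature] <- imp$Gain
  out
}

#' Score and select features for age regression
#'
#' Ranks features by one of the compared selection methods and keeps those
#' passing `keep_rule`:
#' * `"FR"` — univariate linear regression F statistic;
#' * `"MI"` — mutual information (equal-frequency binning plug-in
#'   estimate);
#' * `"RF"`, `"GBRT"`, `"XGB"`, `"XGBRF"`, `"LGB"` — the fitted model's
#'   own importance (impurity decrease for the forest, split gain for the
#'   boosters).
#'
#' @param method one of `"FR"`, `"MI"`, `"RF"`, `"GBRT"`, `"XGB"`,
#'   `"XGBRF"`, `"LGB"`.
#' @param X design matrix with feature IDs as column names.
#' @param y ages.
#' @param keep_rule `list(type = "above_mean")` (default: keep features
#'   scoring above the mean score) or `list(type = "top_k", k = )`.
#' @param seed seed for stochastic scorers.
#' @return character vector of selected feature IDs (a subset of
#'   `colnames(X)`), with the full score vector in attribute `"scores"`.
#' @export
select_features <- function(method = c("FR", "MI", "RF", "GBRT", "XGB", "XGBRF", "LGB"),
                            X, y, keep_rule = list(type = "above_mean"),
                            seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  scores <- switch(method,
                   FR = f_regression_scores(X, y),
                   MI = mi_scores(X, y),
                   model_importance_scores(method, X, y, seed))
  names(scores) <- colnames(X)
  keep <- switch(keep_rule$type,
                 above_mean = scores > mean(scores),
                 top_k = rank(-scores, ties.method = "first") <= keep_rule$k,
                 stop("unknown keep_rule type: ", keep_rule$type))
  sel <- colnames(X)[keep]
  if (length(sel) == 0)
    stop("selection kept no features; loosen keep_rule (e.g. top_k)")
  structure(sel, scores = scores)
}

#' Evaluate one selection method against the unselected baseline
#'
#' Runs every learner under the shared CV scheme on the full and on the
#' selected design, compares the paired per-split R-squared with a
#' Wilcoxon signed-rank test (Bonferroni across the learners), and labels
#' each learner `degraded`, `unchanged` or `improved`. A verdict other
#' than `unchanged` requires adjusted p < 0.05.
#'
#' @param method passed to [select_features()].
#' @param X,y design matrix and ages.
#' @param specs named list of [learner_spec()]s to evaluate (default: the
#'   full registry).
#' @param scheme shared [cv_scheme()].
#' @param keep_rule,seed passed to [select_features()].
#' @return object of class `"selection_outcome"`: list with `method`,
#'   `selected`, `n_features`, and `deltas` (data frame: learner,
#'   mean_r2_before, mean_r2_after, p_adjusted, verdict).
#' @export
evaluate_selection <- function(method, X, y,
                               specs = learner_registry(),
                               scheme = cv_scheme(),
                               keep_rule = list(type = "above_mean"),
                               seed = 1L) {
  X <- as.matrix(X)
  sel <- select_features(method, X, y, keep_rule, seed = seed)
  Xs <- X[, sel, drop = FALSE]
  rows <- lapply(names(specs), function(nm) {
    before <- repeated_cv(specs[[nm]], X, y, scheme)
    after <- repeated_cv(specs[[nm]], Xs, y, scheme)
    tst <- paired_cv_test(after, before, n_comparisons = length(specs))
    verdict <- if (tst$p_adjusted < 0.05)
      ifelse(tst$mean_difference < 0, "degraded", "improved") else "unchanged"
    data.frame(learner = nm,
               mean_r2_before = attr(before, "mean_r2"),
               mean_r2_after = attr(after, "mean_r2"),
               p_adjusted = tst$p_adjusted,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  structure(list(method = method, selected = as.character(sel),
                 n_features = length(sel),
                 deltas = do.call(rbind, rows)),
            class = "selection_outcome")
}

#' Choose the optimal selection method
#'
#' Adjudicates competing selection outcomes: fewest learners degraded,
#' then most learners improved, then smallest selected dimension.
#' Deterministic; the first outcome wins remaining ties.
#'
#' @param outcomes list of `"selection_outcome"` objects evaluated on the
#'   same learner set and CV scheme.
#' @return the chosen `"selection_outcome"`.
#' @export
adjudicate_selection <- function(outcomes) {
  if (length(outcomes) == 0) stop("no selection outcomes to adjudicate")
  stopifnot(all(vapply(outcomes, inherits, logical(1), "selection_outcome")))
  degraded <- vapply(outcomes, function(o) sum(o$deltas$verdict == "degraded"), numeric(1))
  improved <- vapply(outcomes, function(o) sum(o$deltas$verdict == "improved"), numeric(1))
  nfeat <- vapply(outcomes, function(o) o$n_features, numeric(1))
  ord <- order(degraded, -improved, nfeat)
  outcomes[[ord[1]]]
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat(sprintf("Feature selection [%s]: %d features kept\n", x$method, x$n_features))
  print(x$deltas, row.names = FALSE)
  invisible(x)
}
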