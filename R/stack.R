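# Two-stage stacking: stage 1 builds out-of-fold (OOF) base-learner
# predictions ("Predicted Training Set") and fold-model means on new data
# ("Predicted Test Set"); stage 2 fits a generalizer on the OOF columns.

.stack_base_names <- c("Lasso", "EN", "BR", "SVM", "RF", "GBRT", "XGB",
                       "XGBRF", "LGB")
.generalizer_names <- c("SA", "LR", "Lasso", "BR", "LSVM", "SVM", "DT")

#' Stage-1 out-of-fold predictions
#'
#' Splits the training set into `k` folds (one shared split for all
#' learners, so OOF columns are comparable and pairing is valid). Each
#' learner is fitted `k` times on `k - 1` folds; its held-out-fold
#' predictions fill the OOF training matrix, so the entry for sample `i`
#' always comes from a model whose training folds excluded `i`. Each of
#' the `k` fold models also predicts `X_test`, and the fold-mean fills the
#' test matrix.
#'
#' @param specs named list of [learner_spec()]s or [custom_learner()]
#'   handles.
#' @param X_train,y_train training design and ages.
#' @param X_test optional design to produce fold-mean predictions for.
#' @param k number of stage-1 folds (default 5).
#' @param seed seed for the fold split.
#' @return list with `oof_train` (n_train x learners), `oof_test`
#'   (n_test x learners or `NULL`), `models` (per learner, the `k` frozen
#'   fold models), `folds` (integer fold labels) and `specs`.
#' @export
stage1_oof <- function(specs, X_train, y_train, X_test = NULL, k = 5,
                       seed = 1L) {
  X_train <- as.matrix(X_train)
  stopifnot(nrow(X_train) == length(y_train), k >= 2)
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s$name, character(1))
  n <- nrow(X_train)
  folds <- fold_assignment(n, k, seed)
  if (any(tabulate(folds, k) == 0)) stop("a stage-1 fold has no samples")

  oof_train <- matrix(NA_real_, n, length(specs),
                      dimnames = list(rownames(X_train), names(specs)))
  oof_test <- if (!is.null(X_test)) {
    X_test <- as.matrix(X_test)
    matrix(0, nrow(X_test), length(specs),
           dimnames = list(rownames(X_test), names(specs)))
  }
  models <- setNames(vector("list", length(specs)), names(specs))
  for (j in seq_along(specs)) {
    h <- make_learner(specs[[j]])
    fold_models <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- folds != f
      m <- h$fit(X_train[tr, , drop = FALSE], y_train[tr])
      fold_models[[f]] <- m
      oof_train[!tr, j] <- h$predict(m, X_train[!tr, , drop = FALSE])
      if (!is.null(oof_test))
        oof_test[, j] <- oof_test[, j] + h$predict(m, X_test) / k
    }
    models[[j]] <- fold_models
  }
  list(oof_train = oof_train, oof_test = oof_test, models = models,
       folds = folds, specs = specs)
}

#' Fit the stage-2 generalizer
#'
#' Learns weights over the base learners' OOF prediction columns. `"SA"`
#' is the simple-average baseline (equal weights, nothing fitted); the
#' rest are ordinary regressors from the registry. A decision-tree
#' generalizer is permitted but warns, since an unconstrained tree on OOF
#' columns tends to overfit the stage-2 problem badly.
#'
#' @param oof_train OOF prediction matrix (samples x learners).
#' @param y_train ages.
#' @param method one of `"SA"`, `"LR"`, `"Lasso"`, `"BR"`, `"LSVM"`,
#'   `"SVM"`, `"DT"` (default `"LR"`).
#' @param seed seed for stochastic generalizers.
#' @return object of class `"generalizer"`.
#' @export
fit_generalizer <- function(oof_train, y_train, method = "LR", seed = 1L) {
  method <- match.arg(method, .generalizer_names)
  oof_train <- as.matrix(oof_train)
  if (method == "SA")
    return(structure(list(method = "SA", columns = colnames(oof_train)),
                     class = "generalizer"))
  if (method == "DT")
    warning("a decision-tree generalizer is prone to severe overfitting of the OOF columns")
  h <- make_learner(learner_spec(method, seed = seed))
  model <- h$fit(oof_train, y_train)
  structure(list(method = method, model = model, handle = h,
                 columns = colnames(oof_train)),
            class = "generalizer")
}

#' @export
predict.generalizer <- function(object, newdata, ...) {
  Z <- as.matrix(newdata)
  if (!is.null(object$columns) && !is.null(colnames(Z)))
    Z <- Z[, object$columns, drop = FALSE]
  if (object$method == "SA") return(rowMeans(Z))
  object$handle$predict(object$model, Z)
}

#' @export
coef.generalizer <- function(object, ...) {
  switch(object$method,
         SA = setNames(rep(1 / length(object$columns), length(object$columns)),
                       object$columns),
         LR = setNames(object$model[-1], object$columns),
         BR = setNames(object$model$w, object$columns),
         Lasso = {
           b <- as.matrix(coef(object$model, s = "lambda.min"))
           setNames(b[-1, 1], object$columns)
         },
         stop("coefficients are not defined for a ", object$method,
              " generalizer"))
}

# normalize the x argument of agestack()/predict: named list of matrices
as_view_list <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) x <- list(view = as.matrix(x))
  stopifnot(is.list(x), length(x) >= 1)
  if (is.null(names(x))) names(x) <- paste0("view", seq_along(x))
  lapply(x, function(v) check_view(v, require_nonneg = FALSE))
}

# ages for given sample ids: y may be named (required for partial overlap)
ages_for <- function(y, ids, n_total) {
  if (!is.null(names(y))) {
    if (!all(ids %in% names(y)))
      stop("age vector is missing entries for some view samples")
    return(unname(y[ids]))
  }
  y
}

#' Fit a stacked multi-view aging clock
#'
#' The fitting function of the package. Builds the two-stage stacking
#' ensemble: stage 1 fits a panel of heterogeneous base regressors under a
#' shared k-fold split and collects their out-of-fold age predictions;
#' stage 2 fits a generalizer (linear regression by default) on those OOF
#' columns. With two or more views, `strategy = "EM2"` (late fusion,
#' default) stacks each view independently and fuses the OOF columns at
#' the generalizer — views may cover different sample subsets, and only
#' the generalizer needs the overlap — while `strategy = "EM1"` (early
#' fusion) concatenates the view design matrices up front and stacks the
#' combined matrix.
#'
#' @param x design matrix (single view) or named list of per-view design
#'   matrices (typically CLR-transformed abundances, optionally with
#'   one-hot subregion columns appended via [assemble_design()]).
#' @param age numeric ages in years; either aligned with the rows of every
#'   view, or named by sample ID (required when views cover different
#'   samples).
#' @param base_learners character vector of registry names or list of
#'   specs; default `Lasso, EN, BR, SVM, RF, GBRT, XGB, XGBRF, LGB`.
#' @param generalizer stage-2 method, see [fit_generalizer()].
#' @param strategy `"EM2"` (late fusion) or `"EM1"` (early fusion);
#'   ignored for a single view.
#' @param k stage-1 folds (default 5).
#' @param seed integer seed.
#' @return an object of class `"agestack"`; see [predict.agestack()],
#'   [summary.agestack()], [coef.agestack()].
#' @examples
#' \donttest{
#' ch <- simulate_cohort(n_samples = 120, n_species = 30, n_pathways = 20,
#'                       signal_effect = 0.05, seed = 3)
#' sp <- clr_transform(multiplicative_replacement(ch$species_view))
#' fit <- agestack(sp, ch$metadata$age,
#'                 base_learners = c("Lasso", "RF", "LGB"))
#' print(fit)
#' head(predict(fit, sp))
#' }
#' @export
agestack <- function(x, age, base_learners = .stack_base_names,
                     generalizer = "LR", strategy = c("EM2", "EM1"),
                     k = 5, seed = 1L) {
  strategy <- match.arg(strategy)
  views <- as_view_list(x)
  if (is.character(base_learners))
    specs <- learner_registry(base_learners, seed = seed)
  else specs <- base_learners
  cl <- match.call()

  if (length(views) == 1L) strategy <- "single"
  if (strategy == "EM1") {
    common <- Reduce(intersect, lapply(views, rownames))
    if (length(common) == 0) stop("empty sample intersection across views")
    cat_mat <- do.call(cbind, lapply(views, function(v) v[common, , drop = FALSE]))
    views <- list(EM1 = cat_mat)
  }

  common <- Reduce(intersect, lapply(views, rownames))
  if (length(common) == 0)
    stop("empty sample intersection across views: the generalizer has nothing to train on")

  # stage 1 per view, on all samples the view has
  stage1 <- list()
  for (v in names(views)) {
    ids <- rownames(views[[v]])
    yv <- ages_for(age, ids)
    stage1[[v]] <- stage1_oof(specs, views[[v]], yv, X_test = NULL, k = k,
                              seed = child_seed(seed, match(v, names(views))))
  }

  # generalizer needs samples present in every view
  oof <- do.call(cbind, lapply(names(views), function(v) {
    m <- stage1[[v]]$oof_train[common, , drop = FALSE]
    colnames(m) <- paste(v, colnames(m), sep = ".")
    m
  }))
  y_common <- ages_for(age, common)
  gen <- fit_generalizer(oof, y_common, method = generalizer,
                         seed = child_seed(seed, 999L))

  obj <- structure(list(
    call = cl,
    strategy = strategy,
    k = k,
    seed = seed,
    base_learners = names(specs),
    views = lapply(names(views), function(v) list(
      name = v,
      feature_ids = colnames(views[[v]]),
      origin = attr(views[[v]], "origin") %||% rep("primary", ncol(views[[v]])),
      models = stage1[[v]]$models,
      specs = stage1[[v]]$specs,
      n_train = nrow(views[[v]]))),
    generalizer = gen,
    oof = oof,
    y = y_common,
    sample_ids = common
  ), class = "agestack")
  names(obj$views) <- names(views)
  obj$fitted <- predict(gen, oof)
  obj
}

# fold-mean base predictions for one view on new data
view_base_predictions <- function(view_fit, newX) {
  newX <- as.matrix(newX)
  if (!identical(colnames(newX), view_fit$feature_ids)) {
    if (!all(view_fit$feature_ids %in% colnames(newX)))
      stop(sprintf("view '%s': newdata lacks training features", view_fit$name))
    newX <- newX[, view_fit$feature_ids, drop = FALSE]
  }
  out <- matrix(0, nrow(newX), length(view_fit$models),
                dimnames = list(rownames(newX),
                                paste(view_fit$name, names(view_fit$models),
                                      sep = ".")))
  for (j in seq_along(view_fit$models)) {
    h <- make_learner(view_fit$specs[[j]])
    fold_models <- view_fit$models[[j]]
    for (m in fold_models)
      out[, j] <- out[, j] + h$predict(m, newX) / length(fold_models)
  }
  out
}

#' Predict ages from a fitted stacking ensemble
#'
#' Applies the frozen stage-1 fold models (fold-mean per base learner and
#' view) and the fitted generalizer. For a multi-view EM2 model, all
#' training views must be supplied; for EM1, supply the views and they are
#' concatenated as at training time.
#'
#' @param object an [agestack()] fit.
#' @param newdata matrix or named list of per-view matrices with the
#'   training feature columns.
#' @param ... unused.
#' @return numeric vector of predicted ages.
#' @export
predict.agestack <- function(object, newdata, ...) {
  views <- as_view_list(newdata)
  if (object$strategy == "EM1" && length(views) > 1) {
    common <- Reduce(intersect, lapply(views, rownames))
    views <- list(EM1 = do.call(cbind, lapply(views, function(v)
      v[common, , drop = FALSE])))
  }
  need <- names(object$views)
  if (length(views) == 1L && length(need) == 1L) {
    names(views) <- need
  } else if (!all(need %in% names(views))) {
    stop("newdata is missing view(s): ",
         paste(setdiff(need, names(views)), collapse = ", "))
  }
  common <- Reduce(intersect, lapply(views[need], rownames))
  if (length(common) == 0) stop("no samples shared across the supplied views")
  Z <- do.call(cbind, lapply(need, function(v)
    view_base_predictions(object$views[[v]], views[[v]][common, , drop = FALSE])))
  setNames(predict(object$generalizer, Z), common)
}

#' @export
print.agestack <- function(x, ...) {
  cat("Stacked aging clock (", x$strategy, ")\n", sep = "")
  cat(sprintf("  views: %s\n", paste(
    vapply(x$views, function(v) sprintf("%s [%d features, n=%d]",
                                        v$name, length(v$feature_ids), v$n_train),
           character(1)), collapse = "; ")))
  cat(sprintf("  base learners: %s\n", paste(x$base_learners, collapse = ", ")))
  cat(sprintf("  generalizer: %s; stage-1 folds: %d\n",
              x$generalizer$method, x$k))
  sc <- score_predictions(x$y, x$fitted)
  cat(sprintf("  OOF fit (n=%d): R2 = %.3f, MAE = %.2f years\n",
              length(x$y), sc[["r2"]], sc[["mae"]]))
  invisible(x)
}

#' @export
summary.agestack <- function(object, ...) {
  base_r2 <- apply(object$oof, 2, function(col)
    score_predictions(object$y, col)[["r2"]])
  sc <- score_predictions(object$y, object$fitted)
  out <- list(strategy = object$strategy,
              base_oof_r2 = sort(base_r2, decreasing = TRUE),
              ensemble_oof_r2 = sc[["r2"]],
              ensemble_oof_mae = sc[["mae"]],
              weights = tryCatch(coef(object$generalizer),
                                 error = function(e) NULL),
              n = length(object$y))
  class(out) <- "summary.agestack"
  out
}

#' @export
print.summary.agestack <- function(x, ...) {
  cat("Stacked aging clock — OOF diagnostics (n=", x$n, ")\n", sep = "")
  cat(sprintf("  ensemble: R2 = %.3f, MAE = %.2f years\n",
              x$ensemble_oof_r2, x$ensemble_oof_mae))
  cat("  base-learner OOF R2:\n")
  for (nm in names(x$base_oof_r2))
    cat(sprintf("    %-14s %6.3f\n", nm, x$base_oof_r2[nm]))
  if (!is.null(x$weights)) {
    cat("  generalizer weights:\n")
    for (nm in names(x$weights))
      cat(sprintf("    %-14s %8.4f\n", nm, x$weights[nm]))
  }
  invisible(x)
}

#' @export
coef.agestack <- function(object, ...) coef(object$generalizer)

#' @export
fitted.agestack <- function(object, ...) setNames(object$fitted, object$sample_ids)

#' @export
residuals.agestack <- function(object, ...)
  setNames(object$y - object$fitted, object$sample_ids)

#' Plot observed versus stacked out-of-fold predicted age
#'
#' @param x an [agestack()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.agestack <- function(x, ...) {
  graphics::plot(x$y, x$fitted, xlab = "chronological age (years)",
                 ylab = "predicted age (years)",
                 main = "Stacked aging clock (OOF)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
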