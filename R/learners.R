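# Closed registry of heterogeneous base regressors. Each entry builds a
# handle with fit(X, y) -> model and predict(model, X) -> numeric; handles
# are deterministic given the spec seed.

.learner_names <- c("LR", "Lasso", "EN", "BR", "SVM", "LSVM", "DT", "RF",
                    "GBRT", "XGB", "XGBRF", "LGB")

#' Specify a base regressor
#'
#' @param name one of `"LR"` (ordinary least squares), `"Lasso"`, `"EN"`
#'   (elastic net, alpha = 0.5), `"BR"` (Bayesian ridge via evidence
#'   maximization), `"SVM"` (RBF-kernel epsilon-SVR), `"LSVM"`
#'   (linear-kernel SVR), `"DT"` (unpruned CART regression tree), `"RF"` (random
#'   forest, 100 trees), `"GBRT"` (depth-wise gradient boosted trees,
#'   depth 3, learning rate 0.1, 100 rounds), `"XGB"` (gradient boosting,
#'   depth 6, learning rate 0.3, 100 rounds), `"XGBRF"` (random-forest-mode
#'   boosting: one round of 100 subsampled parallel trees), `"LGB"`
#'   (leaf-wise histogram gradient boosting, 31 leaves, learning rate 0.1,
#'   100 rounds).
#' @param params named list of overrides merged over the registry defaults.
#' @param seed integer seed used by stochastic learners.
#' @return an object of class `"learner_spec"`.
#' @export
learner_spec <- function(name, params = list(), seed = 1L) {
  if (!name %in% .learner_names)
    stop(sprintf("unknown learner '%s'; registry: %s", name,
                 paste(.learner_names, collapse = ", ")))
  structure(list(name = name, params = params, seed = as.integer(seed)),
            class = "learner_spec")
}

#' The default base-learner registry
#'
#' @param names which learners to include (default: all twelve).
#' @param seed seed shared by the specs.
#' @return named list of [learner_spec()] objects.
#' @export
learner_registry <- function(names = .learner_names, seed = 1L) {
  setNames(lapply(names, learner_spec, seed = seed), names)
}

#' Wrap user fit/predict functions as a learner handle
#'
#' Mainly for toy learners in tests and for extending the stacking stage
#' with a custom regressor.
#'
#' @param name label for reports.
#' @param fit function `(X, y) -> model`.
#' @param predict function `(model, X) -> numeric`.
#' @return a learner handle usable wherever a [learner_spec()] is accepted.
#' @export
custom_learner <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "learner_handle")
}

# --- internal fitting backends -------------------------------------------

fit_ols <- function(X, y) {
  f <- lm.fit(cbind(`(Intercept)` = 1, X), y)
  b <- f$coefficients
  b[is.na(b)] <- 0
  b
}
predict_ols <- function(b, X) drop(cbind(1, X) %*% b)

fit_glmnet <- function(X, y, alpha, seed) {
  n <- nrow(X)
  foldid <- fold_assignment(n, min(5L, n), child_seed(seed, 17L))
  glmnet::cv.glmnet(X, y, alpha = alpha, nfolds = min(5L, n),
                    foldid = foldid, standardize = TRUE)
}

# Bayesian ridge regression by evidence (type-II ML) maximization:
# w ~ N(0, 1/lambda I), noise precision alpha, both updated by the MacKay
# fixed-point equations on the SVD of the centered design.
fit_bayes_ridge <- function(X, y, max_iter = 100, tol = 1e-4) {
  xc <- colMeans(X); yc <- mean(y)
  Xc <- sweep(X, 2, xc); yy <- y - yc
  sv <- svd(Xc)
  e <- sv$d^2
  Uty <- crossprod(sv$u, yy)
  n <- nrow(X)
  alpha <- 1 / max(var(yy), 1e-9); lambda <- 1
  for (i in seq_len(max_iter)) {
    coef_d <- sv$d * drop(Uty) / (e + lambda / alpha)
    w <- sv$v %*% coef_d
    rss <- sum((yy - Xc %*% w)^2)
    gamma <- sum(alpha * e / (lambda + alpha * e))
    lambda_new <- (gamma + 1e-8) / (sum(w^2) + 1e-8)
    alpha_new <- (n - gamma + 1e-8) / (rss + 1e-8)
    if (abs(log(lambda_new / lambda)) < tol && abs(log(alpha_new / alpha)) < tol) {
      lambda <- lambda_new; alpha <- alpha_new; break
    }
    lambda <- lambda_new; alpha <- alpha_new
  }
  coef_d <- sv$d * drop(Uty) / (e + lambda / alpha)
  w <- drop(sv$v %*% coef_d)
  list(w = w, intercept = yc - sum(xc * w), alpha = alpha, lambda = lambda)
}
predict_bayes_ridge <- function(m, X) drop(X %*% m$w) + m$intercept

# data frame with syntactic, position-stable column names for the
# formula/data-frame backends (rpart, ranger)
df_norm <- function(X) {
  df <- as.data.frame(X)
  colnames(df) <- paste0("V", seq_len(ncol(df)))
  df
}

# epsilon-SVR with the usual variable scaling (predictors and response),
# done outside e1071 so constant columns never trip its scaler
fit_svm <- function(X, y, kernel) {
  ctr <- colMeans(X); scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  yc <- mean(y); ys <- sd(y); if (ys == 0) ys <- 1
  m <- e1071::svm(x = Xs, y = (y - yc) / ys, kernel = kernel, scale = FALSE)
  list(model = m, center = ctr, scale = scl, y_center = yc, y_scale = ys)
}
predict_svm <- function(m, X) {
  Xs <- scale(X, center = m$center, scale = m$scale)
  unname(predict(m$model, Xs)) * m$y_scale + m$y_center
}

fit_xgb <- function(X, y, params, nrounds, seed) {
  d <- xgboost::xgb.DMatrix(X, label = y)
  params <- modifyList(list(objective = "reg:squarederror", nthread = 1,
                            seed = seed), params)
  xgboost::xgb.train(params = params, data = d, nrounds = nrounds, verbose = 0)
}
predict_xgb <- function(m, X) predict(m, xgboost::xgb.DMatrix(X))

#' Instantiate a learner handle from a spec
#'
#' Resolves a [learner_spec()] against the registry, returning an opaque
#' handle with `fit(X, y)` and `predict(model, X)` functions. All handles
#' accept a plain numeric design matrix; scaling, where a backend needs it,
#' happens inside the handle.
#'
#' @param spec a [learner_spec()] (or an existing [custom_learner()]
#'   handle, returned unchanged).
#' @return a `"learner_handle"`.
#' @export
make_learner <- function(spec) {
  if (inherits(spec, "learner_handle")) return(spec)
  if (is.character(spec)) spec <- learner_spec(spec)
  stopifnot(inherits(spec, "learner_spec"))
  name <- spec$name; p <- spec$params; seed <- spec$seed
  h <- switch(
    name,
    LR = list(fit = fit_ols, predict = predict_ols),
    Lasso = list(fit = function(X, y) fit_glmnet(X, y, alpha = p$alpha %||% 1, seed),
                 predict = function(m, X) drop(predict(m, X, s = "lambda.min"))),
    EN = list(fit = function(X, y) fit_glmnet(X, y, alpha = p$alpha %||% 0.5, seed),
              predict = function(m, X) drop(predict(m, X, s = "lambda.min"))),
    BR = list(fit = function(X, y) fit_bayes_ridge(X, y),
              predict = predict_bayes_ridge),
    SVM = list(fit = function(X, y) fit_svm(X, y, kernel = "radial"),
               predict = predict_svm),
    LSVM = list(fit = function(X, y) fit_svm(X, y, kernel = "linear"),
                predict = predict_svm),
    DT = list(fit = function(X, y) {
                df <- df_norm(X); df$.y <- y
                # unpruned CART (grown to purity), the conventional default
                # for a lone regression tree in this model family
                rpart::rpart(.y ~ ., data = df, method = "anova",
                             control = rpart::rpart.control(
                               cp = p$cp %||% 0, minsplit = p$minsplit %||% 2,
                               minbucket = p$minbucket %||% 1,
                               maxdepth = 30, xval = 0))
              },
              predict = function(m, X) unname(predict(m, df_norm(X)))),
    RF = list(fit = function(X, y)
                ranger::ranger(x = df_norm(X), y = y,
                               num.trees = p$num.trees %||% 100,
                               seed = seed, num.threads = 1),
              predict = function(m, X)
                predict(m, df_norm(X), num.threads = 1)$predictions),
    GBRT = list(fit = function(X, y)
                  fit_xgb(X, y, modifyList(list(max_depth = 3, eta = 0.1,
                                                tree_method = "hist"), p),
                          nrounds = p$nrounds %||% 100, seed = seed),
                predict = predict_xgb),
    XGB = list(fit = function(X, y)
                 fit_xgb(X, y, modifyList(list(max_depth = 6, eta = 0.3,
                                               tree_method = "hist"), p),
                         nrounds = p$nrounds %||% 100, seed = seed),
               predict = predict_xgb),
    XGBRF = list(fit = function(X, y)
                   fit_xgb(X, y, modifyList(list(max_depth = 6, eta = 1,
                                                 subsample = 0.8,
                                                 colsample_bynode = 0.8,
                                                 num_parallel_tree = p$num_parallel_tree %||% 100,
                                                 tree_method = "hist"), p),
                           nrounds = 1, seed = seed),
                 predict = predict_xgb),
    LGB = list(fit = function(X, y)
                 fit_xgb(X, y, modifyList(list(grow_policy = "lossguide",
                                               max_leaves = 31, max_depth = 0,
                                               eta = 0.1, tree_method = "hist"),
                                          p),
                         nrounds = p$nrounds %||% 100, seed = seed),
               predict = predict_xgb)
  )
  structure(list(name = name, spec = spec, fit = h$fit, predict = h$predict),
            class = "learner_handle")
}
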