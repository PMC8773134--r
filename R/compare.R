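#' Outer cross-validated comparison of stacking variants
#'
#' Wraps the entire stacking procedure in an outer repeated-CV scheme (the
#' stage-1 k-fold lives inside each outer training set, so no information
#' leaks from an outer test fold into any fitted component) and evaluates,
#' on identical outer splits:
#'
#' * every requested generalizer on each single-view ensemble,
#' * the EM2 (late-fusion) multi-view ensemble,
#' * optionally the EM1 (early-fusion) ensemble,
#' * optionally each base learner fitted directly per view.
#'
#' Stage-1 OOF matrices are computed once per outer split and shared by
#' all generalizers and fusion strategies, so every comparison is paired.
#'
#' @param views named list of per-view design matrices over a common
#'   sample set (identical row order).
#' @param y ages, aligned with the rows.
#' @param scheme outer [cv_scheme()].
#' @param base_learners registry names for the stage-1 panel.
#' @param generalizers character vector of stage-2 methods to compare.
#' @param strategies subset of `c("EM2", "EM1")`; multi-view variants are
#'   skipped when only one view is given.
#' @param include_base also score each base learner alone per view.
#' @param k stage-1 folds.
#' @return list with `r2` and `mae`: splits x variant matrices. Variant
#'   labels are `"<view>|<generalizer>"`, `"EM2|<generalizer>"`,
#'   `"EM1|<generalizer>"`, `"<view>|base:<learner>"`.
#' @export
compare_stacking <- function(views, y, scheme = cv_scheme(),
                             base_learners = .stack_base_names,
                             generalizers = "LR",
                             strategies = "EM2",
                             include_base = FALSE, k = 5) {
  views <- as_view_list(views)
  n <- length(y)
  stopifnot(all(vapply(views, nrow, integer(1)) == n))
  specs <- learner_registry(base_learners, seed = scheme$seed)
  splits <- cv_splits(scheme, n)
  multi <- length(views) > 1

  res_r2 <- list(); res_mae <- list()
  for (r in seq_along(splits)) {
    folds <- splits[[r]]
    for (f in seq_len(scheme$n_folds)) {
      tr <- folds != f
      split_seed <- child_seed(scheme$seed, r, f)
      ytr <- y[tr]; yte <- y[!tr]
      s1 <- lapply(names(views), function(v)
        stage1_oof(specs, views[[v]][tr, , drop = FALSE], ytr,
                   X_test = views[[v]][!tr, , drop = FALSE], k = k,
                   seed = child_seed(split_seed, match(v, names(views)))))
      names(s1) <- names(views)

      row_r2 <- c(); row_mae <- c()
      add <- function(label, yhat) {
        sc <- score_predictions(yte, yhat)
        row_r2[[label]] <<- sc[["r2"]]; row_mae[[label]] <<- sc[["mae"]]
      }
      for (g in generalizers) {
        for (v in names(views)) {
          gen <- suppressWarnings(
            fit_generalizer(s1[[v]]$oof_train, ytr, g, seed = split_seed))
          add(paste0(v, "|", g), predict(gen, s1[[v]]$oof_test))
        }
        if (multi && "EM2" %in% strategies) {
          otr <- do.call(cbind, lapply(names(views), function(v) {
            m <- s1[[v]]$oof_train; colnames(m) <- paste(v, colnames(m), sep = "."); m
          }))
          ote <- do.call(cbind, lapply(names(views), function(v) {
            m <- s1[[v]]$oof_test; colnames(m) <- paste(v, colnames(m), sep = "."); m
          }))
          gen <- suppressWarnings(fit_generalizer(otr, ytr, g, seed = split_seed))
          add(paste0("EM2|", g), predict(gen, ote))
        }
      }
      if (multi && "EM1" %in% strategies) {
        Xcat_tr <- do.call(cbind, lapply(views, function(v) v[tr, , drop = FALSE]))
        Xcat_te <- do.call(cbind, lapply(views, function(v) v[!tr, , drop = FALSE]))
        s1cat <- stage1_oof(specs, Xcat_tr, ytr, X_test = Xcat_te, k = k,
                            seed = child_seed(split_seed, 77L))
        for (g in generalizers) {
          gen <- suppressWarnings(
            fit_generalizer(s1cat$oof_train, ytr, g, seed = split_seed))
          add(paste0("EM1|", g), predict(gen, s1cat$oof_test))
        }
      }
      if (include_base) {
        for (v in names(views)) for (nm in names(specs)) {
          h <- make_learner(specs[[nm]])
          m <- h$fit(views[[v]][tr, , drop = FALSE], ytr)
          add(paste0(v, "|base:", nm),
              h$predict(m, views[[v]][!tr, , drop = FALSE]))
        }
      }
      res_r2[[length(res_r2) + 1L]] <- unlist(row_r2)
      res_mae[[length(res_mae) + 1L]] <- unlist(row_mae)
    }
  }
  list(r2 = do.call(rbind, res_r2), mae = do.call(rbind, res_mae),
       scheme = scheme)
}
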