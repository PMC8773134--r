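test_that("OOF entries come from models that never saw the sample", {
  # fold-mean toy learner: the OOF prediction for sample i must equal the
  # mean of y over the folds excluding i's fold — recomputed by hand
  set.seed(2)
  n <- 10
  X <- matrix(rnorm(n * 3), n, dimnames = list(paste0("s", 1:n), NULL))
  y <- c(21, 35, 44, 52, 60, 68, 73, 80, 85, 90)
  s1 <- stage1_oof(list(fm = mean_learner()), X, y, X_test = X[1:2, ],
                   k = 5, seed = 7)
  folds <- s1$folds
  for (i in seq_len(n)) {
    oracle <- mean(y[folds != folds[i]])
    expect_equal(unname(s1$oof_train[i, "fm"]), oracle)
  }
  # predicted test set = mean over the k fold models
  test_oracle <- mean(vapply(1:5, function(f) mean(y[folds != f]), numeric(1)))
  expect_equal(unname(s1$oof_test[, "fm"]), rep(test_oracle, 2))

  # structural no-leakage audit: perturbing y_i never changes row i's OOF
  y2 <- y; y2[4] <- 1000
  s2 <- stage1_oof(list(fm = mean_learner()), X, y2, k = 5, seed = 7)
  expect_equal(s2$oof_train[4, "fm"], s1$oof_train[4, "fm"])
  expect_false(isTRUE(all.equal(s2$oof_train[-4, "fm"], s1$oof_train[-4, "fm"])))
})

test_that("generalizers combine OOF columns as specified", {
  # SA is the arithmetic mean
  oof <- cbind(a = c(30, 50), b = c(50, 70))
  sa <- fit_generalizer(oof, c(40, 60), "SA")
  expect_equal(unname(predict(sa, oof)), c(40, 60))
  expect_equal(unname(coef(sa)), c(0.5, 0.5))

  # an OOF column equal to y admits an exact linear solution
  set.seed(5)
  oof2 <- cbind(exact = runif(40, 20, 80), noise = rnorm(40))
  y <- oof2[, "exact"]
  lr <- fit_generalizer(oof2, y, "LR")
  expect_equal(score_predictions(y, predict(lr, oof2))[["r2"]], 1,
               tolerance = 1e-10)

  expect_warning(fit_generalizer(oof2, y, "DT"), "overfitting")
})

test_that("the fitted clock predicts deterministically and via composition", {
  ch <- tiny_cohort(n = 80, seed = 91)
  X <- clr_of(ch$species_view)
  y <- setNames(ch$metadata$age, ch$metadata$sample_id)
  fit <- agestack(X, y, base_learners = c("Lasso", "BR"), seed = 11)
  p1 <- predict(fit, X)
  p2 <- predict(fit, X)
  expect_identical(p1, p2)

  # composition contract: prediction = generalizer applied to the
  # fold-mean base-learner outputs
  Z <- agestack:::view_base_predictions(fit$views[[1]], X)
  expect_equal(unname(p1), unname(predict(fit$generalizer, Z)))

  # standard S3 surface
  expect_equal(length(fitted(fit)), 80)
  expect_equal(unname(fitted(fit) + residuals(fit)), unname(y))
  expect_named(coef(fit))
  expect_output(print(fit), "Stacked aging clock")
  expect_output(print(summary(fit)), "base-learner OOF R2")
})

test_that("EM2 handles partial view overlap; EM1 requires the intersection", {
  ch <- tiny_cohort(n = 100, seed = 101)
  sp <- clr_of(ch$species_view)
  pw <- clr_of(ch$pathway_view)[1:80, ]  # view B present for 80% of samples
  y <- setNames(ch$metadata$age, ch$metadata$sample_id)

  fit <- agestack(list(species = sp, pathway = pw), y,
                  base_learners = c("Lasso", "RF"), strategy = "EM2", seed = 3)
  # stage-1 for the partial view used all 80 of its samples
  expect_equal(fit$views$pathway$n_train, 80)
  expect_equal(fit$views$species$n_train, 100)
  # generalizer fitted on the 80-sample intersection
  expect_equal(length(fit$y), 80)
  p <- predict(fit, list(species = sp, pathway = pw))
  expect_length(p, 80)

  em1 <- agestack(list(species = sp, pathway = pw), y,
                  base_learners = c("Lasso", "RF"), strategy = "EM1", seed = 3)
  expect_equal(em1$views[[1]]$n_train, 80)
  expect_equal(length(em1$views$EM1$feature_ids), ncol(sp) + ncol(pw))

  # missing view at prediction time is an error for a two-view model
  expect_error(predict(fit, list(species = sp)), "missing view")

  # disjoint sample sets cannot be stacked
  pw_disjoint <- pw
  rownames(pw_disjoint) <- paste0("zz", seq_len(nrow(pw)))
  expect_error(agestack(list(species = sp, pathway = pw_disjoint),
                        c(y, setNames(rep(50, 80), rownames(pw_disjoint))),
                        base_learners = c("Lasso", "RF")),
               "intersection")
})

test_that("duplicated views add nothing over a single view", {
  ch <- tiny_cohort(n = 150, seed = 111)
  X <- clr_of(ch$species_view)
  y <- ch$metadata$age
  sch <- cv_scheme(2, 5, seed = 13)
  cmp <- compare_stacking(list(a = X, b = X), y, scheme = sch,
                          base_learners = c("Lasso", "RF"),
                          generalizers = "LR", strategies = "EM2")
  one <- cmp$r2[, "a|LR"]
  two <- cmp$r2[, "EM2|LR"]
  # equivalence in magnitude: a copied view carries no extra information,
  # so fusing it moves mean R2 by at most numerical-regularization jitter
  expect_lt(abs(paired_cv_test(two, one)$mean_difference), 0.02)
})
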