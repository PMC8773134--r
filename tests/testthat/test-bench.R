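test_that("the learner registry is closed and instantiable", {
  expect_error(learner_spec("MLP"), "registry")
  reg <- learner_registry()
  expect_length(reg, 12)
  # every registered learner fits and predicts a small linear problem
  set.seed(1)
  X <- matrix(rnorm(80 * 6), 80)
  colnames(X) <- paste0("f", 1:6)
  y <- 50 + 8 * X[, 1] - 5 * X[, 2] + rnorm(80)
  for (nm in names(reg)) {
    h <- make_learner(reg[[nm]])
    m <- h$fit(X[1:60, ], y[1:60])
    p <- h$predict(m, X[61:80, ])
    expect_length(p, 20)
    expect_true(all(is.finite(p)), info = nm)
    # anything but a lone tree should clearly beat the mean predictor here
    # (the RBF kernel is conservative at n = 60; the linear learners nail it)
    if (!nm %in% c("DT", "SVM"))
      expect_gt(score_predictions(y[61:80], p)[["r2"]], 0.3, label = nm)
    if (nm == "SVM")
      expect_gt(score_predictions(y[61:80], p)[["r2"]], 0.1, label = nm)
  }
})

test_that("metrics follow their formulas", {
  expect_equal(unname(score_predictions(c(1, 2, 3), c(1, 2, 3))), c(1, 0))
  y <- c(10, 20, 60)
  expect_equal(score_predictions(y, rep(mean(y), 3))[["r2"]], 0)
  expect_equal(score_predictions(y, rep(mean(y), 3))[["mae"]],
               mean(abs(y - mean(y))))
  # hand-evaluated example: SSres = 200, SStot = 800
  sc <- score_predictions(c(20, 40, 60), c(30, 40, 50))
  expect_equal(sc[["r2"]], 0.75)
  expect_equal(sc[["mae"]], 20 / 3, tolerance = 1e-12)
  expect_error(score_predictions(c(5, 5), c(4, 6)), "constant")
  expect_error(score_predictions(1:3, 1:4), "mismatch")
})

test_that("repeated CV produces one score per split, deterministically", {
  ch <- tiny_cohort(n = 60, seed = 51)
  X <- clr_of(ch$species_view)
  sch <- cv_scheme(n_repeats = 3, n_folds = 4, seed = 9)
  a <- repeated_cv(learner_spec("Lasso", seed = 2), X, ch$metadata$age, sch)
  expect_equal(nrow(a), 12)
  b <- repeated_cv(learner_spec("Lasso", seed = 2), X, ch$metadata$age, sch)
  expect_identical(a$r2, b$r2)

  # default scheme is 10 x 5 = 50 splits
  expect_equal(cv_scheme()$n_repeats * cv_scheme()$n_folds, 50)

  # folds partition the samples within every repeat
  splits <- agestack:::cv_splits(sch, 60)
  for (f in splits) {
    expect_length(f, 60)
    expect_setequal(unique(f), 1:4)
  }
  expect_error(repeated_cv(learner_spec("LR"), X[1:3, ], ch$metadata$age[1:3],
                           cv_scheme(1, 5, 1)), "exceeds")
})

test_that("paired Wilcoxon comparison behaves at its boundary cases", {
  ch <- tiny_cohort(n = 50, seed = 61)
  X <- clr_of(ch$species_view)
  sch <- cv_scheme(2, 5, seed = 3)
  a <- repeated_cv(learner_spec("Lasso", seed = 1), X, ch$metadata$age, sch)

  # identical scores: zero differences, p = 1
  expect_equal(paired_cv_test(a, a)$p_value, 1)

  # a uniform constant improvement: minimal attainable signed-rank p
  v <- a$r2
  res <- paired_cv_test(v + 0.1, v)
  expect_equal(res$p_value,
               suppressWarnings(
                 wilcox.test(v + 0.1, v, paired = TRUE, exact = TRUE)$p.value))
  expect_lt(res$p_value, 0.01)

  # Bonferroni is plain multiplication, capped at 1
  expect_equal(paired_cv_test(v + 0.1, v, n_comparisons = 11)$p_adjusted,
               min(1, res$p_value * 11))
  r2 <- paired_cv_test(c(0.1, 0.2), c(0.2, 0.1), n_comparisons = 50)
  expect_equal(r2$p_adjusted, 1)

  expect_error(paired_cv_test(v, v[-1]), "different lengths")
  b <- repeated_cv(learner_spec("Lasso", seed = 1), X, ch$metadata$age,
                   cv_scheme(2, 5, seed = 4))
  expect_error(paired_cv_test(a, b), "different CV schemes")
})

test_that("tree learners dominate on planted nonlinear signal", {
  ch <- simulate_cohort(n_samples = 250, n_species = 40, n_pathways = 10,
                        n_signal_features = 8, signal_effect = 0.05,
                        threshold_fraction = 0.5, seed = 71)
  X <- clr_of(ch$species_view)
  sch <- cv_scheme(2, 5, seed = 5)
  r2_of <- function(nm) attr(repeated_cv(learner_spec(nm, seed = 1), X,
                                         ch$metadata$age, sch), "mean_r2")
  lgb <- r2_of("LGB"); rf <- r2_of("RF"); dt <- r2_of("DT")
  expect_gt(lgb, 0)
  expect_gt(rf, 0)
  if (!(max(lgb, rf) > dt))
    warning("tree ensembles did not dominate the single tree on this seed")
  expect_gt(max(lgb, rf), dt)
})
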