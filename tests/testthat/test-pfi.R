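test_that("shuffling a constant feature changes nothing, exactly", {
  set.seed(7)
  n <- 60
  X <- cbind(sig = runif(n, 20, 80), const = rep(2, n), noise = rnorm(n))
  rownames(X) <- paste0("s", 1:n)
  y <- X[, "sig"] + rnorm(n, sd = 2)
  fit <- agestack(X[1:40, ], y[1:40], base_learners = c("Lasso", "BR"), seed = 1)
  pfi <- permutation_importance(fit, X[41:60, ], y[41:60],
                                n_shuffles = 10, seed = 2)
  expect_true(all(pfi$deltas["const", ] == 0))

  tb <- test_biomarkers(pfi)
  expect_equal(tb$p_value[tb$feature_id == "const"], 1)
  expect_false(tb$significant[tb$feature_id == "const"])

  # destroying the only real signal collapses the model: mean delta close
  # to the full baseline R2
  expect_gt(tb$mean_delta_r2[tb$feature_id == "sig"], 0.8 * pfi$baseline_r2)
  expect_equal(tb$rank[tb$feature_id == "sig"], 1L)

  expect_error(permutation_importance(fit, X[41:60, ], y[41:60], n_shuffles = 1),
               "n_shuffles")
})

test_that("Bonferroni spans all tested features of all views jointly", {
  ch <- tiny_cohort(n = 90, seed = 121)
  sp <- clr_of(ch$species_view)   # 25 features
  pw <- clr_of(ch$pathway_view)   # 15 features
  y <- setNames(ch$metadata$age, ch$metadata$sample_id)
  fit <- agestack(list(species = sp[1:60, ], pathway = pw[1:60, ]), y,
                  base_learners = c("Lasso", "RF"), seed = 5)
  pfi <- permutation_importance(fit, list(species = sp[61:90, ], pathway = pw[61:90, ]),
                                ch$metadata$age[61:90], n_shuffles = 5, seed = 6)
  expect_equal(nrow(pfi$features), 40)
  tb <- test_biomarkers(pfi)
  expect_equal(tb$p_adjusted, pmin(1, tb$p_value * 40))
  expect_setequal(unique(tb$view), c("species", "pathway"))
})

test_that("one-hot covariate columns are excluded from biomarker PFI", {
  ch <- tiny_cohort(n = 80, seed = 131)
  sp <- clr_of(ch$species_view)
  oh <- encode_subregion(ch$metadata$subregion)
  rownames(oh) <- ch$metadata$sample_id
  d <- assemble_design(sp, list(subregion = oh))
  y <- setNames(ch$metadata$age, ch$metadata$sample_id)
  fit <- agestack(d, y, base_learners = c("Lasso", "BR"), seed = 7)
  # keep the origin tags on the row subset used for evaluation
  d_eval <- d[1:30, , drop = FALSE]
  pfi <- permutation_importance(fit, d_eval, y[1:30], n_shuffles = 5, seed = 8)
  expect_false(any(grepl("^subregion\\.", pfi$features$feature_id)))
  pfi2 <- permutation_importance(fit, d_eval, y[1:30], n_shuffles = 5, seed = 8,
                                 include_covariates = TRUE)
  expect_equal(nrow(pfi2$features), nrow(pfi$features) + ncol(oh))
})

test_that("PFI reruns are identical and invariant to feature order", {
  set.seed(9)
  n <- 50
  X <- matrix(rnorm(n * 4), n, dimnames = list(paste0("s", 1:n),
                                               c("a", "b", "c", "d")))
  y <- 50 + 10 * X[, "b"] + rnorm(n)
  fit <- agestack(X[1:35, ], y[1:35], base_learners = c("Lasso", "BR"), seed = 3)
  p1 <- permutation_importance(fit, X[36:50, ], y[36:50], n_shuffles = 8, seed = 4)
  p2 <- permutation_importance(fit, X[36:50, ], y[36:50], n_shuffles = 8, seed = 4)
  expect_identical(p1$deltas, p2$deltas)
  # reordering newdata columns does not change the result (columns are
  # realigned to the training order)
  p3 <- permutation_importance(fit, X[36:50, c(3, 1, 4, 2)], y[36:50],
                               n_shuffles = 8, seed = 4)
  expect_equal(p1$deltas, p3$deltas)
})

test_that("null features never out-rank planted ones and their deltas are marginal", {
  # permutation importance on correlated (compositional) inputs can assign
  # small but consistent deltas to unplanted features the ensemble uses as
  # proxies; the separation in effect size from real biomarkers stays large
  for (s in 1:3) {
    ch <- simulate_cohort(n_samples = 180, n_species = 24, n_pathways = 5,
                          n_signal_features = 4, signal_effect = 0.06,
                          seed = 300 + s)
    sp <- clr_of(ch$species_view)
    y <- ch$metadata$age
    fit <- agestack(sp[1:130, ], y[1:130], base_learners = c("Lasso", "RF"),
                    seed = 400 + s)
    pfi <- permutation_importance(fit, sp[131:180, ], y[131:180],
                                  n_shuffles = 25, seed = 500 + s)
    tb <- test_biomarkers(pfi)
    truth <- ch$truth$species$feature_id
    planted <- tb[tb$feature_id %in% truth, ]
    nulls <- tb[!tb$feature_id %in% truth, ]
    expect_lte(max(planted$rank), nrow(planted))
    expect_lt(max(nulls$mean_delta_r2), 0.1 * max(planted$mean_delta_r2))
  }
})

test_that("Spearman association recovers trend signs and handles nulls", {
  # strictly increasing feature: rho = 1
  age <- seq(20, 80, length.out = 30)
  sp <- spearman_age_association(2 * age + 5, age)
  expect_equal(sp$rho, 1)

  # constant feature: rho undefined, recorded as missing
  expect_true(is.na(spearman_age_association(rep(1, 30), age)$rho))

  # independent feature at n = 1000: small rho, non-significant
  set.seed(11)
  x <- rnorm(1000); a <- runif(1000, 18, 90)
  sp2 <- spearman_age_association(x, a, n_comparisons = 10)
  expect_lt(abs(sp2$rho), 0.1)
  expect_gt(sp2$p_adjusted, 0.05)

  expect_error(spearman_age_association(1:5, 1:5), "at least 10")
})
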