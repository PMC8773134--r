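test_that("cohorts are deterministic in the seed and respect closure", {
  a <- tiny_cohort(n = 50, seed = 5)
  b <- tiny_cohort(n = 50, seed = 5)
  c <- tiny_cohort(n = 50, seed = 6)
  expect_identical(a$species_view, b$species_view)
  expect_identical(a$metadata, b$metadata)
  expect_false(identical(a$species_view, c$species_view))

  for (v in list(a$species_view, a$pathway_view)) {
    expect_true(all(v >= 0))
    expect_lt(max(abs(rowSums(v) - 1)), 1e-9)
  }
  expect_identical(rownames(a$species_view), rownames(a$pathway_view))
  expect_identical(rownames(a$species_view), a$metadata$sample_id)
})

test_that("age marginal respects range and median target", {
  ch <- simulate_cohort(n_samples = 2000, n_species = 5, n_pathways = 5,
                        n_signal_features = 2,
                        age_range = c(18, 107), age_median = 52, seed = 9)
  expect_gte(min(ch$metadata$age), 18)
  expect_lte(max(ch$metadata$age), 107)
  expect_lt(abs(median(ch$metadata$age) - 52), 3)
})

test_that("planted increasing features correlate positively with age", {
  ch <- simulate_cohort(n_samples = 500, n_species = 30, n_pathways = 10,
                        n_signal_features = 5, signal_effect = 0.05, seed = 13)
  tr <- ch$truth$species
  for (i in seq_len(nrow(tr))) {
    rho <- cor(ch$species_view[, tr$feature_id[i]], ch$metadata$age,
               method = "spearman")
    expect_gt(rho * tr$sign[i], 0)
  }
})

test_that("subregion-age confounding is calibrated and feasible bounds enforced", {
  ch <- simulate_cohort(n_samples = 1000, n_species = 5, n_pathways = 5,
                        n_signal_features = 2,
                        subregions = c(EA = .3, "NA" = .25, NE = .25, SE = .2),
                        confound_strength = 0.3, seed = 17)
  # calibration on the realized sample is essentially exact
  r2b <- 1 - sum((ch$metadata$age -
                    ave(ch$metadata$age, ch$metadata$subregion))^2) /
    sum((ch$metadata$age - mean(ch$metadata$age))^2)
  expect_lt(abs(r2b - 0.3), 0.01)

  # a cross-validated RF association recovers the target within 0.05
  oh <- encode_subregion(ch$metadata$subregion)
  r2cv <- assoc_region_age(oh, ch$metadata$age, "RF",
                           cv_scheme(10, 5, seed = 3), seed = 4)
  expect_lt(abs(r2cv - 0.3), 0.05)

  # unconfounded cohorts show no association
  ch0 <- simulate_cohort(n_samples = 1000, n_species = 5, n_pathways = 5,
                         n_signal_features = 2, confound_strength = 0, seed = 19)
  oh0 <- encode_subregion(ch0$metadata$subregion)
  expect_lt(abs(assoc_region_age(oh0, ch0$metadata$age, "RF",
                                 cv_scheme(10, 5, seed = 3), seed = 4)), 0.05)

  # unattainable targets error out
  expect_error(simulate_cohort(n_samples = 200, n_species = 5, n_pathways = 5,
                               subregions = c(A = .5, B = .5),
                               n_signal_features = 2,
                               confound_strength = 0.95, seed = 1),
               "infeasible")
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(age_range = c(10, 80)), "age_range")
  expect_error(cohort_config(confound_strength = 1), "confound_strength")
  expect_error(cohort_config(n_signal_features = 50, n_species = 20,
                             n_pathways = 10), "exceeds")
  expect_error(cohort_config(noise_dispersion = 0), "noise_dispersion")
})

test_that("a signal-free cohort is unpredictable by any learner", {
  ch <- simulate_cohort(n_samples = 500, n_species = 20, n_pathways = 10,
                        signal_effect = 0, confound_strength = 0, seed = 23)
  X <- clr_of(ch$species_view)
  # a shrinkage learner sits at R2 ~ 0; a forest adds prediction variance,
  # so its held-out R2 is biased slightly negative but never positive
  sc <- repeated_cv(learner_spec("Lasso", seed = 1), X, ch$metadata$age,
                    cv_scheme(2, 5, seed = 7))
  expect_lt(abs(attr(sc, "mean_r2")), 0.05)
  sc_rf <- repeated_cv(learner_spec("RF", seed = 1), X, ch$metadata$age,
                       cv_scheme(2, 5, seed = 7))
  expect_lt(attr(sc_rf, "mean_r2"), 0.05)
})
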