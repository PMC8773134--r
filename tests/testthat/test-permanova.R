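test_that("Bray-Curtis follows the definition", {
  x <- rbind(a = c(2, 2, 0), b = c(0, 2, 2), c = c(2, 2, 0))
  d <- as.matrix(bray_curtis(x))
  expect_equal(d["a", "b"], 0.5)   # (2+0+2)/(2+4+2)
  expect_equal(d["a", "c"], 0)     # identical rows
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d, t(d))

  # disjoint support: complete turnover
  y <- rbind(p = c(1, 1, 0, 0), q = c(0, 0, 1, 1))
  expect_equal(as.matrix(bray_curtis(y))["p", "q"], 1)

  expect_error(bray_curtis(rbind(c(0, 0), c(0, 0))), "all-zero")
})

test_that("sequential PERMANOVA partitions the distance SS and separates groups", {
  # near-perfect separation: between-group distance 1, within 0.05; the
  # smallest attainable p for a 4+4 design is the fraction of label
  # permutations preserving the partition, 4!4!2/8! ~ 0.029
  n <- 8
  g <- rep(c("A", "B"), each = 4)
  d <- matrix(1, n, n) - outer(g, g, "==")
  d[d == 0] <- 0.05
  diag(d) <- 0
  md <- data.frame(grp = g)
  res <- adonis_permanova(as.dist(d), md, "grp", n_permutations = 999, seed = 1)
  expect_gt(res$r2[res$term == "grp"], 0.98)
  expect_lte(res$p_value[res$term == "grp"], 0.05)
  expect_equal(sum(res$r2), 1, tolerance = 1e-9)

  # term + residual R2 always sums to one, multiple terms incl. continuous
  ch <- tiny_cohort(n = 40, seed = 3)
  dd <- bray_curtis(ch$species_view)
  res2 <- adonis_permanova(dd, ch$metadata,
                           c("age", "platform", "extraction_kit"),
                           n_permutations = 199, seed = 2)
  expect_equal(sum(res2$r2), 1, tolerance = 1e-9)
  expect_equal(nrow(res2), 4)  # 3 terms + residual
  expect_true(all(res2$p_value[1:3] >= 1 / 200))
  # Bonferroni across the three tested terms
  expect_equal(res2$p_adjusted[1:3], pmin(1, res2$p_value[1:3] * 3))

  expect_error(adonis_permanova(dd, transform(ch$metadata, k = "x"), "k"),
               "single level")
  expect_warning(adonis_permanova(dd, ch$metadata, "platform",
                                  n_permutations = 50, seed = 1),
                 "coarse")
})

test_that("permutation p matches exhaustive enumeration on a 6-sample toy", {
  set.seed(42)
  x <- matrix(runif(6 * 4), 6)
  x[1:3, 1] <- x[1:3, 1] + 0.6   # mild group signal
  x <- x / rowSums(x)
  g <- rep(c("A", "B"), each = 3)
  d <- bray_curtis(x)

  p_exact <- permanova_p_exact(d, g)      # all 720 label orders
  res <- adonis_permanova(d, data.frame(grp = g), "grp",
                          n_permutations = 9999, seed = 7)
  p_hat <- res$p_value[res$term == "grp"]
  # Monte-Carlo tolerance: 3 SEs at 9999 draws plus enumeration granularity
  tol <- 3 * sqrt(p_exact * (1 - p_exact) / 9999) + 1 / 720
  expect_lt(abs(p_hat - p_exact), tol + 1e-4)

  # the wrapper's pseudo-F agrees with the independent SS identities
  f_oracle <- permanova_F_oracle(d, g)
  expect_equal(res$pseudo_F[res$term == "grp"], f_oracle, tolerance = 1e-10)
})

test_that("PERMANOVA results are invariant to a joint row permutation", {
  ch <- tiny_cohort(n = 30, seed = 8)
  d <- bray_curtis(ch$species_view)
  res1 <- adonis_permanova(d, ch$metadata, c("sex", "platform"),
                           n_permutations = 199, seed = 5)
  perm <- sample(30)
  dm <- as.matrix(d)[perm, perm]
  res2 <- adonis_permanova(as.dist(dm), ch$metadata[perm, ],
                           c("sex", "platform"),
                           n_permutations = 199, seed = 5)
  expect_equal(res1$r2, res2$r2, tolerance = 1e-12)
  expect_equal(res1$pseudo_F, res2$pseudo_F, tolerance = 1e-12)
})

test_that("M49 regrouping maps countries and rejects unknowns", {
  expect_equal(regroup_to_subregion(c("CHN", "USA", "SWE", "ITA")),
               c("EA", "NA", "NE", "SE"))
  expect_equal(expand_subregion_code(c("EA", "WE")),
               c("Eastern Asia", "Western Europe"))
  expect_error(regroup_to_subregion("Atlantis"), "Atlantis")
  expect_error(expand_subregion_code("ZZ"), "ZZ")
})

test_that("metadata columns are filtered by missingness and redundancy", {
  md <- data.frame(age = 1:10,
                   half_missing = c(rep(NA, 5), 1:5),
                   full = letters[1:10],
                   age_category = rep(c("young", "old"), 5))
  out <- suppressMessages(
    filter_metadata_columns(md, missing_threshold = 0.4,
                            redundancy_map = c(age_category = "age")))
  expect_named(out, c("age", "full"))
  expect_error(filter_metadata_columns(data.frame(x = 1)), "age")
})

test_that("subregion screening drops small bins and removes enriched bins first", {
  # bins of 250/300/150: the 150 bin goes before the loop at min_bin_size 200
  md <- data.frame(sample_id = as.character(1:700),
                   subregion = rep(c("A", "B", "C"), c(250, 300, 150)),
                   age = runif(700, 20, 90))
  scr <- screen_subregions(md, min_bin_size = 200, threshold = 0.01,
                           scheme = cv_scheme(2, 5, seed = 1), seed = 2)
  expect_equal(scr$dropped_small_bins, "C")
  expect_false("C" %in% scr$retained_subregions)

  # unconfounded cohort: the loop exits immediately, all large bins retained
  ch0 <- simulate_cohort(n_samples = 400, n_species = 5, n_pathways = 5,
                         n_signal_features = 2, confound_strength = 0, seed = 31)
  scr0 <- screen_subregions(ch0$metadata, min_bin_size = 40, threshold = 0.01,
                            scheme = cv_scheme(2, 5, seed = 1), seed = 3)
  expect_equal(nrow(scr0$epochs), 0)
  expect_setequal(scr0$retained_subregions, unique(ch0$metadata$subregion))

  # one strongly age-enriched subregion is removed in epoch 1, and the
  # removal order is importance-descending with shrinking sample sets
  ch1 <- simulate_cohort(n_samples = 600, n_species = 5, n_pathways = 5,
                         n_signal_features = 2,
                         subregions = c(EA = .3, "NA" = .3, NE = .2, SE = .2),
                         confounded_subregions = "EA",
                         confound_strength = 0.25, seed = 33)
  scr1 <- screen_subregions(ch1$metadata, min_bin_size = 40, threshold = 0.01,
                            scheme = cv_scheme(2, 5, seed = 1), seed = 4)
  expect_equal(scr1$epochs$removed_subregion[1], "EA")
  expect_lt(scr1$final_assoc_r2, 0.01)
  # retained samples exclude every removed subregion (monotone shrinkage)
  kept_md <- ch1$metadata[ch1$metadata$sample_id %in% scr1$retained_sample_ids, ]
  expect_false(any(kept_md$subregion %in% scr1$epochs$removed_subregion))
  expect_setequal(scr1$retained_subregions, unique(kept_md$subregion))

  expect_error(screen_subregions(md[1:100, ], min_bin_size = 200), "all subregion")
})
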