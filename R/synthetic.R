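#' Configuration for a synthetic two-view cohort
#'
#' Collects and validates the parameters of [simulate_cohort()]. The
#' defaults describe a pooled adult stool-metagenome population: ages on
#' 18-107 years with median 52, four M49 subregions, log-normal baseline
#' abundances with a sparsity floor, and a small set of planted features
#' whose log-abundance drifts monotonically with age in each view.
#'
#' @param n_samples number of samples.
#' @param n_species,n_pathways feature dimension of the species / pathway
#'   view.
#' @param age_range numeric length-2, must lie within \[18, 107\] years.
#' @param age_median target median age in years (achieved within sampling
#'   noise via a calibrated Beta marginal).
#' @param subregions named numeric vector of sampling weights, one entry
#'   per subregion label.
#' @param confound_strength target R-squared of the subregion-to-age
#'   association, in \[0, 1). 0 means geography independent of age.
#' @param confounded_subregions labels carrying the planted age
#'   enrichment (each becomes enriched in one age window); default
#'   (`NULL`) uses the first half of the subregion labels. Ignored when
#'   `confound_strength = 0`.
#' @param n_signal_features planted age-associated features per view.
#' @param signal_effect log-abundance slope per year of age for planted
#'   features (sign drawn per feature).
#' @param threshold_fraction fraction of planted features whose trend is a
#'   step (threshold at a mid-life age) rather than linear — heterogeneous
#'   signal shapes exercise non-linear learners.
#' @param noise_dispersion standard deviation of per-entry log-abundance
#'   noise (> 0).
#' @param region_effect standard deviation of subregion-specific
#'   log-abundance offsets (geography structure in the views).
#' @param region_feature_fraction fraction of features per view carrying
#'   subregion offsets.
#' @param sparsity_floor relative abundances below this value are zeroed
#'   before closure (exercises the zero-replacement step).
#' @param seed integer seed; the cohort is a deterministic function of the
#'   configuration.
#' @return an object of class `"cohort_config"`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_samples = 400,
                          n_species = 120,
                          n_pathways = 80,
                          age_range = c(18, 107),
                          age_median = 52,
                          subregions = c(EA = 0.30, "NA" = 0.25, NE = 0.25, SE = 0.20),
                          confound_strength = 0,
                          confounded_subregions = NULL,
                          n_signal_features = 10,
                          signal_effect = 0.03,
                          threshold_fraction = 0,
                          noise_dispersion = 1,
                          region_effect = 1,
                          region_feature_fraction = 0.1,
                          sparsity_floor = 1e-5,
                          seed = 1) {
  stopifnot(n_samples >= 10, n_species >= 2, n_pathways >= 2)
  if (length(age_range) != 2 || age_range[1] < 18 || age_range[2] > 107 ||
      age_range[1] >= age_range[2])
    stop("age_range must be an increasing pair within [18, 107]")
  if (age_median <= age_range[1] || age_median >= age_range[2])
    stop("age_median must lie strictly inside age_range")
  if (is.null(names(subregions)) || any(subregions <= 0))
    stop("subregions must be a named vector of positive weights")
  if (confound_strength < 0 || confound_strength >= 1)
    stop("confound_strength must be in [0, 1)")
  if (n_signal_features > min(n_species, n_pathways))
    stop("n_signal_features exceeds a view dimension")
  if (noise_dispersion <= 0) stop("noise_dispersion must be > 0")
  if (threshold_fraction < 0 || threshold_fraction > 1)
    stop("threshold_fraction must be in [0, 1]")
  structure(list(
    n_samples = as.integer(n_samples),
    n_species = as.integer(n_species),
    n_pathways = as.integer(n_pathways),
    age_range = as.numeric(age_range),
    age_median = as.numeric(age_median),
    subregions = subregions / sum(subregions),
    confound_strength = confound_strength,
    confounded_subregions = confounded_subregions,
    n_signal_features = as.integer(n_signal_features),
    signal_effect = signal_effect,
    threshold_fraction = threshold_fraction,
    noise_dispersion = noise_dispersion,
    region_effect = region_effect,
    region_feature_fraction = region_feature_fraction,
    sparsity_floor = sparsity_floor,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Fraction of age variance explained by group means of `labels`.
r2_between <- function(age, labels) {
  gm <- tapply(age, labels, mean)
  1 - sum((age - gm[labels])^2) / sum((age - mean(age))^2)
}

# Draw ages from a Beta marginal scaled to age_range, with the Beta's second
# shape solved so the population median hits age_median.
draw_ages <- function(n, range, med) {
  q <- (med - range[1]) / (range[2] - range[1])
  a <- 1.5
  b <- uniroot(function(b) qbeta(0.5, a, b) - q, c(0.02, 200))$root
  range[1] + (range[2] - range[1]) * rbeta(n, a, b)
}

# Assign subregions with a target age~subregion R^2. The planted
# confounding is concentrated in `confounded` subregions: each confounded
# label owns an age-quantile window (widths proportional to its sampling
# weight, packed from the old end of the age axis). With mixing
# probability m a sample inside a window takes that window's label
# ("sample enrichment in a certain age range"); all other draws are
# age-independent, so the *unconfounded* labels have identical conditional
# age distributions and removing the confounded bins decouples geography
# from age. The mixing fraction is calibrated by bisection on the realized
# ages so the between-subregion R^2 of age hits `target`.
assign_subregions <- function(age, weights, target, confounded = NULL) {
  n <- length(age)
  labs <- names(weights)
  indep <- sample(labs, n, replace = TRUE, prob = weights)
  if (target == 0) return(structure(indep, confounded = character(0)))
  if (is.null(confounded)) confounded <- labs[seq_len(ceiling(length(labs) / 2))]
  stopifnot(all(confounded %in% labs))

  q <- rank(age, ties.method = "first") / n
  hi_edge <- 1 - c(0, cumsum(weights[confounded]))
  window_label <- rep(NA_character_, n)
  for (j in seq_along(confounded)) {
    inw <- q <= hi_edge[j] & q > hi_edge[j + 1]
    window_label[inw] <- confounded[j]
  }
  others <- setdiff(labs, confounded)
  fallback <- if (length(others))
    sample(others, n, replace = TRUE, prob = weights[others]) else indep
  u <- runif(n)
  mix <- function(m) ifelse(u < m & !is.na(window_label), window_label,
                            ifelse(u < m, fallback, indep))
  r2max <- r2_between(age, mix(1))
  if (target > r2max - 0.02)
    stop(sprintf(
      "infeasible confound_strength %.3f: at most ~%.3f achievable with %d confounded subregion(s)",
      target, r2max - 0.02, length(confounded)))
  lo <- 0; hi <- 1
  for (i in 1:60) {
    m <- (lo + hi) / 2
    if (r2_between(age, mix(m)) < target) lo <- m else hi <- m
  }
  structure(mix((lo + hi) / 2), confounded = confounded)
}

# One compositional view: log-normal baseline + planted age trends +
# subregion offsets, sparsified and closed to unit row sums.
make_view <- function(prefix, p, age, subregion, cfg) {
  n <- length(age)
  feature_ids <- sprintf("%s%03d", prefix, seq_len(p))
  mu0 <- rnorm(p, mean = 0, sd = 2)

  sig_idx <- sort(sample.int(p, cfg$n_signal_features))
  # balanced trend directions (as many age-enriched as age-depleted
  # markers) so the planted drift cancels in the per-sample geometric mean
  # and does not bleed into unplanted CLR coordinates via closure
  sign <- sample(rep_len(c(1, -1), cfg$n_signal_features))
  shape <- ifelse(runif(cfg$n_signal_features) < cfg$threshold_fraction,
                  "threshold", "linear")
  L <- matrix(rep(mu0, each = n), nrow = n)
  age_c <- age - mean(age)
  for (j in seq_along(sig_idx)) {
    if (shape[j] == "linear") {
      eff <- sign[j] * cfg$signal_effect * age_c
    } else {
      cut <- quantile(age, runif(1, 0.3, 0.7))
      step <- (age > cut) - mean(age > cut)
      # step height comparable to a linear drift over ~30 years
      eff <- sign[j] * cfg$signal_effect * 30 * step
    }
    L[, sig_idx[j]] <- L[, sig_idx[j]] + eff
  }

  n_reg <- ceiling(cfg$region_feature_fraction * p)
  reg_idx <- sample.int(p, n_reg)
  labs <- names(cfg$subregions)
  offs <- matrix(rnorm(length(labs) * n_reg, sd = cfg$region_effect),
                 nrow = length(labs), dimnames = list(labs, NULL))
  L[, reg_idx] <- L[, reg_idx] + offs[subregion, , drop = FALSE]

  L <- L + matrix(rnorm(n * p, sd = cfg$noise_dispersion), nrow = n)
  A <- exp(L)
  A <- A / rowSums(A)
  A[A < cfg$sparsity_floor] <- 0
  keep <- rowSums(A) > 0
  if (!all(keep)) stop("sparsity floor zeroed an entire sample row")
  A <- A / rowSums(A)
  dimnames(A) <- list(NULL, feature_ids)
  list(values = A,
       truth = data.frame(feature_id = feature_ids[sig_idx],
                          sign = sign, shape = shape,
                          stringsAsFactors = FALSE))
}

# representative countries per synthetic subregion label (for metadata
# plumbing; regrouping maps them back)
.synthetic_countries <- list(
  EA = c("CHN", "JPN"), "NA" = c("USA", "CAN"), NE = c("SWE", "DNK"),
  SE = c("ITA", "ESP"), WE = c("DEU", "FRA", "NLD"), CE = c("AUT", "HUN"),
  SA = c("IND"), SEA = c("IDN", "MYS"), WA = c("ISR", "KAZ"),
  OC = c("FJI"), AF = c("TZA", "GHA", "MDG", "ETH"), SAM = c("PER")
)

#' Generate a synthetic two-view compositional cohort
#'
#' Draws a cohort with two compositional views (species-like and
#' pathway-like), per-sample metadata, and a ground-truth record of the
#' planted age-associated features. Ages follow a calibrated Beta marginal
#' on the configured range; subregion labels are assigned by an
#' age-quantile/independent mixture whose mixing fraction is calibrated on
#' the realized ages so the subregion-to-age association R-squared hits
#' `confound_strength`; baseline log-abundances are Gaussian per feature
#' (log-normal abundances) with planted linear or threshold age trends and
#' subregion offsets; rows are sparsified below `sparsity_floor` and closed
#' to unit sum. The result is a deterministic function of the
#' configuration, including its seed.
#'
#' @param config a [cohort_config()] object, or `NULL` to build one from
#'   `...`.
#' @param ... passed to [cohort_config()] when `config` is `NULL`.
#' @return an object of class `"synthetic_cohort"`: a list with elements
#'   `species_view`, `pathway_view` (samples x features matrices, rows
#'   summing to 1), `metadata` (data frame with `sample_id`, `age`,
#'   `country`, `subregion`, `westernized`, `sex`, `bmi`, `platform`,
#'   `extraction_kit`), `truth` (per-view data frames of planted feature
#'   IDs, trend signs and shapes) and `config`.
#' @examples
#' ch <- simulate_cohort(n_samples = 50, n_species = 20, n_pathways = 15,
#'                       seed = 7)
#' range(ch$metadata$age)
#' rowSums(ch$species_view)[1:3]
#' ch$truth$species
#' @export
simulate_cohort <- function(config = NULL, ...) {
  cfg <- if (is.null(config)) cohort_config(...) else config
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    ids <- sprintf("SAMP%05d", seq_len(n))
    age <- draw_ages(n, cfg$age_range, cfg$age_median)
    subregion <- assign_subregions(age, cfg$subregions, cfg$confound_strength,
                                   cfg$confounded_subregions)
    confounded <- attr(subregion, "confounded")
    subregion <- as.character(subregion)

    sp <- make_view("sp", cfg$n_species, age, subregion, cfg)
    pw <- make_view("pw", cfg$n_pathways, age, subregion, cfg)
    rownames(sp$values) <- ids
    rownames(pw$values) <- ids

    country <- vapply(subregion, function(s) {
      pool <- .synthetic_countries[[s]] %||% paste0(s, "1")
      pool[sample.int(length(pool), 1)]
    }, character(1))
    metadata <- data.frame(
      sample_id = ids,
      age = age,
      country = country,
      subregion = subregion,
      westernized = sample(c("yes", "no"), n, replace = TRUE, prob = c(.85, .15)),
      sex = sample(c("female", "male"), n, replace = TRUE),
      bmi = pmax(15, rnorm(n, 24, 4)),
      platform = sample(c("IlluminaHiSeq", "IlluminaNovaSeq"), n,
                        replace = TRUE, prob = c(.7, .3)),
      extraction_kit = sample(c("Qiagen", "MoBio"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    structure(list(species_view = sp$values,
                   pathway_view = pw$values,
                   metadata = metadata,
                   truth = list(species = sp$truth, pathway = pw$truth,
                                confounded_subregions = confounded),
                   config = cfg),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic two-view cohort: %d samples\n", nrow(x$metadata)))
  cat(sprintf("  species view: %d features; pathway view: %d features\n",
              ncol(x$species_view), ncol(x$pathway_view)))
  cat(sprintf("  age: %.1f-%.1f y (median %.1f); subregions: %s\n",
              min(x$metadata$age), max(x$metadata$age), median(x$metadata$age),
              paste(names(x$config$subregions), collapse = ", ")))
  cat(sprintf("  planted signal features: %d per view; confound target R2 = %.2f\n",
              x$config$n_signal_features, x$config$confound_strength))
  invisible(x)
}

#' Write a synthetic cohort to the standard pipeline input files
#'
#' Writes two abundance TSVs (`species.tsv`, `pathways.tsv`), a metadata TSV
#' (`metadata.tsv`) and a JSON ground-truth file (`truth.json`) into `dir`.
#'
#' @param cohort a `"synthetic_cohort"` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_table(cohort$species_view, file.path(dir, "species.tsv"))
  write_abundance_table(cohort$pathway_view, file.path(dir, "pathways.tsv"))
  write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "columns")
  invisible(dir)
}
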