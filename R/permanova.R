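#' Filter metadata columns by missingness and redundancy
#'
#' Keeps reliable, non-redundant metadata: columns whose missing fraction
#' is below `missing_threshold` and that are not declared redundant to a
#' kept column (e.g. an age category derived from age).
#'
#' @param metadata data frame; empty strings and `NA` count as missing.
#' @param missing_threshold drop columns with missing fraction `>=` this
#'   value (default 0.4).
#' @param redundancy_map named character vector mapping redundant columns to
#'   the column they duplicate (`c(age_category = "age")`); a redundant
#'   column is dropped whenever its target is kept.
#' @return the filtered data frame; dropped column names are reported via
#'   `message()`.
#' @export
filter_metadata_columns <- function(metadata, missing_threshold = 0.4,
                                    redundancy_map = c(age_category = "age")) {
  stopifnot(is.data.frame(metadata))
  if (!"age" %in% names(metadata)) stop("metadata must contain an 'age' column")
  miss <- vapply(metadata, function(x) mean(is.na(x) | (is.character(x) & x == "")),
                 numeric(1))
  drop <- names(metadata)[miss >= missing_threshold & names(metadata) != "age"]
  redundant <- names(redundancy_map)[redundancy_map %in% setdiff(names(metadata), drop) &
                                     names(redundancy_map) %in% names(metadata)]
  drop <- union(drop, redundant)
  if (length(drop))
    message("dropping metadata column(s): ", paste(drop, collapse = ", "))
  metadata[, setdiff(names(metadata), drop), drop = FALSE]
}

#' The bundled UN M49 country-to-subregion mapping
#'
#' @return data frame with columns `country` (ISO-3 code),
#'   `subregion_code`, `subregion` (full UN geoscheme name).
#' @export
m49_mapping <- function() {
  path <- system.file("extdata", "m49_subregions.tsv", package = "agestack")
  # "NA" is the Northern America code, not a missing value
  read.delim(path, stringsAsFactors = FALSE, na.strings = "")
}

#' Regroup countries to UN M49 subregions
#'
#' Coarsens country labels to subregion-level bins (UN standard country or
#' area codes for statistical use, M49), the grouping used before
#' decoupling geography from age.
#'
#' @param country character vector of country codes.
#' @param mapping data frame with `country` and `subregion_code` columns
#'   (default: the bundled [m49_mapping()]).
#' @return character vector of subregion codes (e.g. `"EA"` for Eastern
#'   Asia).
#' @export
regroup_to_subregion <- function(country, mapping = m49_mapping()) {
  idx <- match(country, mapping$country)
  if (anyNA(idx)) {
    bad <- unique(country[is.na(idx)])
    stop("country label(s) not in the M49 mapping: ", paste(bad, collapse = ", "))
  }
  mapping$subregion_code[idx]
}

#' Expand a subregion code to its full M49 name
#'
#' @param code character vector of subregion codes (e.g. `"EA"`, `"WE"`).
#' @param mapping as in [regroup_to_subregion()].
#' @return full subregion names (e.g. `"Eastern Asia"`).
#' @export
expand_subregion_code <- function(code, mapping = m49_mapping()) {
  lut <- unique(mapping[, c("subregion_code", "subregion")])
  idx <- match(code, lut$subregion_code)
  if (anyNA(idx))
    stop("unknown subregion code(s): ", paste(unique(code[is.na(idx)]), collapse = ", "))
  lut$subregion[idx]
}

#' Bray-Curtis dissimilarity matrix
#'
#' Computes `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` between all sample
#' pairs of an abundance view — the beta-diversity measure used for the
#' PERMANOVA screening. For closed (unit-sum) compositions the values lie
#' in \[0, 1\].
#'
#' @param view samples x features non-negative matrix.
#' @return a `dist` object (symmetric, zero diagonal).
#' @export
bray_curtis <- function(view) {
  x <- check_view(view)
  if (any(rowSums(x) == 0))
    stop("all-zero sample row(s): Bray-Curtis undefined (",
         paste(head(rownames(x)[rowSums(x) == 0], 3), collapse = ", "), ")")
  vegan::vegdist(x, method = "bray")
}

#' Covariate-adjusted PERMANOVA on a dissimilarity matrix
#'
#' Sequential (Type-I) partitioning of the sum of squares of a
#' Gower-centered distance matrix across the model terms, in the order
#' given, with a free-permutation test of sample labels (9999 permutations
#' by default) and Bonferroni adjustment across terms. Continuous terms
#' (age, BMI) enter as single-df regression terms. Computation is delegated
#' to \code{vegan::adonis2(..., by = "terms")}.
#'
#' @param dmat a `dist` object or square symmetric matrix.
#' @param metadata data frame aligned with `dmat` rows.
#' @param terms character vector of metadata columns, in model order.
#' @param n_permutations number of permutations (default 9999; fewer than
#'   99 triggers a warning).
#' @param seed integer seed for the permutation stream.
#' @return data frame with one row per term plus a `Residual` row:
#'   `term`, `df`, `sum_sq`, `r2`, `pseudo_F`, `p_value`, `p_adjusted`
#'   (Bonferroni across the tested terms), `n_permutations`. Term and
#'   residual `r2` sum to 1. Samples with a missing value in any term are
#'   dropped listwise with a message.
#' @export
adonis_permanova <- function(dmat, metadata, terms,
                             n_permutations = 9999, seed = NULL) {
  stopifnot(is.data.frame(metadata), length(terms) >= 1)
  missing_terms <- setdiff(terms, names(metadata))
  if (length(missing_terms))
    stop("term(s) not in metadata: ", paste(missing_terms, collapse = ", "))
  if (n_permutations < 99)
    warning("fewer than 99 permutations: p-values are very coarse")
  m <- as.matrix(dmat)
  if (nrow(m) != nrow(metadata))
    stop("dmat and metadata have different numbers of samples")

  md <- metadata[, terms, drop = FALSE]
  keep <- complete.cases(md)
  if (!all(keep)) {
    message(sprintf("dropping %d sample(s) with missing values in PERMANOVA terms",
                    sum(!keep)))
    m <- m[keep, keep, drop = FALSE]
    md <- md[keep, , drop = FALSE]
  }
  for (t in terms) {
    v <- md[[t]]
    if (!is.numeric(v) && length(unique(v)) < 2)
      stop(sprintf("term '%s' has a single level after filtering", t))
    if (is.character(v)) md[[t]] <- factor(v)
  }

  d <- as.dist(m)
  fml <- as.formula(paste("d ~", paste(terms, collapse = " + ")))
  res <- with_seed(seed %||% 4242,
                   vegan::adonis2(fml, data = md, permutations = n_permutations,
                                  by = "terms", parallel = 1))
  tab <- as.data.frame(res)
  tab <- tab[rownames(tab) != "Total", , drop = FALSE]
  out <- data.frame(
    term = rownames(tab),
    df = tab$Df,
    sum_sq = tab$SumOfSqs,
    r2 = tab$R2,
    pseudo_F = tab$F,
    p_value = tab$`Pr(>F)`,
    stringsAsFactors = FALSE
  )
  is_term <- out$term != "Residual"
  out$p_adjusted <- NA_real_
  out$p_adjusted[is_term] <- pmin(1, out$p_value[is_term] * sum(is_term))
  out$n_permutations <- n_permutations
  rownames(out) <- NULL
  out
}

#' Per-covariate PERMANOVA adjusted for technical confounders
#'
#' Runs one sequential PERMANOVA per covariate with the technical
#' confounders (sequencing platform, DNA extraction kit) in the same
#' formula, and Bonferroni-corrects the covariate p-values across the
#' covariates tested. The default places each covariate first in its
#' formula; `covariate_first = FALSE` puts the confounders first, i.e. the
#' covariate is assessed on the residual after the confounders.
#'
#' @param dmat,metadata,n_permutations,seed as in [adonis_permanova()].
#' @param covariates character vector of covariate columns.
#' @param confounders character vector of confounder columns (may be
#'   empty).
#' @param covariate_first logical; term order within each formula.
#' @return data frame with one row per covariate: its term statistics from
#'   the per-covariate model, `p_adjusted` Bonferroni-corrected across
#'   covariates.
#' @export
permanova_covariates <- function(dmat, metadata, covariates,
                                 confounders = c("platform", "extraction_kit"),
                                 n_permutations = 9999, seed = NULL,
                                 covariate_first = TRUE) {
  rows <- lapply(seq_along(covariates), function(i) {
    cv <- covariates[i]
    terms <- if (covariate_first) c(cv, confounders) else c(confounders, cv)
    res <- adonis_permanova(dmat, metadata, terms,
                            n_permutations = n_permutations,
                            seed = child_seed(seed %||% 4242, i))
    res[res$term == cv, c("term", "df", "sum_sq", "r2", "pseudo_F", "p_value"),
        drop = FALSE]
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_value * length(covariates))
  out$n_permutations <- n_permutations
  rownames(out) <- NULL
  out
}
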