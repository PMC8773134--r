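# End-to-end orchestration: simulate/read -> metadata filter -> regroup ->
# screen -> preprocess -> bench -> select -> stack -> interpret.

# row-subset a design matrix, keeping the column-origin tags ([ drops attrs)
subset_rows <- function(d, rows) {
  o <- attr(d, "origin")
  y <- d[rows, , drop = FALSE]
  attr(y, "origin") <- o
  y
}

# polynomial string hash (mod 2^31 - 1; exact in doubles) as a manifest tag
str_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Configuration for [run_pipeline()]
#'
#' Either `input` (paths to species / pathways / metadata TSVs) or
#' `synthetic` (a [cohort_config()]) must be given.
#'
#' @param input named list with `species`, `pathways`, `metadata` file
#'   paths, or `NULL`.
#' @param synthetic a [cohort_config()], or `NULL`.
#' @param out_dir output directory.
#' @param stages character subset of
#'   `c("screen", "bench", "select", "train", "interpret")`.
#' @param min_age samples younger than this are removed (default 18).
#' @param missing_threshold metadata column missingness cutoff.
#' @param n_permutations PERMANOVA permutations (default 999 here; raise
#'   to 9999 for a full analysis).
#' @param min_bin_size,screen_threshold subregion screening parameters.
#' @param cv outer [cv_scheme()] used for benchmarking and screening.
#' @param delta zero-replacement delta ("auto" or numeric).
#' @param bench_learners learners scored in the bench stage.
#' @param select_methods selection methods compared in the select stage.
#' @param base_learners stage-1 panel for the ensemble.
#' @param generalizer stage-2 method.
#' @param use_subregion_feature append the one-hot subregion block to each
#'   view's design.
#' @param holdout_fraction samples held out from ensemble training for
#'   PFI evaluation.
#' @param pfi_shuffles shuffles per feature in the interpret stage.
#' @param seed master seed.
#' @return a `"pipeline_config"` list.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            out_dir = tempfile("agestack_run_"),
                            stages = c("screen", "select", "train", "interpret"),
                            min_age = 18,
                            missing_threshold = 0.4,
                            n_permutations = 999,
                            min_bin_size = 200,
                            screen_threshold = 0.01,
                            cv = cv_scheme(n_repeats = 2, n_folds = 5),
                            delta = "auto",
                            bench_learners = c("LR", "Lasso", "RF", "LGB"),
                            select_methods = c("FR", "GBRT"),
                            base_learners = .stack_base_names,
                            generalizer = "LR",
                            use_subregion_feature = TRUE,
                            holdout_fraction = 0.25,
                            pfi_shuffles = 50,
                            seed = 1L) {
  if (is.null(input) && is.null(synthetic))
    stop("provide either 'input' paths or a 'synthetic' cohort_config")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full aging-clock pipeline
#'
#' Executes the configured stages in order, writes per-stage reports and a
#' JSON manifest (the full serialized configuration plus a hash tag
#' repeated in every output header line) into `config$out_dir`, and
#' returns the in-memory results. Any stage failure aborts with the stage
#' name in the error.
#'
#' @param config a [pipeline_config()], or the path of a YAML file with
#'   the same fields.
#' @return list with elements per executed stage (`metadata`, `screen`,
#'   `bench`, `selection`, `model`, `biomarkers`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfgl <- yaml::read_yaml(config)
    if (!is.null(cfgl$synthetic)) cfgl$synthetic <- do.call(cohort_config, cfgl$synthetic)
    if (!is.null(cfgl$cv)) cfgl$cv <- do.call(cv_scheme, cfgl$cv)
    config <- do.call(pipeline_config, cfgl)
  }
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "agestack",
                   version = as.character(utils::packageVersion("agestack")),
                   config = lapply(cfg, function(x)
                     if (is.function(x)) NULL else unclass(x)))
  mstr <- jsonlite::toJSON(manifest, auto_unbox = TRUE, null = "null")
  tag <- str_hash(as.character(mstr))
  writeLines(as.character(mstr), file.path(cfg$out_dir, "manifest.json"))
  stamp <- function(path) cat(sprintf("# manifest %s\n", tag), file = path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  out <- list(out_dir = cfg$out_dir, manifest_hash = tag)

  # --- input ---------------------------------------------------------------
  dat <- stage("input", {
    if (!is.null(cfg$synthetic)) {
      ch <- simulate_cohort(cfg$synthetic)
      list(views = list(species = ch$species_view, pathway = ch$pathway_view),
           metadata = ch$metadata, truth = ch$truth)
    } else {
      list(views = list(species = read_abundance_table(cfg$input$species),
                        pathway = read_abundance_table(cfg$input$pathways)),
           metadata = read.delim(cfg$input$metadata, stringsAsFactors = FALSE),
           truth = NULL)
    }
  })

  # --- metadata filter + regroup ------------------------------------------
  md <- stage("metadata", {
    md <- filter_metadata_columns(dat$metadata, cfg$missing_threshold)
    md <- md[!is.na(md$age) & md$age >= cfg$min_age, , drop = FALSE]
    if (!"subregion" %in% names(md) && "country" %in% names(md))
      md$subregion <- regroup_to_subregion(md$country)
    md
  })
  al <- align_samples(dat$views, md)
  views <- al$views; md <- al$metadata
  out$metadata <- md

  # --- screen --------------------------------------------------------------
  if ("screen" %in% cfg$stages) {
    out$screen <- stage("screen", {
      perma <- lapply(views, function(v) {
        keep <- rownames(v)
        permanova_covariates(bray_curtis(v), md[match(keep, md$sample_id), ],
                             covariates = intersect(c("age", "subregion", "westernized",
                                                      "sex", "bmi"), names(md)),
                             confounders = intersect(c("platform", "extraction_kit"),
                                                     names(md)),
                             n_permutations = cfg$n_permutations,
                             seed = child_seed(cfg$seed, 11L))
      })
      scr <- screen_subregions(md, min_bin_size = cfg$min_bin_size,
                               threshold = cfg$screen_threshold,
                               scheme = cfg$cv, seed = child_seed(cfg$seed, 12L))
      path <- file.path(cfg$out_dir, "screen_epochs.tsv")
      stamp(path)
      suppressWarnings(write.table(scr$epochs, path, sep = "\t", quote = FALSE,
                                   row.names = FALSE, append = TRUE))
      list(permanova = perma, screen = scr)
    })
    keep <- out$screen$screen$retained_sample_ids
    md <- md[md$sample_id %in% keep, , drop = FALSE]
    views <- lapply(views, function(v) v[rownames(v) %in% keep, , drop = FALSE])
  }

  # --- preprocess ----------------------------------------------------------
  designs <- stage("preprocess", {
    ds <- lapply(views, function(v)
      clr_transform(multiplicative_replacement(v, delta = cfg$delta)))
    if (cfg$use_subregion_feature) {
      oh <- encode_subregion(md)
      rownames(oh) <- md$sample_id
      ds <- lapply(ds, function(d)
        assemble_design(d, list(subregion = oh[rownames(d), , drop = FALSE])))
    }
    ds
  })
  age <- setNames(md$age, md$sample_id)

  # --- bench ---------------------------------------------------------------
  if ("bench" %in% cfg$stages) {
    out$bench <- stage("bench", {
      rows <- list()
      for (v in names(designs)) for (nm in cfg$bench_learners) {
        sc <- repeated_cv(learner_spec(nm, seed = cfg$seed),
                          subset_rows(designs[[v]], md$sample_id),
                          md$age, cfg$cv)
        rows[[length(rows) + 1L]] <-
          data.frame(view = v, learner = nm, repeat_ = sc$repeat_,
                     fold = sc$fold, r2 = sc$r2, mae = sc$mae)
      }
      tab <- do.call(rbind, rows)
      path <- file.path(cfg$out_dir, "bench.tsv")
      stamp(path)
      suppressWarnings(write.table(tab, path, sep = "\t", quote = FALSE,
                                   row.names = FALSE, append = TRUE))
      tab
    })
  }

  # --- select --------------------------------------------------------------
  if ("select" %in% cfg$stages) {
    out$selection <- stage("select", {
      sel <- lapply(names(designs), function(v) {
        X <- subset_rows(designs[[v]], md$sample_id)
        prim <- attr(X, "origin") %||% rep("primary", ncol(X))
        Xp <- X[, prim == "primary", drop = FALSE]
        outs <- lapply(cfg$select_methods, function(m)
          evaluate_selection(m, Xp, md$age,
                             specs = learner_registry(cfg$bench_learners,
                                                      seed = cfg$seed),
                             scheme = cfg$cv, seed = child_seed(cfg$seed, 21L)))
        chosen <- adjudicate_selection(outs)
        path <- file.path(cfg$out_dir, paste0("selected_", v, ".txt"))
        writeLines(chosen$selected, path)
        chosen
      })
      setNames(sel, names(designs))
    })
    designs <- lapply(names(designs), function(v) {
      X <- designs[[v]]
      prim <- attr(X, "origin") %||% rep("primary", ncol(X))
      keep_cols <- colnames(X) %in% out$selection[[v]]$selected | prim != "primary"
      Y <- X[, keep_cols, drop = FALSE]
      attr(Y, "origin") <- prim[keep_cols]
      Y
    })
    names(designs) <- names(out$selection)
  }

  # --- train + interpret ---------------------------------------------------
  if ("train" %in% cfg$stages) {
    split <- with_seed(child_seed(cfg$seed, 31L), {
      ho <- sample(md$sample_id, ceiling(cfg$holdout_fraction * nrow(md)))
      list(holdout = ho, train = setdiff(md$sample_id, ho))
    })
    model <- stage("train", {
      tr_views <- lapply(designs, function(d)
        subset_rows(d, rownames(d)[rownames(d) %in% split$train]))
      agestack(tr_views, age, base_learners = cfg$base_learners,
               generalizer = cfg$generalizer, k = 5,
               seed = child_seed(cfg$seed, 32L))
    })
    out$model <- model
    pred_path <- file.path(cfg$out_dir, "predictions.tsv")
    ho_views <- lapply(designs, function(d)
      d[rownames(d) %in% split$holdout, , drop = FALSE])
    pred <- predict(model, ho_views)
    stamp(pred_path)
    suppressWarnings(write.table(
      data.frame(sample_id = names(pred), predicted_age = pred),
      pred_path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))

    if ("interpret" %in% cfg$stages) {
      out$biomarkers <- stage("interpret", {
        tab <- biomarker_report(model, ho_views, age[names(pred)],
                                n_shuffles = cfg$pfi_shuffles,
                                seed = child_seed(cfg$seed, 33L))
        path <- file.path(cfg$out_dir, "biomarkers.tsv")
        stamp(path)
        suppressWarnings(write.table(tab, path, sep = "\t", quote = FALSE,
                                     row.names = FALSE, append = TRUE))
        tab
      })
    }
  }
  invisible(out)
}
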