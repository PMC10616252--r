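#' Pipeline configuration
#'
#' Collects every tunable the end-to-end workflow consumes: input
#' paths (or a synthetic-cohort spec), the absorption-rate threshold
#' (percent), the biomarker cutoff `top_k`, the significance threshold
#' `alpha`, PERMANOVA permutations, the calibration grid, and seeds.
#' Round-trips losslessly through YAML via [write_config()] /
#' [read_config()].
#'
#' @param abundance_path,metadata_path TSV inputs; ignored when
#'   `spec` is given.
#' @param spec An [synthetic_spec()] to simulate the cohort instead of
#'   reading files.
#' @param threshold Absorption-rate threshold in percent (default 10).
#' @param top_k Biomarker cutoff (default 10).
#' @param alpha Significance threshold for p-values (default 0.01).
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param n_mix Calibration mixing grid (default 5, 10, ..., 30).
#' @param n_repeats Calibration randomizations (default 5).
#' @param test_fraction Calibration held-out fraction (default 0.3).
#' @param seed Master seed for every random stage.
#' @param out_dir Run directory for stage artifacts.
#' @return An object of class `se_config`.
#' @export
pipeline_config <- function(abundance_path = NULL, metadata_path = NULL,
                            spec = NULL, threshold = 10, top_k = 10,
                            alpha = 0.01, n_permutations = 999,
                            n_mix = seq(5, 30, by = 5), n_repeats = 5,
                            test_fraction = 0.3, seed = 1L,
                            out_dir = tempfile("sehybrid_run_")) {
  if (is.null(spec) && (is.null(abundance_path) || is.null(metadata_path))) {
    abort("provide either a synthetic spec or abundance/metadata paths")
  }
  structure(list(
    abundance_path = abundance_path, metadata_path = metadata_path,
    spec = spec, threshold = threshold, top_k = top_k, alpha = alpha,
    n_permutations = n_permutations, n_mix = n_mix, n_repeats = n_repeats,
    test_fraction = test_fraction, seed = as.integer(seed), out_dir = out_dir
  ), class = "se_config")
}

#' @rdname pipeline_config
#' @param config An `se_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$spec)) {
    x$spec <- unclass(x$spec)
    # named vectors must become maps, or YAML drops the names
    x$spec$host_effect_sizes <- as.list(x$spec$host_effect_sizes)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$spec)) {
    sp <- lapply(x$spec[setdiff(names(x$spec), c("n_batches", "n_regions"))], unlist)
    x$spec <- do.call(synthetic_spec, sp)
  }
  x$n_mix <- as.numeric(unlist(x$n_mix))
  do.call(pipeline_config, x)
}

# Rank a batch's genera, falling back to both intervention stages when
# the batch has too few before-intervention profiles on its own.
rank_batch <- function(abundance, metadata, batch_id, seed) {
  keep <- metadata$batch == batch_id & metadata$stage == "before"
  if (sum(keep) < 10) keep <- metadata$batch == batch_id
  rank_features(abundance[match(metadata$sample_id[keep], abundance$sample_id), ],
                metadata$efficiency[keep], seed = seed)
}

stage_write <- function(obj, dir, name) {
  path <- file.path(dir, name)
  if (inherits(obj, "data.frame")) readr::write_tsv(obj, path, progress = FALSE)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full workflow end to end
#'
#' Executes, in order: simulate/load -> absorption labelling ->
#' alpha/beta diversity and host-variable effect-size scan (on the
#' first batch, before-intervention samples) -> all-genus feature
#' ranking -> learning curve -> top-k biomarker selection -> one-hot
#' encoding and L2 fusion -> hyperparameter tuning and training ->
#' direct transfer to the second batch -> hybrid calibration curve ->
#' cross-batch shared-biomarker screening and cross-cohort refined
#' evaluation. Every stage writes a TSV/JSON artifact into the run
#' directory, plus a provenance manifest (config hash, seeds, package
#' version, artifact list). Identical config and seed give identical
#' numeric outputs.
#'
#' @param config An `se_config` from [pipeline_config()].
#' @return Invisibly, a list of stage results; the run directory is in
#'   its `out_dir` element.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  log_stage <- function(stage, event, ...) {
    inform(sprintf("[%s] %s%s", stage, event,
                   if (...length()) paste0(" (", paste(..., sep = ", "), ")") else ""))
  }

  # --- load or simulate ---------------------------------------------------
  if (!is.null(config$spec)) {
    cohort <- generate_cohort(config$spec, seed = config$seed)
    abundance <- cohort$abundance; metadata <- cohort$metadata
    log_stage("simulate", "generated cohort", paste0("n=", nrow(abundance)))
  } else {
    abundance <- read_abundance(config$abundance_path)
    metadata <- read_metadata(config$metadata_path)
    log_stage("load", "read inputs", paste0("n=", nrow(abundance)))
  }
  paired <- align_samples(abundance, metadata)
  abundance <- paired$abundance; metadata <- paired$metadata

  # --- labels -------------------------------------------------------------
  metadata <- derive_absorption_labels(metadata, threshold_pct = config$threshold)
  abundance <- abundance[abundance$sample_id %in% metadata$sample_id, ]
  counts <- table(metadata$efficiency[metadata$stage == "before"])
  log_stage("label", "derived efficiency labels",
            paste(names(counts), counts, sep = "=", collapse = ", "))
  artifacts["labels"] <- stage_write(
    metadata[c("sample_id", "subject_id", "stage", "batch", "region",
               "absorption_rate", "efficiency")],
    config$out_dir, "labels.tsv")

  # batch layout: model on batch 1; transfer/calibrate on batch 2 (same
  # region) when present; cross-region refine on the last other-region batch
  batches <- unique(metadata$batch)
  b1 <- batches[1]
  before <- metadata$stage == "before"
  sel <- function(b, stage_before = TRUE) {
    keep <- metadata$batch == b & (if (stage_before) before else !before)
    list(abundance = abundance[match(metadata$sample_id[keep], abundance$sample_id), ],
         metadata = metadata[keep, ])
  }
  base <- sel(b1)

  # --- diversity ----------------------------------------------------------
  adiv <- alpha_diversity(base$abundance)
  artifacts["alpha_diversity"] <- stage_write(adiv, config$out_dir, "alpha_diversity.tsv")
  b1_all <- metadata$batch == b1
  dist_b1 <- bray_curtis(abundance[match(metadata$sample_id[b1_all], abundance$sample_id), ])
  scan_vars <- c("stage", "efficiency", "gender", "age", "bmi", "probiotics", "health_status")
  scan <- effect_size_scan(dist_b1, metadata[b1_all, ], scan_vars,
                           n_permutations = config$n_permutations, seed = config$seed)
  artifacts["effect_sizes"] <- stage_write(as.data.frame(scan), config$out_dir, "effect_sizes.tsv")
  log_stage("diversity", "effect-size scan done",
            paste0("top=", scan$variable[1], " R2=", signif(scan$r_squared[1], 3)))

  # correlation of alpha diversity with selenium content (before stage)
  corr <- dplyr::bind_rows(lapply(c("shannon", "simpson"), function(ix) {
    dplyr::mutate(spearman_cor(adiv[[ix]], base$metadata$selenium_before), index = ix)
  }))
  artifacts["diversity_selenium_cor"] <- stage_write(corr, config$out_dir, "diversity_selenium_cor.tsv")

  # --- rank, learning curve, biomarkers ------------------------------------
  y_base <- base$metadata$efficiency
  genus_tbl <- base$abundance
  ranking <- rank_features(genus_tbl, y_base, seed = config$seed)
  artifacts["ranking"] <- stage_write(as.data.frame(ranking), config$out_dir, "ranking.tsv")
  k_grid <- sort(unique(pmin(c(1, 2, 5, config$top_k, 15, 20, length(genus_columns(genus_tbl))),
                             length(genus_columns(genus_tbl)))))
  curve <- learning_curve(ranking, genus_tbl, y_base, k_values = k_grid, seed = config$seed)
  artifacts["learning_curve"] <- stage_write(as.data.frame(curve), config$out_dir, "learning_curve.tsv")
  biomarkers <- select_biomarkers(ranking, k = config$top_k)
  artifacts["biomarkers"] <- stage_write(tibble::tibble(genus = biomarkers),
                                         config$out_dir, "biomarkers.tsv")
  log_stage("biomarkers", "selected", paste0("k=", config$top_k))

  # --- encode, fuse, train -------------------------------------------------
  recipe <- feature_recipe(biomarkers)
  X_base <- apply_recipe(recipe, base$abundance, base$metadata)
  model <- tune_and_train(X_base, y_base, recipe = recipe,
                          source_data = list(abundance = base$abundance,
                                             metadata = base$metadata,
                                             labels = y_base),
                          seed = config$seed)
  # reference models: all genera, biomarkers only (no metadata)
  all_recipe <- feature_recipe(genus_columns(genus_tbl), encoding = NULL, normalize = FALSE)
  model_all <- tune_and_train(apply_recipe(all_recipe, base$abundance), y_base,
                              search_space = as.data.frame(model$params),
                              recipe = all_recipe, seed = config$seed)
  bio_recipe <- feature_recipe(biomarkers, encoding = NULL, normalize = FALSE)
  model_bio <- tune_and_train(apply_recipe(bio_recipe, base$abundance), y_base,
                              search_space = as.data.frame(model$params),
                              recipe = bio_recipe, seed = config$seed)
  cv_aucs <- c(model_all$cv_auc, model_bio$cv_auc, model$cv_auc)
  model_summary <- tibble::tibble(
    model = c("all_genera", "biomarkers", "biomarkers_plus_metadata"),
    cv_auc = cv_aucs
  )
  artifacts["models"] <- stage_write(model_summary, config$out_dir, "model_cv_auc.tsv")
  log_stage("train", "tuned and trained",
            paste0("fused CV AUC=", signif(model$cv_auc, 3)))

  results <- list(config = config, metadata = metadata, ranking = ranking,
                  learning_curve = curve, biomarkers = biomarkers,
                  effect_sizes = scan, alpha_diversity = adiv,
                  model = model, model_summary = model_summary,
                  out_dir = config$out_dir)

  # --- transfer + calibration on a same-region second batch ---------------
  same_region <- batches[-1][vapply(batches[-1], function(b) {
    metadata$region[match(b, metadata$batch)] == base$metadata$region[1]
  }, logical(1))]
  if (length(same_region)) {
    b2 <- sel(same_region[1])
    transfer <- transfer_evaluate(model, b2$abundance, b2$metadata,
                                  labels = b2$metadata$efficiency)
    n2 <- nrow(b2$metadata)
    usable_mix <- config$n_mix[config$n_mix <= n2 - max(1, floor(config$test_fraction * n2))]
    calib <- calibrate_hybrid(model, b2$abundance, b2$metadata,
                              labels = b2$metadata$efficiency,
                              n_mix = usable_mix, test_fraction = config$test_fraction,
                              n_repeats = config$n_repeats, seed = config$seed)
    artifacts["calibration_curve"] <- stage_write(as.data.frame(calib),
                                                  config$out_dir, "calibration_curve.tsv")
    log_stage("calibrate", "hybrid calibration done",
              paste0("transfer AUC=", signif(transfer$auc, 3),
                     " best calibrated=", signif(max(calib$auc_mean), 3)))
    results$transfer <- transfer
    results$calibration <- calib
    results$ranking_batch2 <- rank_batch(abundance, metadata, same_region[1], config$seed)
  }

  # --- cross-region shared-feature refinement ------------------------------
  other_region <- batches[-1][vapply(batches[-1], function(b) {
    metadata$region[match(b, metadata$batch)] != base$metadata$region[1]
  }, logical(1))]
  if (length(other_region)) {
    b3 <- sel(other_region[1])
    rankings <- list(ranking)
    if (!is.null(results$ranking_batch2)) rankings <- c(rankings, list(results$ranking_batch2))
    rankings <- c(rankings, list(rank_batch(abundance, metadata, other_region[1], config$seed)))
    shared <- shared_biomarkers(rankings, k = config$top_k)
    naive <- transfer_evaluate(model, b3$abundance, b3$metadata,
                               labels = b3$metadata$efficiency)
    results$cross_cohort_naive <- naive
    if (length(shared)) {
      refined <- cross_cohort_refine(model, shared, b3$abundance, b3$metadata,
                                     labels = b3$metadata$efficiency)
      results$shared_biomarkers <- shared
      results$cross_cohort_refined <- refined$evaluation
      artifacts["shared_biomarkers"] <- stage_write(tibble::tibble(genus = shared),
                                                    config$out_dir, "shared_biomarkers.tsv")
      log_stage("refine", "cross-cohort refinement done",
                paste0("naive AUC=", signif(naive$auc, 3),
                       " refined AUC=", signif(refined$evaluation$auc, 3)))
    }
  }

  # --- manifest + summary ---------------------------------------------------
  summary <- list(
    n_samples = nrow(abundance),
    class_counts = as.list(counts),
    top_effect_variable = scan$variable[1],
    biomarkers = biomarkers,
    cv_auc = model_summary$cv_auc,
    transfer_auc = results$transfer$auc %||% NA,
    best_calibrated_auc = if (!is.null(results$calibration)) max(results$calibration$auc_mean) else NA,
    cross_cohort_naive_auc = results$cross_cohort_naive$auc %||% NA,
    cross_cohort_refined_auc = results$cross_cohort_refined$auc %||% NA
  )
  artifacts["summary"] <- stage_write(summary, config$out_dir, "summary.json")
  cfg_for_hash <- unclass(config); cfg_for_hash$out_dir <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("sehybrid")),
    seed = config$seed,
    config_hash = rlang::hash(cfg_for_hash),
    artifacts = as.list(basename(artifacts))
  )
  stage_write(manifest, config$out_dir, "manifest.json")
  invisible(results)
}
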