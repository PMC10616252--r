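# Rank-based AUC: probability a random HE score exceeds a random LE
# score, ties counting one half (Mann-Whitney statistic / (n1 n0)).
auc_rank <- function(scores, y) {
  y <- as_efficiency(y)
  n_pos <- sum(y == "HE")
  n_neg <- sum(y == "LE")
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == "HE"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Feature recipe: how to turn a cohort into a model matrix
#'
#' Records the exact transformation applied at training time — the
#' genus subset (in order), the one-hot encoding spec (or `NULL` when
#' host metadata is not used) and the normalization flag — so the
#' identical columns can be rebuilt for any new batch or cohort.
#' Genus columns absent from a target table are zero-filled with a
#' logged notice; extra genera are ignored.
#'
#' @param genera Character vector of genus columns, in column order.
#' @param encoding An [encoding_spec()] or `NULL` for microbes-only.
#' @param normalize Per-row L2 normalization flag.
#' @return An object of class `se_recipe`.
#' @export
feature_recipe <- function(genera, encoding = encoding_spec(), normalize = TRUE) {
  structure(list(genera = genera, encoding = encoding, normalize = normalize),
            class = "se_recipe")
}

#' Apply a feature recipe to an abundance table (+ metadata)
#'
#' @param recipe An `se_recipe`.
#' @param abundance Abundance tibble.
#' @param metadata Metadata tibble (required when the recipe encodes
#'   host variables).
#' @return Feature tibble with exactly the recipe's columns.
#' @export
apply_recipe <- function(recipe, abundance, metadata = NULL) {
  missing_g <- setdiff(recipe$genera, names(abundance))
  if (length(missing_g)) {
    inform(paste0("zero-filling genera absent from target: ",
                  paste(missing_g, collapse = ", ")))
    for (g in missing_g) abundance[[g]] <- 0
  }
  microbial <- abundance[c("sample_id", recipe$genera)]
  if (is.null(recipe$encoding)) {
    m <- feature_matrix(microbial)
    if (recipe$normalize) m <- l2_normalize_rows(m)
    out <- matrix_to_tbl(m)
    attr(out, "normalized") <- recipe$normalize
    return(out)
  }
  if (is.null(metadata)) abort("recipe encodes host variables: metadata is required")
  metadata <- metadata[match(microbial$sample_id, metadata$sample_id), ]
  if (any(is.na(metadata$sample_id))) abort("metadata lacks rows for some abundance samples")
  fuse_and_normalize(microbial, one_hot_encode(metadata, recipe$encoding),
                     normalize = recipe$normalize)
}

default_search_space <- function() {
  expand.grid(max_depth = c(2, 4), eta = c(0.1, 0.3), nrounds = c(50, 150),
              lambda = c(1, 10), KEEP.OUT.ATTRS = FALSE)
}

#' Tune and train the efficiency classifier
#'
#' Grid search over a small hyperparameter space (tree depth, learning
#' rate, boosting rounds, L2 penalty) scored by mean k-fold
#' cross-validated AUC; the best configuration is refit on all data.
#' Fold assignment and every other random draw derive from `seed`, so
#' the selected configuration and the fitted model are deterministic.
#'
#' @param data Feature tibble (`sample_id` + numeric columns), e.g.
#'   from [apply_recipe()] or [fuse_and_normalize()].
#' @param y LE/HE labels, one per row.
#' @param search_space Data frame of candidate configurations with
#'   columns among `max_depth`, `eta`, `nrounds`, `lambda`,
#'   `subsample`; default a 16-point grid.
#' @param cv_folds Number of CV folds (default 5).
#' @param recipe Optional `se_recipe` stored for transfer/calibration.
#' @param source_data Optional list(abundance, metadata, labels) of the
#'   training cohort, stored for [cross_cohort_refine()].
#' @param seed Integer seed.
#' @return An object of class `se_model`.
#' @export
tune_and_train <- function(data, y, search_space = default_search_space(),
                           cv_folds = 5, recipe = NULL, source_data = NULL,
                           seed = 1L) {
  y <- as_efficiency(y)
  if (nlevels(droplevels(y)) < 2) abort("both classes must be present in y")
  if (cv_folds < 2) abort("cv_folds must be >= 2")
  X <- feature_matrix(data)
  if (all(apply(X, 2, function(v) length(unique(v)) == 1))) {
    warn("all feature columns are constant; model will be uninformative")
  }
  seed <- as.integer(seed)
  res <- withr::with_seed(seed, {
    fold <- make_folds(y, cv_folds)
    scores <- vapply(seq_len(nrow(search_space)), function(i) {
      cfg <- as.list(search_space[i, , drop = FALSE])
      cv_auc(X, y, cfg, cfg$nrounds %||% 100, fold)
    }, numeric(1))
    list(fold = fold, scores = scores)
  })
  best_i <- which.max(res$scores)
  best <- as.list(search_space[best_i, , drop = FALSE])
  nrounds <- best$nrounds %||% 100
  booster <- withr::with_seed(seed, fit_xgb(X, as.integer(y) - 1L, best, nrounds))
  train_pred <- predict_xgb(booster, X)
  structure(list(
    booster = booster,
    features = colnames(X),
    params = best, nrounds = nrounds,
    cv_auc = res$scores[best_i], cv_auc_all = res$scores,
    train_X = X, train_y = y, train_pred = train_pred,
    recipe = recipe, source_data = source_data,
    seed = seed
  ), class = "se_model")
}

#' @export
print.se_model <- function(x, ...) {
  cat(sprintf("<se_model> %d features; CV AUC %.3f; depth %d, eta %g, %d rounds, lambda %g\n",
              length(x$features), x$cv_auc, x$params$max_depth, x$params$eta,
              x$nrounds, x$params$lambda %||% 1))
  invisible(x)
}

#' Evaluate a classifier by ROC AUC
#'
#' Scores the test samples and computes the area under the ROC curve
#' by the rank (Mann-Whitney) definition: the probability that a
#' random HE sample scores above a random LE sample, ties counting
#' one half. A single-class test set leaves the AUC undefined (`NA`,
#' flagged) rather than erroring.
#'
#' @param model An `se_model`.
#' @param data Feature tibble with the model's columns.
#' @param y LE/HE labels for `data`.
#' @return An `se_eval` list: `auc`, per-sample `scores` tibble,
#'   `class_counts`, `flag`.
#' @export
evaluate_auc <- function(model, data, y) {
  y <- as_efficiency(y)
  X <- feature_matrix(data)[, model$features, drop = FALSE]
  s <- predict_xgb(model$booster, X)
  auc <- auc_rank(s, y)
  flag <- if (is.na(auc)) "single-class test set: AUC undefined" else NA_character_
  if (!is.na(flag)) warn(flag)
  structure(list(
    auc = auc,
    scores = tibble::tibble(sample_id = rownames(X), score = s, label = y),
    class_counts = table(y), flag = flag
  ), class = "se_eval")
}

#' @export
print.se_eval <- function(x, ...) {
  cat(sprintf("<se_eval> AUC = %s on %d samples (%s)\n",
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)),
              nrow(x$scores),
              paste(names(x$class_counts), x$class_counts, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Apply a trained model to a new batch or cohort
#'
#' Rebuilds the model's feature columns on the target cohort via its
#' stored recipe (zero-filling genera the target lacks) and evaluates
#' the AUC — the "direct transfer" baseline that batch and region
#' effects degrade.
#'
#' @param model An `se_model` carrying a recipe.
#' @param abundance Target abundance tibble.
#' @param metadata Target metadata tibble.
#' @param labels Optional LE/HE labels; derived from the metadata's
#'   selenium columns at the 10% threshold when omitted.
#' @return An `se_eval`.
#' @export
transfer_evaluate <- function(model, abundance, metadata, labels = NULL) {
  if (is.null(model$recipe)) abort("model has no feature recipe; train with recipe =")
  if (is.null(labels)) {
    metadata <- derive_absorption_labels(metadata)
    labels <- metadata$efficiency
  }
  feats <- apply_recipe(model$recipe, abundance, metadata)
  evaluate_auc(model, feats, labels)
}

#' Hybrid cross-batch calibration curve
#'
#' Mixes `n` randomly chosen new-batch samples into the base training
#' data, retrains the classifier with the base model's hyperparameters
#' (no re-tuning, so the curve is attributable to data mixing alone),
#' and evaluates on held-out new-batch samples. Per repeat the test
#' set (`test_fraction` of the new batch) is drawn first, then each
#' `n` draws its calibration samples from the remainder; calibration
#' and test sets are disjoint by construction and asserted so. Results
#' are aggregated as mean and sd of AUC over repeats.
#'
#' @param model Base `se_model` (with recipe).
#' @param abundance,metadata The new batch.
#' @param labels Optional LE/HE labels (derived when omitted).
#' @param n_mix Numbers of new-batch samples to mix in (default
#'   5, 10, ..., 30). `0` is allowed and reproduces direct transfer.
#' @param test_fraction Held-out fraction of the new batch (default 0.3).
#' @param n_repeats Randomization repeats (default 5).
#' @param seed Integer seed.
#' @return Tibble of class `se_calibration`: `n_mixed`, `auc_mean`,
#'   `auc_sd`, `n_repeats`; per-draw detail in attribute `draws`.
#' @export
calibrate_hybrid <- function(model, abundance, metadata, labels = NULL,
                             n_mix = seq(5, 30, by = 5), test_fraction = 0.3,
                             n_repeats = 5, seed = 1L) {
  if (is.null(model$recipe)) abort("model has no feature recipe")
  if (is.null(labels)) {
    metadata <- derive_absorption_labels(metadata)
    labels <- metadata$efficiency
  }
  y_new <- as_efficiency(labels)
  if (nlevels(droplevels(y_new)) < 2) abort("both classes must be present in the new batch")
  X_new <- feature_matrix(apply_recipe(model$recipe, abundance, metadata))[, model$features, drop = FALSE]
  n <- nrow(X_new)
  n_test <- max(1L, floor(test_fraction * n))
  n_avail <- n - n_test
  usable <- n_mix[n_mix <= n_avail]
  skipped <- setdiff(n_mix, usable)
  if (length(skipped)) {
    warn(paste0("n_mix values exceeding the available remainder skipped: ",
                paste(skipped, collapse = ", ")))
  }
  if (!length(usable)) abort("no usable n_mix value: all exceed the available remainder")
  usable <- sort(usable)

  draws <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(n_repeats), function(r) {
      test_idx <- sample.int(n, n_test)
      rest <- setdiff(seq_len(n), test_idx)
      purrr::map_dfr(usable, function(nm) {
        calib_idx <- if (nm > 0) sample(rest, nm) else integer(0)
        stopifnot(length(intersect(calib_idx, test_idx)) == 0)
        Xtr <- rbind(model$train_X, X_new[calib_idx, , drop = FALSE])
        ytr <- factor(c(as.character(model$train_y), as.character(y_new[calib_idx])),
                      levels = c("LE", "HE"))
        bst <- fit_xgb(Xtr, as.integer(ytr) - 1L, model$params, model$nrounds)
        auc <- auc_rank(predict_xgb(bst, X_new[test_idx, , drop = FALSE]), y_new[test_idx])
        tibble::tibble(repeat_id = r, n_mixed = nm, auc = auc,
                       test_idx = list(sort(test_idx)), calib_idx = list(sort(calib_idx)))
      })
    })
  })
  out <- draws |>
    dplyr::group_by(.data$n_mixed) |>
    dplyr::summarise(auc_mean = mean(.data$auc, na.rm = TRUE),
                     auc_sd = stats::sd(.data$auc, na.rm = TRUE),
                     n_repeats = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$n_mixed)
  attr(out, "draws") <- draws
  attr(out, "test_fraction") <- test_fraction
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("se_calibration", class(out))
  out
}

#' Cross-cohort model refinement on shared biomarkers
#'
#' Rebuilds the base model keeping only the region-stable shared genus
#' features (host metadata is still encoded and fused), retrains on
#' the base cohort with the base hyperparameters, and evaluates on the
#' target cohort. This is the shared-feature screening step that
#' rescues transfer across regions when most biomarkers are
#' region-specific.
#'
#' @param model Base `se_model` trained with `source_data`.
#' @param shared_genera Non-empty character vector of shared genus
#'   names (see [shared_biomarkers()]), all present in the base cohort.
#' @param abundance,metadata The target cohort.
#' @param labels Optional LE/HE labels (derived when omitted).
#' @param seed Integer seed for the refit.
#' @return A list with the refined `model` (`se_model`) and its target
#'   `evaluation` (`se_eval`).
#' @export
cross_cohort_refine <- function(model, shared_genera, abundance, metadata,
                                labels = NULL, seed = model$seed) {
  if (!length(shared_genera)) {
    abort("shared_genera is empty; compute it with shared_biomarkers()")
  }
  src <- model$source_data
  if (is.null(src)) abort("model was trained without source_data; cannot rebuild features")
  absent <- setdiff(shared_genera, genus_columns(src$abundance))
  if (length(absent)) {
    abort(paste0("shared genera absent from the base cohort: ", paste(absent, collapse = ", ")))
  }
  recipe <- feature_recipe(shared_genera, encoding = model$recipe$encoding,
                           normalize = model$recipe$normalize)
  X_base <- apply_recipe(recipe, src$abundance, src$metadata)
  refined <- tune_and_train(X_base, src$labels,
                            search_space = as.data.frame(model$params),
                            cv_folds = 2, recipe = recipe, source_data = src,
                            seed = seed)
  eval <- transfer_evaluate(refined, abundance, metadata, labels = labels)
  list(model = refined, evaluation = eval)
}
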