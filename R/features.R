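#' One-hot encoding specification for host variables
#'
#' Fixes the category lists, bin edges and column order used to encode
#' host metadata as binary indicator vectors. Defaults follow the
#' standard clinical discretisation: gender Male/Female; age Young
#' (<= 35) / Middle (36-59) / Old (>= 60); BMI Low (< 18.5) / Middle
#' (18.5-23.9) / High (>= 24); probiotics yes/no; health status
#' healthy/unhealthy. Bins partition the real line with no gaps:
#' BMI values in (23.9, 24) fall in Middle, i.e. Middle is [18.5, 24).
#'
#' @param variables Character vector of variables to encode, in column
#'   order.
#' @param health_status_levels Category list for `health_status`.
#' @return An object of class `se_encoding`.
#' @export
encoding_spec <- function(variables = c("gender", "age", "bmi", "probiotics", "health_status"),
                          health_status_levels = c("healthy", "unhealthy")) {
  cats <- host_variable_categories()
  cats$health_status <- health_status_levels
  unknown <- setdiff(variables, names(cats))
  if (length(unknown)) abort(paste0("unknown variables: ", paste(unknown, collapse = ", ")))
  structure(list(variables = variables, categories = cats[variables]),
            class = "se_encoding")
}

# Age bins: Young <= 35, Middle 36-59 (continuous reading [36, 60), via
# (35, 60) for non-integer ages), Old >= 60.
bin_age <- function(age) {
  if (any(is.na(age) | age <= 0)) abort("age must be positive and non-missing")
  ifelse(age <= 35, "Young", ifelse(age < 60, "Middle", "Old"))
}

# BMI bins: Low < 18.5, Middle [18.5, 24), High >= 24.
bin_bmi <- function(bmi) {
  if (any(is.na(bmi) | bmi <= 0)) abort("bmi must be positive and non-missing")
  ifelse(bmi < 18.5, "Low", ifelse(bmi < 24, "Middle", "High"))
}

#' One-hot encode host metadata
#'
#' Each variable becomes a block of binary indicator columns, one per
#' category, with exactly one active bit per sample: Male -> (1, 0),
#' Female -> (0, 1); age 36 -> (0, 1, 0); and so on. Continuous age and
#' BMI are binned first (see [encoding_spec()]). Column order is fixed
#' by the spec, so encodings from different cohorts are column-
#' compatible by construction.
#'
#' @param meta Metadata tibble.
#' @param spec An `se_encoding` from [encoding_spec()].
#' @return Tibble: `sample_id` + indicator columns named
#'   `<variable>_<category>`.
#' @export
one_hot_encode <- function(meta, spec = encoding_spec()) {
  blocks <- lapply(spec$variables, function(v) {
    if (!v %in% names(meta)) abort(paste0("metadata lacks variable: ", v))
    val <- meta[[v]]
    if (v == "age") val <- bin_age(val)
    if (v == "bmi") val <- bin_bmi(val)
    cats <- spec$categories[[v]]
    bad <- !val %in% cats
    if (any(bad)) {
      abort(sprintf("unmappable %s value '%s' for sample %s",
                    v, val[bad][1], meta$sample_id[bad][1]))
    }
    m <- outer(val, cats, "==") * 1
    colnames(m) <- paste(v, cats, sep = "_")
    m
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- meta$sample_id
  matrix_to_tbl(out)
}

fit_xgb <- function(X, y01, params, nrounds) {
  defaults <- list(objective = "binary:logistic", eval_metric = "auc",
                   max_depth = 4, eta = 0.3, lambda = 1,
                   subsample = 1, colsample_bytree = 1, nthread = 1)
  params <- modifyList(defaults, params[setdiff(names(params), "nrounds")])
  dm <- xgboost::xgb.DMatrix(X, label = y01)
  xgboost::xgb.train(params = params, data = dm, nrounds = nrounds, verbose = 0)
}

predict_xgb <- function(booster, X) {
  predict(booster, xgboost::xgb.DMatrix(X))
}

#' Rank genus features by classifier importance
#'
#' Fits a gradient-boosted decision-tree ensemble on all features and
#' ranks them by their weight-importance score: the number of tree
#' splits using each feature (the split-count "weight" metric;
#' gain-based importance is available via `importance = "gain"`).
#' Features never used in a split receive a score of zero; ties are
#' broken lexicographically by feature name, so the ranking is
#' deterministic given the seed.
#'
#' @param data Feature tibble: `sample_id` + numeric feature columns.
#' @param y LE/HE labels, one per row of `data`.
#' @param hyperparams Named list of xgboost parameters (plus optional
#'   `nrounds`, default 100) overriding the defaults.
#' @param importance `"weight"` (split counts, default) or `"gain"`.
#' @param seed Integer seed.
#' @return Tibble of class `se_ranking`: `feature`, `importance`,
#'   `rank`, with provenance attributes.
#' @export
rank_features <- function(data, y, hyperparams = list(), importance = c("weight", "gain"),
                          seed = 1L) {
  importance <- match.arg(importance)
  y <- as_efficiency(y)
  if (nlevels(droplevels(y)) < 2) abort("both classes must be present in y")
  if (nrow(data) < 10) abort("need at least 10 samples to rank features")
  X <- feature_matrix(data)
  nrounds <- hyperparams$nrounds %||% 100
  bst <- withr::with_seed(as.integer(seed),
                          fit_xgb(X, as.integer(y) - 1L, hyperparams, nrounds))
  imp <- xgboost::xgb.importance(model = bst)
  score <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (!is.null(imp) && nrow(imp)) {
    col <- if (importance == "weight") imp$Frequency else imp$Gain
    score[imp$Feature] <- col
  }
  ord <- order(-score, names(score))
  out <- tibble::tibble(feature = names(score)[ord],
                        importance = unname(score[ord]),
                        rank = seq_along(score))
  attr(out, "provenance") <- list(seed = as.integer(seed), importance = importance,
                                  hyperparams = hyperparams, n_samples = nrow(X))
  class(out) <- c("se_ranking", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stratified fold assignment; reduces fold count with a warning when a
# class has fewer members than requested folds.
make_folds <- function(y, cv_folds) {
  min_class <- min(table(y))
  if (cv_folds > min_class) {
    warn(sprintf("cv_folds reduced from %d to %d (smallest class size)", cv_folds, min_class))
    cv_folds <- min_class
  }
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    fold[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
  }
  fold
}

# Mean cross-validated AUC for a fixed feature matrix and parameters.
cv_auc <- function(X, y, params, nrounds, fold) {
  k <- max(fold)
  aucs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    bst <- fit_xgb(X[tr, , drop = FALSE], as.integer(y[tr]) - 1L, params, nrounds)
    auc_rank(predict_xgb(bst, X[!tr, , drop = FALSE]), y[!tr])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Learning curve over top-k feature subsets
#'
#' For each `k`, retrains the classifier on the top-k ranked features
#' and reports the mean cross-validated AUC, tracing how performance
#' saturates as features are added in importance order. Fold
#' assignment is drawn once from the seed and shared across all `k`,
#' so the curve's variation is attributable to the feature subset
#' alone (and `k = `#features reproduces the all-feature CV AUC).
#'
#' @param ranking An `se_ranking` from [rank_features()].
#' @param data Feature tibble used to build the ranking.
#' @param y LE/HE labels.
#' @param k_values Feature-subset sizes to evaluate.
#' @param cv_folds Number of CV folds (default 5).
#' @param hyperparams xgboost parameter overrides (as in
#'   [rank_features()]).
#' @param seed Integer seed.
#' @return Tibble of class `se_learning_curve`: `k`, `mean_auc`.
#' @export
learning_curve <- function(ranking, data, y, k_values = seq_along(ranking$feature),
                           cv_folds = 5, hyperparams = list(), seed = 1L) {
  y <- as_efficiency(y)
  X <- feature_matrix(data)
  if (any(k_values < 1 | k_values > nrow(ranking))) {
    abort("k_values must lie in [1, number of ranked features]")
  }
  nrounds <- hyperparams$nrounds %||% 100
  withr::with_seed(as.integer(seed), {
    fold <- make_folds(y, cv_folds)
    out <- tibble::tibble(
      k = as.integer(k_values),
      mean_auc = vapply(k_values, function(k) {
        feats <- ranking$feature[seq_len(k)]
        cv_auc(X[, feats, drop = FALSE], y, hyperparams, nrounds, fold)
      }, numeric(1))
    )
  })
  class(out) <- c("se_learning_curve", class(out))
  out
}

#' Select the top-k biomarkers from a ranking
#'
#' @param ranking An `se_ranking`.
#' @param k Number of biomarkers to keep (default 10, the point where
#'   the learning curve typically plateaus).
#' @return Character vector of the top-k feature names, in rank order.
#' @export
select_biomarkers <- function(ranking, k = 10) {
  if (k <= 0) abort("k must be positive")
  if (k > nrow(ranking)) abort("k exceeds the number of ranked features")
  ranking$feature[seq_len(k)]
}

#' Fuse microbial and encoded host features with row L2 normalization
#'
#' Horizontally concatenates the biomarker abundance columns (first)
#' with the one-hot metadata columns, then scales each row to unit
#' Euclidean norm. All-zero rows are left as zeros and flagged with a
#' warning. Both inputs must list samples in the same order.
#'
#' @param microbial Feature tibble of biomarker abundances.
#' @param encoded One-hot tibble from [one_hot_encode()].
#' @param normalize Apply the per-row L2 normalization (default TRUE).
#' @return Feature tibble (`sample_id` + fused columns) with attribute
#'   `normalized`.
#' @export
fuse_and_normalize <- function(microbial, encoded, normalize = TRUE) {
  if (!identical(microbial$sample_id, encoded$sample_id)) {
    abort("sample order differs between microbial and encoded tables")
  }
  m <- cbind(feature_matrix(microbial), feature_matrix(encoded))
  if (normalize) {
    m <- l2_normalize_rows(m)
    zero <- attr(m, "zero_rows")
    if (length(zero)) warn(paste0("all-zero rows left unnormalized: ", paste(zero, collapse = ", ")))
  }
  out <- matrix_to_tbl(m)
  attr(out, "normalized") <- normalize
  out
}

#' Biomarkers shared across batches or cohorts
#'
#' Intersects the top-k sets of several rankings — the Venn-diagram
#' core of cross-cohort feature screening. An empty intersection is a
#' legitimate outcome and returns an empty set with a warning.
#'
#' @param rankings A list of two or more `se_ranking` objects.
#' @param k Top-k cutoff applied to each ranking (default 10).
#' @return Character vector of shared feature names (lexicographic).
#' @export
shared_biomarkers <- function(rankings, k = 10) {
  if (length(rankings) < 2) abort("need at least two rankings")
  sets <- lapply(rankings, select_biomarkers, k = k)
  shared <- sort(Reduce(intersect, sets))
  if (!length(shared)) warn("no biomarker shared by every ranking")
  shared
}
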