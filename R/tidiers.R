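#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted efficiency model
#'
#' One row per feature with its split-count (weight) and gain
#' importance in the fitted ensemble.
#'
#' @param x An `se_model`.
#' @param ... Ignored.
#' @return A tibble: `feature`, `weight`, `gain`.
#' @export
#' @exportS3Method generics::tidy
tidy.se_model <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  out <- tibble::tibble(feature = x$features, weight = 0, gain = 0)
  if (!is.null(imp) && nrow(imp)) {
    i <- match(imp$Feature, out$feature)
    out$weight[i] <- imp$Frequency
    out$gain[i] <- imp$Gain
  }
  dplyr::arrange(out, dplyr::desc(.data$weight), .data$feature)
}

#' @rdname tidy.se_model
#' @return For `glance()`: a one-row tibble of hyperparameters and CV
#'   performance.
#' @export
#' @exportS3Method generics::glance
glance.se_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$features),
    max_depth = x$params$max_depth, eta = x$params$eta,
    nrounds = x$nrounds, lambda = x$params$lambda %||% 1,
    cv_auc = x$cv_auc,
    train_auc = auc_rank(x$train_pred, x$train_y)
  )
}

#' Tidy an evaluation report
#'
#' @param x An `se_eval`.
#' @param ... Ignored.
#' @return For `tidy()`: the per-sample score tibble; for `glance()`:
#'   a one-row tibble with `auc`, class counts and the degeneracy flag.
#' @export
#' @exportS3Method generics::tidy
tidy.se_eval <- function(x, ...) x$scores

#' @rdname tidy.se_eval
#' @export
#' @exportS3Method generics::glance
glance.se_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc,
                 n_le = as.integer(x$class_counts[["LE"]]),
                 n_he = as.integer(x$class_counts[["HE"]]),
                 flag = x$flag)
}
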