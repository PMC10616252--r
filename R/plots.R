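#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_ribbon labs theme_minimal coord_flip
NULL

#' Plot a hybrid-calibration curve
#'
#' Mean test AUC (with a +/- 1 sd ribbon) against the number of
#' new-batch samples mixed into training.
#'
#' @param object An `se_calibration` from [calibrate_hybrid()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.se_calibration <- function(object, ...) {
  ggplot(object, aes(x = .data$n_mixed, y = .data$auc_mean)) +
    geom_ribbon(aes(ymin = .data$auc_mean - .data$auc_sd,
                    ymax = .data$auc_mean + .data$auc_sd), alpha = 0.2) +
    geom_line() + geom_point() +
    labs(x = "new-batch samples mixed into training", y = "mean test AUC",
         title = "Hybrid cross-batch calibration") +
    theme_minimal()
}

#' Plot a feature-refinement learning curve
#'
#' @param object An `se_learning_curve` from [learning_curve()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.se_learning_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$k, y = .data$mean_auc)) +
    geom_line() + geom_point() +
    labs(x = "top-k features", y = "mean CV AUC",
         title = "Learning curve over ranked features") +
    theme_minimal()
}

#' Plot host-variable effect sizes on community composition
#'
#' PERMANOVA R-squared per variable, largest first.
#'
#' @param object An `se_effect_scan` from [effect_size_scan()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.se_effect_scan <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      variable = stats::reorder(.data$variable, .data$r_squared))
  ggplot(df, aes(x = .data$variable, y = .data$r_squared)) +
    geom_col() + coord_flip() +
    labs(x = NULL, y = expression(PERMANOVA ~ R^2),
         title = "Effect sizes of host variables") +
    theme_minimal()
}
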