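# ggplot2 visualizations for the main result types.

#' @export
autoplot.stabcast_relevance <- function(object, n_top = 10, ...) {
  top <- head(object, n_top)
  ggplot2::ggplot(top, ggplot2::aes(
    x = .data$relevance,
    y = stats::reorder(.data$feature, .data$relevance)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "standardized relevance", y = NULL,
      title = "KL-divergence feature relevance",
      subtitle = paste0("top ", min(n_top, nrow(object)), " of ",
                        nrow(object), " features; mass = ",
                        round(sum(top$relevance), 3))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.stabcast_feature_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve, c("mae", "rsq"),
                              names_to = "metric")
  ggplot2::ggplot(dplyr::filter(long, !.data$failed),
                  ggplot2::aes(.data$k, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(mae = "MAE", rsq = "R²"))) +
    ggplot2::labs(x = "number of features (by decreasing relevance)",
                  y = NULL,
                  title = "Validation performance vs feature count") +
    ggplot2::theme_minimal()
}

#' Parity plot of predicted vs measured stability constants
#'
#' @param truth Measured log10 beta values.
#' @param pred Prediction tibble with `.pred` and `.pred_std` (as returned
#'   by the `predict()` methods); error bars show the 1-sigma uncertainty.
#' @return A ggplot object.
#' @export
plot_parity <- function(truth, pred) {
  stopifnot(length(truth) == nrow(pred))
  mu <- pred[[".pred"]]
  sd1 <- pred[[".pred_std"]]
  df <- tibble(truth = truth, pred = mu, std = sd1)
  ev <- evaluate_predictions(df$truth, df$pred)
  ggplot2::ggplot(df, ggplot2::aes(.data$truth, .data$pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$pred - .data$std,
                                        ymax = .data$pred + .data$std),
                           width = 0, colour = "grey40", alpha = 0.5) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = expression(measured ~ log[10] ~ beta),
      y = expression(predicted ~ log[10] ~ beta),
      title = sprintf("Parity plot (MAE = %.2f, R² = %.2f)",
                      ev$mae, ev$rsq)
    ) +
    ggplot2::theme_minimal()
}
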