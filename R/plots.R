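#' Plot the diurnal profile of an hourly series
#'
#' Hour-of-day boxplots, the standard way to look at ED arrival and
#' occupancy seasonality; an optional horizontal line marks the crowding
#' threshold.
#'
#' @param series An hourly series.
#' @param threshold Optional crowding threshold to draw.
#' @return A ggplot object.
#' @export
plot_diurnal <- function(series, threshold = NULL) {
  df <- as_hourly_series(series) |>
    dplyr::mutate(hour = factor(lubridate::hour(.data$timestamp),
                                levels = 0:23))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "grey85") +
    ggplot2::labs(x = "hour of day", y = "value") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot performance per horizon
#'
#' @param pph_tbl Output of [pph()].
#' @return A ggplot object: AUC against horizon with CI ribbons per model.
#' @export
plot_pph <- function(pph_tbl) {
  ggplot2::ggplot(pph_tbl,
                  ggplot2::aes(x = .data$horizon, y = .data$auc,
                               colour = .data$model_id,
                               fill = .data$model_id)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "forecast horizon (h)", y = "AUC",
                  colour = "model", fill = "model") +
    ggplot2::theme_minimal()
}

#' Plot performance per origin
#'
#' @param ppo_tbl Output of [ppo()].
#' @return A ggplot object: AUC against origin hour of day with CI
#'   ribbons per model.
#' @export
plot_ppo <- function(ppo_tbl) {
  ggplot2::ggplot(ppo_tbl,
                  ggplot2::aes(x = .data$origin_hour, y = .data$auc,
                               colour = .data$model_id,
                               fill = .data$model_id)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "forecast origin (hour of day)", y = "AUC",
                  colour = "model", fill = "model") +
    ggplot2::theme_minimal()
}

#' Plot the origin-by-horizon AUC matrix
#'
#' @param matrix_tbl Output of [auc_matrix()] (one model).
#' @return A ggplot tile plot; undefined cells are blank.
#' @export
plot_auc_matrix <- function(matrix_tbl) {
  ggplot2::ggplot(matrix_tbl,
                  ggplot2::aes(x = .data$horizon, y = .data$origin_hour,
                               fill = .data$auc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "white") +
    ggplot2::scale_y_reverse(breaks = 0:23) +
    ggplot2::labs(x = "horizon (h)", y = "origin (hour of day)",
                  fill = "AUC") +
    ggplot2::theme_minimal()
}
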