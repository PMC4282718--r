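#' Heatmap of the ordered genetic correlation matrix
#'
#' @param object A `met_ordered_correlation` from [order_correlation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.met_ordered_correlation <- function(object, ...) {
  C <- object$correlation
  df <- tibble::as_tibble(C, rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "correlation")
  df$row <- factor(df$row, levels = rev(rownames(C)))
  df$col <- factor(df$col, levels = colnames(C))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Between-environment genetic correlations",
                  subtitle = "dendrogram ordering") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_text(size = 6),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Latent regression plot for one variety and factor
#'
#' Points show the (partial) regression component against the rotated
#' loadings, coloured by whether the variety was grown in the environment;
#' the line through the origin has slope equal to the variety's rotated
#' score.
#'
#' @param object A `met_latent_regression` from [latent_regression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.met_latent_regression <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$x, .data$y, colour = .data$observed)) +
    ggplot2::geom_abline(intercept = 0, slope = object$slope) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                            `FALSE` = "#b2182b"),
                                 labels = c(`TRUE` = "grown",
                                            `FALSE` = "not grown"),
                                 name = NULL) +
    ggplot2::labs(
      x = sprintf("factor %d loading (t/ha)", object$factor_index),
      y = "partial regression component (t/ha)",
      title = sprintf("%s, factor %d (slope %.2f)", object$variety,
                      object$factor_index, object$slope)
    ) +
    ggplot2::theme_minimal()
}

#' Environment prediction panel plot
#'
#' One panel per trial-site location; predicted genetic values by year for
#' each variety, with standard error bars, solid/hollow points for grown /
#' not grown.
#'
#' @param object A `met_environment_panel` from [environment_panel()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.met_environment_panel <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$year), .data$prediction,
                                   colour = .data$variety,
                                   group = .data$variety)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$prediction - .data$se,
                                        ymax = .data$prediction + .data$se),
                           width = 0.15) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$observed)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                labels = c(`TRUE` = "grown",
                                           `FALSE` = "not grown"),
                                name = NULL) +
    ggplot2::facet_wrap(~location) +
    ggplot2::labs(x = "year", y = "predicted genetic value (t/ha)",
                  title = paste("Region", attr(object, "region"))) +
    ggplot2::theme_minimal()
}

#' Distribution of per-environment variance accounted for across FA orders
#'
#' @param object A `met_order_selection` from [select_order()].
#' @param ... Unused.
#' @return A ggplot object (boxplots of `v_j` per order, overall `v_bar`
#'   annotated).
#' @export
autoplot.met_order_selection <- function(object, ...) {
  df <- purrr::imap(object$fits, function(f, k) {
    ve <- variance_explained(f)
    dplyr::mutate(ve$v, order = paste0("FA", k), v_bar = ve$v_bar)
  }) |>
    dplyr::bind_rows()
  labs <- df |>
    dplyr::distinct(.data$order, .data$v_bar) |>
    dplyr::mutate(label = sprintf("(%.0f)", .data$v_bar))
  ggplot2::ggplot(df, ggplot2::aes(.data$order, .data$v)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_text(data = labs, y = 102,
                       ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::labs(x = NULL, y = "% genetic variance accounted for") +
    ggplot2::theme_minimal()
}
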