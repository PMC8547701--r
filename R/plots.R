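# ggplot2 displays for the main result types

#' Plot per-family age histograms
#'
#' Copy counts in 10,000-year bins, one panel per superfamily, families as
#' stacked series.
#'
#' @param hist Tibble from [family_age_histogram()].
#' @param max_age Right edge in years (default 2e6).
#' @return A ggplot object.
#' @export
plot_age_histogram <- function(hist, max_age = 2e6) {
  hist %>%
    filter(.data$bin_start < max_age) %>%
    mutate(superfamily = str_sub(.data$family_id, 1, 3)) %>%
    ggplot2::ggplot(ggplot2::aes(
      x = .data$bin_start / 1000, y = .data$n, fill = .data$family_id
    )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~superfamily, scales = "free_y") +
    ggplot2::labs(x = "age (kya, 10 ky bins)", y = "insertions") +
    ggplot2::theme_minimal()
}

#' Plot methylation metaprofiles
#'
#' Mean profile value per slot (-20 upstream windows, TE body, +20
#' downstream windows), faceted by context, coloured by tissue.
#'
#' @param profiles Long profile tibble from [te_methylation_profile()].
#' @return A ggplot object.
#' @export
plot_methylation_profile <- function(profiles) {
  profiles %>%
    group_by(.data$tissue, .data$context, .data$slot) %>%
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") %>%
    ggplot2::ggplot(ggplot2::aes(
      x = .data$slot, y = .data$value, colour = .data$tissue
    )) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~context) +
    ggplot2::labs(
      x = "position (100 bp windows; 0 = TE body)",
      y = "methylated / covered cytosines"
    ) +
    ggplot2::theme_minimal()
}

#' Plot permutation importance
#'
#' @param x A `te_importance`.
#' @param object,... For the autoplot method.
#' @param top_n Number of features shown (default 30).
#' @return A ggplot object.
#' @export
plot_importance <- function(x, top_n = 30) {
  stopifnot(inherits(x, "te_importance"))
  x$features %>%
    head(top_n) %>%
    mutate(feature = factor(.data$feature, levels = rev(.data$feature))) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$delta_rmse_kya, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "RMSE increase when permuted (kya)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_importance
#' @export
autoplot.te_importance <- function(object, ...) plot_importance(object, ...)

#' Plot ICE curves
#'
#' Individual per-copy deviation traces (thin lines) with per-superfamily
#' mean curves (thick lines).
#'
#' @param x A `te_ice`.
#' @param object,... For the autoplot method.
#' @param max_curves Number of individual curves drawn (default 200).
#' @return A ggplot object.
#' @export
plot_ice <- function(x, max_curves = 200) {
  stopifnot(inherits(x, "te_ice"))
  ids <- unique(x$curves$copy_id)
  show <- ids[seq_len(min(length(ids), max_curves))]
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = filter(x$curves, .data$copy_id %in% show),
      ggplot2::aes(x = .data$grid_value, y = .data$deviation,
                   group = .data$copy_id),
      alpha = 0.15
    ) +
    ggplot2::geom_line(
      data = x$group_means,
      ggplot2::aes(x = .data$grid_value, y = .data$mean_deviation,
                   colour = .data$superfamily),
      linewidth = 1.2
    ) +
    ggplot2::labs(
      x = x$feature,
      y = "predicted - observed age (years)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_ice
#' @export
autoplot.te_ice <- function(object, ...) plot_ice(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
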