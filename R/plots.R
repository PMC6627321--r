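# ggplot2 display helpers for the main result types.

#' Conservation profile plot
#'
#' Identity and occupancy per alignment column, with hot-spot runs shaded
#' when supplied.
#'
#' @param profiles Column profiles from [profile_columns()].
#' @param hotspots Optional `utr_hotspots` object.
#' @return A ggplot object.
#' @export
plot_conservation <- function(profiles, hotspots = NULL) {
  long <- tidyr::pivot_longer(
    profiles[, c("col", "identity_pct", "occupancy_pct")],
    cols = c("identity_pct", "occupancy_pct"),
    names_to = "score", values_to = "pct")
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$pct,
                                           colour = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "alignment column", y = "%", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(hotspots) && nrow(hotspots$runs)) {
    gg <- gg + ggplot2::geom_rect(
      data = hotspots$runs,
      ggplot2::aes(xmin = .data$start_col - 0.5, xmax = .data$end_col + 0.5),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "orange",
      inherit.aes = FALSE)
  }
  gg
}

#' @rdname plot_conservation
#' @param object A `utr_hotspots` object.
#' @param profiles_data Column profiles of the same alignment.
#' @param ... Unused.
#' @export
autoplot.utr_hotspots <- function(object, profiles_data, ...) {
  plot_conservation(profiles_data, object)
}

#' Sliding-window GC plot
#'
#' @param series Output of [gc_window_series()].
#' @param boundary Optional intron-1 offset to mark.
#' @return A ggplot object.
#' @export
plot_gc_windows <- function(series, boundary = NULL) {
  gg <- ggplot2::ggplot(series, ggplot2::aes(x = .data$center,
                                             y = .data$pct)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (window center)", y = "GC %") +
    ggplot2::theme_minimal()
  if (!is.null(boundary)) {
    gg <- gg + ggplot2::geom_vline(xintercept = boundary, linetype = 2)
  }
  gg
}

#' Group-wise section-length box plot
#'
#' @param lengths A `utr_lengths` object from [summarize_lengths()].
#' @param metric Which length metric to show (default "after").
#' @return A ggplot object.
#' @export
plot_section_lengths <- function(lengths, metric = "after") {
  dat <- filter(lengths$lengths, .data$metric == !!metric)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = sprintf("%s length (nt)", metric)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_section_lengths
#' @param object A `utr_lengths` object.
#' @param ... Passed on as the metric.
#' @export
autoplot.utr_lengths <- function(object, ...) {
  plot_section_lengths(object, ...)
}
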