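# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot component formation across the AS sweep
#'
#' Number of connected components against the alignment-score cut-off
#' (log10 scale, loosest cut-off on the left), the standard way to read
#' where sequence classes separate.
#'
#' @param object A `cdh_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cdh_sweep <- function(object, ...) {
  d <- glance(object)
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$cutoff),
                                  y = .data$n_components)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "log10 alignment-score cut-off",
                  y = "connected components",
                  title = "Cluster formation across AS cut-offs") +
    ggplot2::theme_minimal()
}

#' Plot a sequence logo
#'
#' Stacked-letter logo over the reference-defined columns: letter heights
#' are residue frequency times column information content (bits).
#'
#' @param object A `cdh_logo`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cdh_logo <- function(object, ...) {
  d <- object$columns |>
    dplyr::filter(!is.na(.data$residue)) |>
    dplyr::mutate(height = .data$freq * .data$info) |>
    dplyr::group_by(.data$position) |>
    dplyr::arrange(.data$height, .by_group = TRUE) |>
    dplyr::mutate(ymax = cumsum(.data$height),
                  ymid = .data$ymax - .data$height / 2) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$ymid,
                                  label = .data$residue,
                                  size = .data$height,
                                  colour = .data$residue)) +
    ggplot2::geom_text(fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(1, 8)) +
    ggplot2::labs(x = "reference position", y = "bits",
                  title = "Sequence logo (reference-anchored columns)") +
    ggplot2::theme_minimal()
}

#' Plot oxidized/reduced UV-Vis spectra
#'
#' Overlays the oxidized and reduced spectra and, when both are given,
#' the reduced-minus-oxidized difference spectrum (dashed).
#'
#' @param ox Oxidized spectrum tibble (`wavelength`, `absorbance`).
#' @param red Optional reduced spectrum tibble.
#' @return A ggplot.
#' @export
plot_spectra <- function(ox, red = NULL) {
  d <- dplyr::bind_rows(oxidized = ox, reduced = red, .id = "state")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$wavelength,
                                       y = .data$absorbance,
                                       colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "absorbance (AU)",
                  title = "UV-Vis spectra") +
    ggplot2::theme_minimal()
  if (!is.null(red)) {
    diff <- spectral_features(ox, red)$difference
    p <- p + ggplot2::geom_line(
      data = dplyr::mutate(diff, state = "difference"),
      linetype = "dashed")
  }
  p
}

#' Plot a purification table
#'
#' Yield and purification factor per step and assay, faceted by the
#' derived quantity.
#'
#' @param table Output of [purification_table()].
#' @return A ggplot.
#' @export
plot_purification <- function(table) {
  d <- table |>
    dplyr::select("step", "assay", "yield_pct", "purification_factor") |>
    tidyr::pivot_longer(c("yield_pct", "purification_factor"),
                        names_to = "quantity") |>
    dplyr::mutate(step = factor(.data$step, levels = unique(table$step)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$value,
                                  fill = .data$assay)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Purification summary") +
    ggplot2::theme_minimal()
}
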