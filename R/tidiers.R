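# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn build_network tidy(): the edge table as a tibble.
#' @param x A `cdh_network`.
#' @param ... Unused.
#' @export
tidy.cdh_network <- function(x, ...) {
  tibble::as_tibble(x$edges)
}

#' @describeIn build_network glance(): one-row summary (nodes, edges,
#'   threshold, components at the build threshold).
#' @export
glance.cdh_network <- function(x, ...) {
  comp <- components_at_cutoff(x, x$build_threshold)
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 build_threshold = x$build_threshold,
                 n_components = dplyr::n_distinct(comp$component))
}

#' @describeIn sweep_components tidy(): per-cutoff component membership.
#' @param x A `cdh_sweep`.
#' @param ... Unused.
#' @export
tidy.cdh_sweep <- function(x, ...) {
  tibble::as_tibble(x$components)
}

#' @describeIn sweep_components glance(): one row per cutoff with the
#'   component count.
#' @export
glance.cdh_sweep <- function(x, ...) {
  x$components |>
    dplyr::group_by(cutoff = .data$cutoff) |>
    dplyr::summarise(n_components = dplyr::n_distinct(.data$component),
                     largest = max(.data$component_size)) |>
    dplyr::arrange(dplyr::desc(.data$cutoff))
}

#' @describeIn build_logo tidy(): the long position/residue frequency
#'   table.
#' @param x A `cdh_logo`.
#' @param ... Unused.
#' @export
tidy.cdh_logo <- function(x, ...) {
  tibble::as_tibble(x$columns)
}
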