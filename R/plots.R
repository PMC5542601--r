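#' Plot indicator time series across scenarios
#'
#' One panel per haul plan (towing duration), one curve per layout pattern,
#' in the style of the fish-count / encircled-area / entry-width summary
#' figures.
#'
#' @param results A `seine_suite`, list of `seine_scenario` objects, or a
#'   single scenario.
#' @param which `"count"`, `"area"` or `"width"`.
#' @return A ggplot object.
#' @export
plot_indicators <- function(results, which = c("count", "area", "width")) {
  which <- match.arg(which)
  if (inherits(results, "seine_scenario")) results <- list(results)
  if (inherits(results, "seine_suite")) results <- results$results
  df <- dplyr::bind_rows(purrr::map(results, function(r) {
    dplyr::mutate(r$indicators,
                  pattern = r$summary$pattern,
                  tow_minutes = r$summary$tow_minutes)
  }))
  col <- switch(which, count = "fish_encircled", area = "area_m2",
                width = "entry_width_m")
  ylab <- switch(which, count = "fish encircled [count]",
                 area = expression("encircled area " * (m^2)),
                 width = "entry width [m]")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data[[col]],
                                   colour = .data$pattern)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~tow_minutes,
                        labeller = ggplot2::labeller(
                          tow_minutes = function(v) paste0(v, " min towing")),
                        ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "time [s]", y = ylab, colour = "layout") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an initial layout
#'
#' @param object A [make_layout()] object.
#' @param ... Unused.
#' @return A ggplot object showing the two ropes, vessel and net.
#' @export
autoplot.seine_layout <- function(object, ...) {
  v <- layout_vertices(object)
  pts <- tibble::tibble(
    what = c("vessel", "net"),
    x_m = c(object$vessel_position[1], object$net_position[1]),
    y_m = c(object$vessel_position[2], object$net_position[2])
  )
  ggplot2::ggplot(v, ggplot2::aes(.data$x_m, .data$y_m)) +
    ggplot2::geom_path(ggplot2::aes(group = .data$rope_id,
                                    colour = factor(.data$rope_id))) +
    ggplot2::geom_point(data = pts, ggplot2::aes(shape = .data$what), size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$pattern, x = "x [m]", y = "y [m]",
                  colour = "rope", shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the indicators of a single scenario
#'
#' @param object A `seine_scenario`.
#' @param ... Unused.
#' @return A ggplot object with the three indicator time series.
#' @export
autoplot.seine_scenario <- function(object, ...) {
  df <- tidyr::pivot_longer(object$indicators, -"t_s",
                            names_to = "indicator", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$t_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~indicator, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = "time [s]", y = NULL,
      title = sprintf("%s layout, %g min towing", object$summary$pattern,
                      object$summary$tow_minutes)
    ) +
    ggplot2::theme_minimal()
}
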