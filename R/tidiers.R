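#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a scenario result
#'
#' @param x A `seine_scenario`.
#' @param ... Unused.
#' @return The indicator time series as a tibble, with `pattern` and
#'   `tow_minutes` columns.
#' @export
tidy.seine_scenario <- function(x, ...) {
  dplyr::mutate(x$indicators, pattern = x$summary$pattern,
                tow_minutes = x$summary$tow_minutes, .before = 1)
}

#' @rdname tidy.seine_scenario
#' @export
glance.seine_scenario <- function(x, ...) x$summary

#' Tidy a scenario suite
#'
#' @param x A `seine_suite`.
#' @param ... Unused.
#' @return Bound indicator time series (tidy) or per-scenario summary rows
#'   (glance).
#' @export
tidy.seine_suite <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$results, tidy))
}

#' @rdname tidy.seine_suite
#' @export
glance.seine_suite <- function(x, ...) x$summary

#' Tidy a collection-phase result
#'
#' @param x A `collection_result`.
#' @param ... Unused.
#' @return Indicator time series (tidy) or the three summary instants
#'   (glance).
#' @export
tidy.collection_result <- function(x, ...) x$indicators

#' @rdname tidy.collection_result
#' @export
glance.collection_result <- function(x, ...) x$summary
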