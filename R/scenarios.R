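#' Configure a fishing scenario
#'
#' A scenario is a layout pattern plus a haul-in procedure plus the virtual
#' fish population, with all physical and behavioural parameters resolved.
#' The twelve reference scenarios are the four patterns crossed with 0, 15
#' and 35 minutes of towing.
#'
#' @param pattern Layout pattern name.
#' @param tow_minutes Towing-phase duration (minutes).
#' @param rope_length_each Rope length (m).
#' @param tow_speed,winch_speed Haul speeds (m/s).
#' @param fish_dens Fish density (fish per m^2).
#' @param placement Population placement, `"grid"` or `"uniform_random"`.
#' @param seed Integer seed used for population placement and the fish
#'   engine RNG streams.
#' @param dynamics A [dynamics_params()] object.
#' @param reaction A [reaction_params()] object (its seed is overridden by
#'   `seed`).
#' @param region_margin Padding (m) for the fishing-ground corridor.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(pattern = "square", tow_minutes = 15,
                            rope_length_each = 2000,
                            tow_speed = 1.0289, winch_speed = 0.9,
                            fish_dens = 0.01, placement = "grid", seed = 1L,
                            dynamics = dynamics_params(),
                            reaction = reaction_params(),
                            region_margin = 50) {
  reaction$seed <- as.integer(seed)
  structure(
    list(pattern = pattern, tow_minutes = tow_minutes,
         rope_length_each = rope_length_each, tow_speed = tow_speed,
         winch_speed = winch_speed, fish_dens = fish_dens,
         placement = placement, seed = as.integer(seed),
         dynamics = dynamics, reaction = reaction,
         region_margin = region_margin),
    class = "scenario_config"
  )
}

#' Run one fishing scenario end to end
#'
#' Chains layout construction, rope-dynamics simulation, population
#' generation over the swept corridor, and the collection-phase fish
#' engine.
#'
#' @param config A [scenario_config()] object.
#' @param keep_kinematics Keep the (large) kinematics log in the result.
#' @return A `seine_scenario` object: `config`, `summary` (one-row tibble
#'   with initial / winch-start / end counts and percentage changes),
#'   `indicators`, final `population`, `counters`, and optionally
#'   `kinematics`.
#' @export
run_scenario <- function(config, keep_kinematics = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  layout <- make_layout(config$pattern, config$rope_length_each)
  plan <- make_haul_plan(config$tow_minutes, config$tow_speed, config$winch_speed)
  kin <- simulate_haul(layout, plan, config$dynamics)
  region <- scenario_region(layout, plan, config$region_margin)
  pop <- generate_population(population_spec(
    region, fish_dens = config$fish_dens, placement = config$placement,
    seed = config$seed
  ))
  res <- run_collection(kin, pop, config$reaction)
  s <- res$summary
  ini <- s$fish_encircled[1]
  pct <- function(v) if (ini > 0) round(100 * (v - ini) / ini) else NA_real_
  summary <- tibble::tibble(
    pattern = config$pattern,
    tow_minutes = config$tow_minutes,
    initial = ini,
    at_winch_start = s$fish_encircled[2],
    at_winch_start_pct = pct(s$fish_encircled[2]),
    at_end = s$fish_encircled[3],
    at_end_pct = pct(s$fish_encircled[3]),
    n_fish = nrow(pop),
    t_end_s = s$t_s[3]
  )
  structure(
    list(config = config, summary = summary, indicators = res$indicators,
         population = res$population, counters = res$counters,
         kinematics = if (keep_kinematics) kin else NULL,
         instants = res$summary),
    class = "seine_scenario"
  )
}

#' @export
print.seine_scenario <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<seine_scenario> %s x %g min: initial %d, at winch start %d (%+d%%), at end %d (%+d%%)\n",
    s$pattern, s$tow_minutes, s$initial, s$at_winch_start, s$at_winch_start_pct,
    s$at_end, s$at_end_pct
  ))
  invisible(x)
}

#' Run a batch of scenarios
#'
#' @param patterns Character vector of layout patterns.
#' @param tow_minutes Numeric vector of towing durations (minutes); the
#'   full crossing of `patterns` and `tow_minutes` is run.
#' @param ... Passed to [scenario_config()] for every scenario.
#' @param keep_kinematics Keep kinematics logs (memory-heavy).
#' @return A `seine_suite` list of `seine_scenario` objects with a bound
#'   `summary` tibble.
#' @export
run_scenario_suite <- function(patterns = c("rectangle", "square", "triangle", "diamond"),
                               tow_minutes = c(0, 15, 35), ...,
                               keep_kinematics = FALSE) {
  grid <- expand.grid(pattern = patterns, tow_minutes = tow_minutes,
                      stringsAsFactors = FALSE)
  results <- purrr::pmap(grid, function(pattern, tow_minutes) {
    run_scenario(scenario_config(pattern = pattern, tow_minutes = tow_minutes, ...),
                 keep_kinematics = keep_kinematics)
  })
  names(results) <- paste0(grid$pattern, "_", grid$tow_minutes)
  structure(
    list(results = results,
         summary = dplyr::bind_rows(purrr::map(results, "summary"))),
    class = "seine_suite"
  )
}

#' Tabulate scenario results in the reference-table style
#'
#' One row per scenario with the encircled-fish counts and, in
#' parentheses, the percentage change relative to the initial layout.
#'
#' @param results A `seine_suite`, a list of `seine_scenario` objects, or a
#'   single scenario.
#' @return A tibble with raw counts, percentages, and formatted display
#'   cells (`at_winch_start_cell`, `at_end_cell`).
#' @export
summarize_scenarios <- function(results) {
  if (inherits(results, "seine_scenario")) results <- list(results)
  if (inherits(results, "seine_suite")) results <- results$results
  if (length(results) == 0) stop("no scenario results to summarize", call. = FALSE)
  s <- dplyr::bind_rows(purrr::map(results, "summary"))
  dplyr::mutate(
    s,
    at_winch_start_cell = sprintf("%d (%d%%)", .data$at_winch_start,
                                  .data$at_winch_start_pct),
    at_end_cell = sprintf("%d (%d%%)", .data$at_end, .data$at_end_pct)
  )
}

#' @export
print.seine_suite <- function(x, ...) {
  cat("<seine_suite> ", length(x$results), " scenarios\n", sep = "")
  print(summarize_scenarios(x)[, c("pattern", "tow_minutes", "initial",
                                   "at_winch_start_cell", "at_end_cell")])
  invisible(x)
}

#' Relative catch performance between two layout patterns
#'
#' Percentage excess of the final encircled count of one pattern over
#' another, within each haul plan:
#' `100 * (end[pattern_a] - end[pattern_b]) / end[pattern_b]`.
#'
#' @param results A `seine_suite` or list of scenarios.
#' @param pattern_a,pattern_b Patterns to compare (default square vs
#'   rectangle).
#' @return Tibble with `tow_minutes` and `excess_pct`.
#' @export
compare_patterns <- function(results, pattern_a = "square", pattern_b = "rectangle") {
  s <- summarize_scenarios(results)
  a <- s[s$pattern == pattern_a, c("tow_minutes", "at_end")]
  b <- s[s$pattern == pattern_b, c("tow_minutes", "at_end")]
  m <- dplyr::inner_join(a, b, by = "tow_minutes", suffix = c("_a", "_b"))
  tibble::tibble(
    tow_minutes = m$tow_minutes,
    excess_pct = 100 * (m$at_end_a - m$at_end_b) / m$at_end_b
  )
}

#' Catch gain from including a towing phase
#'
#' Percentage increase of the final encircled count relative to the
#' no-towing haul of the same layout pattern.
#'
#' @param results A `seine_suite` or list of scenarios.
#' @return Tibble with `pattern`, `tow_minutes`, `gain_pct` (NA for the
#'   0-minute reference rows).
#' @export
towing_gain <- function(results) {
  s <- summarize_scenarios(results)
  base <- s[s$tow_minutes == 0, c("pattern", "at_end")]
  names(base)[2] <- "end0"
  m <- dplyr::left_join(s, base, by = "pattern")
  tibble::tibble(
    pattern = m$pattern,
    tow_minutes = m$tow_minutes,
    gain_pct = ifelse(m$tow_minutes == 0, NA_real_,
                      100 * (m$at_end - m$end0) / m$end0)
  )
}
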