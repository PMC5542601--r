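#' Simulate the collection phase
#'
#' Steps the fish population through the haul described by a kinematics log:
#' at every `dt_fish` step the gear is interpolated in time, the seabed
#' rope sections extracted, every agent reacts once (to the nearest point
#' over both ropes' sections), and the indicators -- encircled area, entry
#' width, fish encircled -- are logged.
#'
#' @param kinlog A [simulate_haul()] / [kinematics_log()] object.
#' @param population Agent tibble from [generate_population()].
#' @param params A [reaction_params()] object.
#' @param engine `"cpp"` (fast path, default) or `"r"` (reference
#'   implementation in plain R built from [react_fish()] and friends; use
#'   only on small problems).
#' @param check_crossings Track violations of the herding-barrier invariant
#'   (an agent displacement crossing a seabed rope section); counted in the
#'   result's `counters`.
#' @return A `collection_result` list: `indicators` (tibble `t_s`,
#'   `area_m2`, `entry_width_m`, `fish_encircled`), `population` (final
#'   agent tibble), `summary` (tibble with rows Initial / At start of
#'   winching / At end of process), and `counters` (herd, raise and
#'   barrier-crossing event counts).
#' @export
run_collection <- function(kinlog, population, params = reaction_params(),
                           engine = c("cpp", "r"), check_crossings = TRUE) {
  stopifnot(inherits(kinlog, "seine_kinematics"))
  engine <- match.arg(engine)
  winch_start <- kinlog$meta$tow_duration %||% 0
  tend <- kinlog$times[length(kinlog$times)]
  if (tend < winch_start) {
    stop("kinematics log is shorter than the haul: winching never starts", call. = FALSE)
  }
  radius <- kinlog$meta$rope_radius %||% 0.018

  if (engine == "cpp") {
    par <- list(
      l_min = params$l_min, l_move = params$l_move, p_herd = params$p_herd,
      dt_fish = params$dt_fish, contact_tol = params$contact_tol,
      rope_radius = radius, barrier_margin = params$barrier_margin,
      winch_start = winch_start, check_crossings = isTRUE(check_crossings),
      seed = as.double(params$seed)
    )
    raw <- run_collection_cpp(
      kinlog$times, kinlog$rope1, kinlog$rope2, kinlog$net,
      as.double(population$x), as.double(population$y),
      as.logical(population$raised), par
    )
    ind <- tibble::tibble(
      t_s = raw$indicators[, 1],
      area_m2 = raw$indicators[, 2],
      entry_width_m = raw$indicators[, 3],
      fish_encircled = as.integer(raw$indicators[, 4])
    )
    pop <- tibble::tibble(
      id = population$id, x = raw$x, y = raw$y, raised = raw$raised,
      herded_dist = population$herded_dist + raw$herded_dist
    )
    counters <- list(
      n_herd_events = raw$n_herd_events,
      n_raise_events = raw$n_raise_events,
      n_crossings = raw$n_crossings
    )
    idx_winch <- raw$idx_winch
  } else {
    out <- run_collection_r(kinlog, population, params, winch_start)
    ind <- out$indicators
    pop <- out$population
    counters <- out$counters
    idx_winch <- out$idx_winch
  }

  summary <- tibble::tibble(
    instant = c("initial", "at_winch_start", "at_end"),
    t_s = ind$t_s[c(1L, idx_winch, nrow(ind))],
    fish_encircled = ind$fish_encircled[c(1L, idx_winch, nrow(ind))],
    area_m2 = ind$area_m2[c(1L, idx_winch, nrow(ind))],
    entry_width_m = ind$entry_width_m[c(1L, idx_winch, nrow(ind))]
  )
  structure(
    list(indicators = ind, population = pop, summary = summary,
         counters = counters, params = params, meta = kinlog$meta),
    class = "collection_result"
  )
}

# plain-R reference engine: same stepping rules as the C++ path, built from
# the exported per-fish operations; for small verification problems only
run_collection_r <- function(kinlog, population, params, winch_start) {
  times <- kinlog$times
  t0 <- times[1]
  tend <- times[length(times)]
  nt <- floor((tend - t0) / params$dt_fish + 1e-9) + 1
  ind <- matrix(0, nt, 4)
  pop <- as.list(population)
  na <- length(pop$x)
  n_herd <- 0
  n_raise <- 0
  idx_winch <- nt
  winch_seen <- FALSE
  for (it in seq_len(nt)) {
    t <- min(t0 + (it - 1) * params$dt_fish, tend)
    snap <- gear_at_time(kinlog, t, params$contact_tol)
    secs <- seabed_sections(snap)
    if (length(secs) > 0) {
      for (i in seq_len(na)) {
        fish <- list(x = pop$x[i], y = pop$y[i], raised = pop$raised[i],
                     herded_dist = pop$herded_dist[i])
        if (fish$raised) {
          fish <- update_raised(fish, secs, params)
        } else {
          fish <- react_fish(fish, secs, params)
          ev <- attr(fish, "event")
          if (ev == "herd") n_herd <- n_herd + 1
          if (ev == "raise") n_raise <- n_raise + 1
        }
        pop$x[i] <- fish$x
        pop$y[i] <- fish$y
        pop$raised[i] <- fish$raised
        pop$herded_dist[i] <- fish$herded_dist
      }
    }
    poly <- encirclement_polygon(snap)
    popt <- tibble::tibble(x = pop$x, y = pop$y, raised = pop$raised)
    ind[it, ] <- c(t, attr(poly, "area"), entry_width(snap),
                   count_encircled(popt, poly))
    if (!winch_seen && t >= winch_start - 1e-9) {
      idx_winch <- it
      winch_seen <- TRUE
    }
  }
  list(
    indicators = tibble::tibble(
      t_s = ind[, 1], area_m2 = ind[, 2], entry_width_m = ind[, 3],
      fish_encircled = as.integer(ind[, 4])
    ),
    population = tibble::tibble(id = population$id, x = pop$x, y = pop$y,
                                raised = pop$raised, herded_dist = pop$herded_dist),
    counters = list(n_herd_events = n_herd, n_raise_events = n_raise,
                    n_crossings = NA_real_),
    idx_winch = idx_winch
  )
}

#' @export
print.collection_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<collection_result> %s, %g min tow: %d fish initially, %d at winch start, %d at end\n",
    x$meta$pattern %||% "?", x$meta$tow_minutes %||% NA,
    s$fish_encircled[1], s$fish_encircled[2], s$fish_encircled[3]
  ))
  invisible(x)
}
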