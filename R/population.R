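#' Specify a virtual fish population
#'
#' Describes the fish population placed on the virtual fishing ground before
#' a haul. Grid placement puts one fish at the centre of each square cell of
#' side `sqrt(1 / fish_dens)` tiling the region (deterministic and, for
#' square/rectangular grounds, exact: `area * fish_dens` fish). Uniform
#' random placement draws `round(area * fish_dens)` i.i.d. positions.
#'
#' The grid is laid out in the region's own frame (rotated by `grid_angle`),
#' so a ground that is a square or rectangle tiles exactly regardless of its
#' orientation in world coordinates.
#'
#' @param region Either a planar polygon (matrix with x, y columns, open
#'   ring) bounding the fishing ground, or a [make_layout()] object, in which
#'   case the initial layout loop is used and `grid_angle` is taken from the
#'   layout.
#' @param fish_dens Average fish density in fish per square metre
#'   (default 0.01, i.e. 100 fish per hectare-sized 10000 m^2).
#' @param placement `"grid"` (default, deterministic) or `"uniform_random"`.
#' @param seed Integer seed for random placement.
#' @param grid_angle Rotation (radians) of the grid frame; ignored when
#'   `region` is a layout.
#' @return A `population_spec` list.
#' @export
population_spec <- function(region, fish_dens = 0.01,
                            placement = c("grid", "uniform_random"),
                            seed = 1L, grid_angle = 0) {
  placement <- match.arg(placement)
  if (inherits(region, "seine_layout")) {
    grid_angle <- region$grid_angle
    region <- region$loop
  }
  region <- as.matrix(region)
  if (!is.numeric(fish_dens) || length(fish_dens) != 1 || !is.finite(fish_dens) ||
      fish_dens < 0) {
    stop("`fish_dens` must be a single non-negative number", call. = FALSE)
  }
  if (nrow(region) < 3 || polygon_area(region) <= 0) {
    stop("`region` must be a non-degenerate polygon (>= 3 vertices)", call. = FALSE)
  }
  structure(
    list(region = region[, 1:2, drop = FALSE], fish_dens = fish_dens,
         placement = placement, seed = as.integer(seed), grid_angle = grid_angle),
    class = "population_spec"
  )
}

#' Generate the fish population for a haul
#'
#' @param spec A [population_spec()].
#' @return A tibble of agents with columns `id`, `x`, `y` (metres), `raised`
#'   (logical, all `FALSE` initially) and `herded_dist` (cumulative herded
#'   distance in metres, all 0).
#' @examples
#' lay <- make_layout("square")
#' pop <- generate_population(population_spec(lay))
#' nrow(pop)  # 10000
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  poly <- spec$region
  if (spec$fish_dens == 0) {
    return(tibble::tibble(id = integer(), x = numeric(), y = numeric(),
                          raised = logical(), herded_dist = numeric()))
  }
  cell <- sqrt(1 / spec$fish_dens)
  if (spec$placement == "grid") {
    a <- spec$grid_angle
    rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)     # frame -> world
    roti <- t(rot)                                              # world -> frame
    pf <- poly %*% t(roti)
    xr <- range(pf[, 1]); yr <- range(pf[, 2])
    xs <- seq(xr[1] + cell / 2, xr[2], by = cell)
    ys <- seq(yr[1] + cell / 2, yr[2], by = cell)
    g <- as.matrix(expand.grid(x = xs, y = ys))
    gw <- g %*% t(rot)
    keep <- points_in_polygon(gw, poly)
    pts <- gw[keep, , drop = FALSE]
  } else {
    n <- round(spec$fish_dens * polygon_area(poly))
    pts <- withr::with_seed(spec$seed, {
      xr <- range(poly[, 1]); yr <- range(poly[, 2])
      out <- matrix(NA_real_, n, 2)
      filled <- 0L
      while (filled < n) {
        m <- max(2L * (n - filled), 100L)
        cand <- cbind(stats::runif(m, xr[1], xr[2]), stats::runif(m, yr[1], yr[2]))
        cand <- cand[points_in_polygon(cand, poly), , drop = FALSE]
        take <- min(nrow(cand), n - filled)
        if (take > 0) {
          out[(filled + 1):(filled + take), ] <- cand[seq_len(take), ]
          filled <- filled + take
        }
      }
      out
    })
  }
  tibble::tibble(
    id = seq_len(nrow(pts)),
    x = pts[, 1],
    y = pts[, 2],
    raised = FALSE,
    herded_dist = 0
  )
}

#' Fishing-ground region for a scenario
#'
#' The ground must cover the initial layout and the corridor swept while the
#' vessel steams ahead during towing and winching; fish outside it can never
#' be encircled. Returns an axis-aligned rectangle: the layout bounding box
#' padded by `margin` and extended forward to the vessel's maximum travel.
#'
#' @param layout A [make_layout()] object.
#' @param plan A [make_haul_plan()] object.
#' @param margin Padding in metres around the corridor (default 50).
#' @return A 4-vertex polygon matrix (open ring).
#' @export
scenario_region <- function(layout, plan, margin = 50) {
  stopifnot(inherits(layout, "seine_layout"), inherits(plan, "haul_plan"))
  bb <- apply(layout$loop, 2, range)
  winch_duration <- (layout$rope_length_each - plan$min_rope) / max(plan$winch_speed, 1e-9)
  winch_duration <- min(winch_duration, max(plan$max_time - plan$tow_duration, 0))
  travel <- plan$tow_speed * plan$tow_duration +
    (plan$winch_tow_speed %||% 0) * winch_duration
  x0 <- bb[1, 1] - margin
  x1 <- bb[2, 1] + travel + margin
  y0 <- bb[1, 2] - margin
  y1 <- bb[2, 2] + margin
  m <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
  colnames(m) <- c("x", "y")
  m
}
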