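#' Construct an idealized initial seine-rope layout
#'
#' Builds the resolved planar geometry of one of the four idealized layout
#' patterns in which two seine ropes (default 2000 m each) are deployed on
#' the seabed before the haul starts. The vessel sits at the junction of the
#' two ropes, the net at the opposite end of the loop, and the tow heading
#' points along the vessel--net symmetry axis, away from the net (+x).
#'
#' The pattern dimensions are fixed by the rope-length constraint (each rope
#' traverses half the loop perimeter) together with conventional shape
#' choices: the square has 1000 m sides; the rectangle is 1600 m x 400 m
#' (64 % of the square's area); the triangle is equilateral with 1333.3 m
#' sides, vessel at the apex and net at the base midpoint; the diamond is a
#' rhombus with 1000 m sides and an 82 degree apex angle at the vessel and
#' net vertices.
#'
#' @param pattern One of `"rectangle"`, `"square"`, `"triangle"`, `"diamond"`.
#' @param rope_length_each Length of each of the two seine ropes in metres
#'   (default 2000, the legal maximum in the Norwegian coastal fishery).
#'   All dimensions scale linearly with this value.
#' @return An object of class `seine_layout`: a list with the pattern name,
#'   `rope_length_each`, the ordered vertex matrices `vertices_rope1` and
#'   `vertices_rope2` (vessel end to net end), `vessel_position`,
#'   `net_position`, `tow_heading`, the closed loop ring `loop`, and
#'   `grid_angle`, the rotation (radians) of the layout's natural grid frame
#'   used for deterministic grid population placement.
#' @examples
#' lay <- make_layout("square")
#' layout_area(lay)  # 1e6 m^2
#' @export
make_layout <- function(pattern = c("rectangle", "square", "triangle", "diamond"),
                        rope_length_each = 2000) {
  pattern <- match.arg(pattern)
  if (!is.numeric(rope_length_each) || length(rope_length_each) != 1 ||
      !is.finite(rope_length_each) || rope_length_each <= 0) {
    stop("`rope_length_each` must be a single positive number", call. = FALSE)
  }
  sc <- rope_length_each / 2000
  grid_angle <- 0
  if (pattern == "square") {
    h <- 1000 * sqrt(2) / 2          # half diagonal of a 1000 m square
    v1 <- rbind(c(0, 0), c(-h, h), c(-2 * h, 0))
    grid_angle <- pi / 4
  } else if (pattern == "rectangle") {
    v1 <- rbind(c(0, 0), c(0, 200), c(-1600, 200), c(-1600, 0))
  } else if (pattern == "triangle") {
    s <- 4000 / 3
    h <- s * sqrt(3) / 2
    v1 <- rbind(c(0, 0), c(-h, s / 2), c(-h, 0))
  } else {
    apex <- 82 * pi / 180            # rhombus apex angle at vessel and net
    cx <- 1000 * cos(apex / 2)
    sy <- 1000 * sin(apex / 2)
    v1 <- rbind(c(0, 0), c(-cx, sy), c(-2 * cx, 0))
  }
  v1 <- v1 * sc
  v2 <- v1 %*% diag(c(1, -1))
  colnames(v1) <- colnames(v2) <- c("x", "y")
  # ring: rope1 vertices, then rope2 interior vertices reversed
  interior2 <- v2[rev(seq(2, nrow(v2) - 1)), , drop = FALSE]
  loop <- rbind(v1, interior2)
  structure(
    list(
      pattern = pattern,
      rope_length_each = rope_length_each,
      vertices_rope1 = v1,
      vertices_rope2 = v2,
      vessel_position = c(x = 0, y = 0),
      net_position = c(x = v1[nrow(v1), 1], y = 0),
      tow_heading = c(x = 1, y = 0),
      loop = loop,
      grid_angle = grid_angle
    ),
    class = "seine_layout"
  )
}

#' Layout vertices as a tidy table
#'
#' @param layout A [make_layout()] object.
#' @return A tibble with columns `rope_id`, `vertex_index`, `x_m`, `y_m`.
#' @export
layout_vertices <- function(layout) {
  stopifnot(inherits(layout, "seine_layout"))
  v1 <- layout$vertices_rope1
  v2 <- layout$vertices_rope2
  tibble::tibble(
    rope_id = rep(1:2, c(nrow(v1), nrow(v2))),
    vertex_index = c(seq_len(nrow(v1)), seq_len(nrow(v2))),
    x_m = c(v1[, 1], v2[, 1]),
    y_m = c(v1[, 2], v2[, 2])
  )
}

#' Enclosed area of the initial layout loop
#'
#' @param layout A [make_layout()] object.
#' @return Enclosed area in square metres (shoelace formula on the loop).
#' @export
layout_area <- function(layout) {
  stopifnot(inherits(layout, "seine_layout"))
  polygon_area(layout$loop)
}

polyline_length <- function(v) {
  if (nrow(v) < 2) return(0)
  sum(sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2)))
}

#' @export
print.seine_layout <- function(x, ...) {
  cat(sprintf(
    "<seine_layout> %s: 2 ropes x %g m, enclosed area %.0f m^2, net at (%.1f, %.1f)\n",
    x$pattern, x$rope_length_each, layout_area(x), x$net_position[1], x$net_position[2]
  ))
  invisible(x)
}

#' Plan a haul-in procedure
#'
#' A haul plan is a towing phase of `tow_minutes` at `tow_speed` followed by
#' winching both ropes at `winch_speed` while the vessel holds station (or
#' keeps way on at `winch_tow_speed`). `tow_minutes = 0` is the anchor-seine
#' style procedure where winching starts immediately.
#'
#' @param tow_minutes Duration of the towing phase in minutes (>= 0). The
#'   reference scenarios use 0, 15 and 35.
#' @param tow_speed Vessel speed in m/s (default 1.0289 m/s = 2 knots).
#' @param winch_speed Rope retrieval speed per rope in m/s (default 0.9).
#' @param winch_tow_speed Vessel speed (m/s) while winching. The default 0
#'   has the vessel holding station during hauling (the classical
#'   anchor-seine closure): at the reference speeds a continuously steaming
#'   vessel would outrun the recovered rope, pull the gear taut and lift it
#'   off the seabed before the wings close. Set a positive value to keep
#'   way on during hauling.
#' @param min_area Encirclement area (m^2) at which the collection phase is
#'   considered over and the record truncated (default 1e5, 10 % of the
#'   square layout's initial area). Below this the encirclement is a sliver
#'   narrower than the herding resolution (`l_move`, the population grid
#'   spacing) and the wings are closing onto the net path -- the closing
#'   phase, which the collection model does not resolve.
#' @param min_rope Unwinched rope length (m) at which winching stops
#'   (default 50).
#' @param max_time Maximum simulated haul time in seconds (default 5000).
#' @return A `haul_plan` list with `tow_duration` in seconds and the above
#'   fields.
#' @examples
#' make_haul_plan(15)$tow_duration  # 900 s
#' @export
make_haul_plan <- function(tow_minutes, tow_speed = 1.0289, winch_speed = 0.9,
                           winch_tow_speed = 0, min_area = 1e5, min_rope = 50,
                           max_time = 5000) {
  if (!is.numeric(tow_minutes) || length(tow_minutes) != 1 || !is.finite(tow_minutes) ||
      tow_minutes < 0) {
    stop("`tow_minutes` must be a single non-negative number", call. = FALSE)
  }
  for (nm in c("tow_speed", "winch_speed", "winch_tow_speed", "min_area",
               "min_rope", "max_time")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop(sprintf("`%s` must be a single non-negative number", nm), call. = FALSE)
    }
  }
  if (tow_minutes > 0 && tow_speed <= 0) {
    stop("a towing phase requires a positive `tow_speed`", call. = FALSE)
  }
  structure(
    list(
      tow_minutes = tow_minutes,
      tow_duration = 60 * tow_minutes,
      tow_speed = tow_speed,
      winch_speed = winch_speed,
      winch_tow_speed = winch_tow_speed,
      min_area = min_area,
      min_rope = min_rope,
      max_time = max_time
    ),
    class = "haul_plan"
  )
}

#' @export
print.haul_plan <- function(x, ...) {
  cat(sprintf(
    "<haul_plan> tow %g min at %.4f m/s, then winch at %.2f m/s per rope\n",
    x$tow_minutes, x$tow_speed, x$winch_speed
  ))
  invisible(x)
}
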