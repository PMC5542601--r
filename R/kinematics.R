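#' Gear kinematics log
#'
#' The interchange artifact between the rope-dynamics solver and the fish
#' engine: time-stamped 3-D positions of a fixed number of points along each
#' rope (vessel end to net end), plus vessel and net positions and the
#' remaining unwinched rope length. Internally ropes are stored as numeric
#' arrays with dimensions `(3, n_nodes, n_frames)`.
#'
#' @param times Strictly increasing frame times (s).
#' @param rope1,rope2 Arrays `(3, n_nodes, n_frames)` of node positions (m).
#' @param vessel,net Matrices `(3, n_frames)` of positions.
#' @param remaining Matrix `(2, n_frames)` of unwinched rope length per rope
#'   (m), or NULL.
#' @param meta Named list of scenario metadata (layout pattern, plan,
#'   rope diameter, ...).
#' @return An object of class `seine_kinematics`.
#' @export
kinematics_log <- function(times, rope1, rope2, vessel, net, remaining = NULL,
                           meta = list()) {
  log <- structure(
    list(version = 1L, times = as.numeric(times), rope1 = rope1, rope2 = rope2,
         vessel = vessel, net = net, remaining = remaining, meta = meta),
    class = "seine_kinematics"
  )
  validate_kinematics(log)
  log
}

validate_kinematics <- function(log) {
  nf <- length(log$times)
  if (nf < 1) stop("kinematics log has no frames", call. = FALSE)
  if (nf > 1 && any(diff(log$times) <= 0)) {
    stop("kinematics frame times must be strictly increasing", call. = FALSE)
  }
  for (nm in c("rope1", "rope2")) {
    d <- dim(log[[nm]])
    if (length(d) != 3 || d[1] != 3 || d[3] != nf) {
      stop(sprintf("`%s` must be a (3, n_nodes, n_frames) array", nm), call. = FALSE)
    }
    if (!all(is.finite(log[[nm]]))) {
      stop(sprintf("`%s` contains non-finite coordinates", nm), call. = FALSE)
    }
  }
  invisible(log)
}

#' @export
print.seine_kinematics <- function(x, ...) {
  cat(sprintf(
    "<seine_kinematics> %d frames, t = [%.1f, %.1f] s, %d + %d rope nodes\n",
    length(x$times), x$times[1], x$times[length(x$times)],
    dim(x$rope1)[2], dim(x$rope2)[2]
  ))
  invisible(x)
}

fmt17 <- function(x) sprintf("%.17g", x)

triplet_json <- function(m) {
  # m: 3 x n matrix -> "[[x,y,z],...]" at full precision
  paste0("[", paste0("[", fmt17(m[1, ]), ",", fmt17(m[2, ]), ",", fmt17(m[3, ]),
                     "]", collapse = ","), "]")
}

#' Write / read a kinematics log (JSON-lines interchange file)
#'
#' One header line (`version`, node counts, metadata) followed by one JSON
#' object per frame. Coordinates are written with 17 significant digits so
#' the round trip is bit-exact.
#'
#' @param log A `seine_kinematics` object.
#' @param path File path.
#' @return `write_kinematics` returns `path` invisibly; `read_kinematics`
#'   returns a `seine_kinematics` object.
#' @export
write_kinematics <- function(log, path) {
  stopifnot(inherits(log, "seine_kinematics"))
  validate_kinematics(log)
  nf <- length(log$times)
  n1 <- dim(log$rope1)[2]
  n2 <- dim(log$rope2)[2]
  meta <- log$meta
  meta_json <- if (length(meta)) {
    jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
  } else "{}"
  header <- sprintf('{"version":%d,"n_nodes":[%d,%d],"meta":%s}',
                    log$version, n1, n2, meta_json)
  lines <- character(nf + 1L)
  lines[1] <- header
  has_rem <- !is.null(log$remaining)
  for (k in seq_len(nf)) {
    rem <- if (has_rem) {
      sprintf(',"remaining":[%s,%s]', fmt17(log$remaining[1, k]), fmt17(log$remaining[2, k]))
    } else ""
    lines[k + 1L] <- sprintf(
      '{"t":%s,"rope1":%s,"rope2":%s,"vessel":[%s,%s,%s],"net":[%s,%s,%s]%s}',
      fmt17(log$times[k]),
      triplet_json(log$rope1[, , k, drop = FALSE][, , 1]),
      triplet_json(log$rope2[, , k, drop = FALSE][, , 1]),
      fmt17(log$vessel[1, k]), fmt17(log$vessel[2, k]), fmt17(log$vessel[3, k]),
      fmt17(log$net[1, k]), fmt17(log$net[2, k]), fmt17(log$net[3, k]),
      rem
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_kinematics
#' @export
read_kinematics <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("kinematics file has no frames", call. = FALSE)
  header <- jsonlite::fromJSON(lines[1])
  if (is.null(header$version) || header$version != 1) {
    stop("unsupported kinematics schema version", call. = FALSE)
  }
  n1 <- header$n_nodes[1]
  n2 <- header$n_nodes[2]
  nf <- length(lines) - 1L
  times <- numeric(nf)
  rope1 <- array(NA_real_, c(3, n1, nf))
  rope2 <- array(NA_real_, c(3, n2, nf))
  vessel <- matrix(NA_real_, 3, nf)
  net <- matrix(NA_real_, 3, nf)
  remaining <- NULL
  for (k in seq_len(nf)) {
    fr <- jsonlite::fromJSON(lines[k + 1L])
    if (is.null(fr$t) || is.null(fr$rope1) || is.null(fr$rope2)) {
      stop(sprintf("malformed frame on line %d", k + 1L), call. = FALSE)
    }
    r1 <- fr$rope1
    r2 <- fr$rope2
    if (nrow(r1) != n1 || nrow(r2) != n2) {
      stop(sprintf("ragged node count on line %d", k + 1L), call. = FALSE)
    }
    times[k] <- fr$t
    rope1[, , k] <- t(r1)
    rope2[, , k] <- t(r2)
    vessel[, k] <- fr$vessel
    net[, k] <- fr$net
    if (!is.null(fr$remaining)) {
      if (is.null(remaining)) remaining <- matrix(NA_real_, 2, nf)
      remaining[, k] <- fr$remaining
    }
  }
  if (nf > 1 && any(diff(times) <= 0)) {
    stop("kinematics frame times must be strictly increasing", call. = FALSE)
  }
  meta <- header$meta
  if (length(meta) == 0) meta <- list()
  kinematics_log(times, rope1, rope2, vessel, net, remaining, meta)
}

#' Interpolated gear geometry at an arbitrary time
#'
#' Outer loop of the nested interpolation: every rope node position is the
#' linear blend of its positions in the two bracketing frames. No
#' extrapolation outside the logged time range.
#'
#' @param log A `seine_kinematics` object.
#' @param t Query time in seconds; must lie within the logged range.
#' @param contact_tol Bottom clearance (m) below which a node counts as on
#'   the seabed (default 0.05); clearance is node height minus rope radius.
#' @return A `gear_snapshot` list with `t`, per-rope node matrices (`rope1`,
#'   `rope2`, n x 3), `vessel`, `net`, logical contact masks `contact1`,
#'   `contact2`, and the rope radius used.
#' @export
gear_at_time <- function(log, t, contact_tol = 0.05) {
  stopifnot(inherits(log, "seine_kinematics"))
  times <- log$times
  nf <- length(times)
  if (!is.finite(t) || t < times[1] - 1e-9 || t > times[nf] + 1e-9) {
    stop(sprintf("time %g outside the logged range [%g, %g]", t, times[1], times[nf]),
         call. = FALSE)
  }
  t <- min(max(t, times[1]), times[nf])
  k <- findInterval(t, times, rightmost.closed = TRUE)
  k <- min(max(k, 1L), nf - 1L)
  if (nf == 1L) k <- 1L
  if (nf == 1L) {
    al <- 0
    k2 <- 1L
  } else {
    span <- times[k + 1L] - times[k]
    al <- if (span > 0) (t - times[k]) / span else 0
    k2 <- k + 1L
  }
  blend <- function(arr) {
    m <- (1 - al) * arr[, , k] + al * arr[, , k2]
    t(m)
  }
  r1 <- blend(log$rope1)
  r2 <- blend(log$rope2)
  vessel <- (1 - al) * log$vessel[, k] + al * log$vessel[, k2]
  net <- (1 - al) * log$net[, k] + al * log$net[, k2]
  radius <- log$meta$rope_radius %||% 0.018
  snap <- list(
    t = t, rope1 = r1, rope2 = r2, vessel = vessel, net = net,
    contact1 = (r1[, 3] - radius) <= contact_tol,
    contact2 = (r2[, 3] - radius) <= contact_tol,
    rope_radius = radius, contact_tol = contact_tol
  )
  class(snap) <- "gear_snapshot"
  snap
}

#' Position at a fractional arc length along a rope
#'
#' Inner loop of the nested interpolation: linear interpolation along the
#' piecewise-linear rope polyline of a snapshot.
#'
#' @param snapshot A [gear_at_time()] snapshot.
#' @param rope_id 1 or 2.
#' @param s Arc-length fraction in `[0, 1]`; 0 is the vessel end, 1 the net
#'   end.
#' @return Length-3 position (m).
#' @export
point_on_rope <- function(snapshot, rope_id, s) {
  stopifnot(inherits(snapshot, "gear_snapshot"))
  if (!is.numeric(s) || length(s) != 1 || !is.finite(s) || s < 0 || s > 1) {
    stop("`s` must be a single value in [0, 1]", call. = FALSE)
  }
  v <- if (rope_id == 1) snapshot$rope1 else if (rope_id == 2) snapshot$rope2 else
    stop("`rope_id` must be 1 or 2", call. = FALSE)
  seg <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  target <- s * cum[length(cum)]
  j <- findInterval(target, cum, rightmost.closed = TRUE)
  j <- min(max(j, 1L), nrow(v) - 1L)
  a <- if (seg[j] > 1e-12) (target - cum[j]) / seg[j] else 0
  v[j, ] + a * (v[j + 1L, ] - v[j, ])
}

# contiguous seabed-contact run nearest the net end; c(start, end) node
# indices, or NULL when the rope has no contact
contact_run <- function(mask) {
  e <- max(which(mask), -1L)
  if (e < 1L) return(NULL)
  a <- e
  while (a > 1L && mask[a - 1L]) a <- a - 1L
  c(a, e)
}

#' Seabed-contacting rope sections of a snapshot
#'
#' For each rope, the single contiguous contact section reaching closest to
#' the net end (isolated touch-down islands near the vessel are ignored),
#' closed at the net position. These are the planar polylines fish react to.
#'
#' @param snapshot A [gear_at_time()] snapshot.
#' @return List of 0, 1 or 2 polyline matrices (x, y columns).
#' @export
seabed_sections <- function(snapshot) {
  stopifnot(inherits(snapshot, "gear_snapshot"))
  out <- list()
  for (i in 1:2) {
    v <- if (i == 1) snapshot$rope1 else snapshot$rope2
    mask <- if (i == 1) snapshot$contact1 else snapshot$contact2
    run <- contact_run(mask)
    if (is.null(run)) next
    sec <- rbind(v[run[1]:run[2], 1:2, drop = FALSE], snapshot$net[1:2])
    out[[length(out) + 1L]] <- sec
  }
  out
}

#' Encirclement polygon of a snapshot
#'
#' The closed planar ring formed by the seabed-contacting section of rope 1
#' (vessel side to net), the net position, the reversed contact section of
#' rope 2, and the straight entry chord between the two vessel-side lift-off
#' points.
#'
#' @param snapshot A [gear_at_time()] snapshot.
#' @return A vertex matrix (open ring, x and y columns) with attribute
#'   `area` (m^2); a 0-row matrix with area 0 when either rope has no
#'   seabed contact.
#' @export
encirclement_polygon <- function(snapshot) {
  stopifnot(inherits(snapshot, "gear_snapshot"))
  run1 <- contact_run(snapshot$contact1)
  run2 <- contact_run(snapshot$contact2)
  if (is.null(run1) || is.null(run2)) {
    out <- matrix(numeric(), 0, 2, dimnames = list(NULL, c("x", "y")))
    attr(out, "area") <- 0
    return(out)
  }
  ring <- rbind(
    snapshot$rope1[run1[1]:run1[2], 1:2, drop = FALSE],
    snapshot$net[1:2],
    snapshot$rope2[run2[2]:run2[1], 1:2, drop = FALSE]
  )
  colnames(ring) <- c("x", "y")
  attr(ring, "area") <- polygon_area(ring)
  ring
}

#' Entry width of the gear
#'
#' Planar distance between the vessel-nearest seabed-contact points of the
#' two ropes: the only opening through which fish can still enter the
#' encircled area. Zero when the two points coincide or when a rope has no
#' seabed contact.
#'
#' @param snapshot A [gear_at_time()] snapshot.
#' @return Width in metres.
#' @export
entry_width <- function(snapshot) {
  stopifnot(inherits(snapshot, "gear_snapshot"))
  run1 <- contact_run(snapshot$contact1)
  run2 <- contact_run(snapshot$contact2)
  if (is.null(run1) || is.null(run2)) return(0)
  p1 <- snapshot$rope1[run1[1], 1:2]
  p2 <- snapshot$rope2[run2[1], 1:2]
  sqrt(sum((p1 - p2)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
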