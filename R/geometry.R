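#' Absolute polygon area (shoelace formula)
#'
#' @param polygon A matrix of vertices (x, y columns, open ring; a repeated
#'   closing vertex is tolerated). Objects with extra columns are accepted.
#' @return Area in squared input units; 0 for fewer than 3 vertices.
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
polygon_area <- function(polygon) {
  p <- as.matrix(polygon)[, 1:2, drop = FALSE]
  n <- nrow(p)
  if (n >= 2 && all(p[1, ] == p[n, ])) {
    p <- p[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3) return(0)
  xn <- p[c(2:n, 1), 1]
  yn <- p[c(2:n, 1), 2]
  abs(sum(p[, 1] * yn - xn * p[, 2])) / 2
}

#' Even-odd point-in-polygon test
#'
#' Ray-casting with the even-odd rule. Points lying on the boundary (within
#' `boundary_tol`) are counted as inside.
#'
#' @param points Matrix of query points (x, y columns).
#' @param polygon Polygon vertex matrix (open ring).
#' @param boundary Count boundary points as inside (default TRUE).
#' @param boundary_tol Distance tolerance for the boundary test in metres.
#' @return Logical vector, one entry per query point.
#' @export
points_in_polygon <- function(points, polygon, boundary = TRUE, boundary_tol = 1e-9) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  poly <- as.matrix(polygon)[, 1:2, drop = FALSE]
  n <- nrow(poly)
  if (n >= 2 && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3 || nrow(pts) == 0) return(rep(FALSE, nrow(pts)))
  storage.mode(pts) <- "double"
  storage.mode(poly) <- "double"
  points_in_polygon_cpp(pts, poly, boundary, boundary_tol)
}

#' Nearest point on the seabed rope sections
#'
#' Euclidean point-to-polyline distance over a list of planar polylines (the
#' seabed-contacting sections of the two ropes). Also reports which side of
#' the nearest segment the query point lies on (sign of the cross product of
#' the segment direction with the offset vector).
#'
#' @param position Numeric length-2 planar position (m).
#' @param sections List of polyline matrices (x, y columns); empty or
#'   degenerate sections give distance `Inf`.
#' @return A list with `distance` (m), `point` (closest point, length-2),
#'   `side` (+1, -1 or 0), `section` and `segment` (indices of the nearest
#'   segment).
#' @export
nearest_rope_point <- function(position, sections) {
  p <- as.numeric(position)[1:2]
  best <- list(distance = Inf, point = c(NA_real_, NA_real_), side = 0,
               section = NA_integer_, segment = NA_integer_)
  for (si in seq_along(sections)) {
    v <- as.matrix(sections[[si]])
    if (is.null(v) || nrow(v) < 2) next
    a <- v[-nrow(v), 1:2, drop = FALSE]
    b <- v[-1, 1:2, drop = FALSE]
    d <- b - a
    L2 <- rowSums(d^2)
    t <- ((p[1] - a[, 1]) * d[, 1] + (p[2] - a[, 2]) * d[, 2]) / pmax(L2, 1e-300)
    t <- pmin(pmax(t, 0), 1)
    qx <- a[, 1] + t * d[, 1]
    qy <- a[, 2] + t * d[, 2]
    dist <- sqrt((p[1] - qx)^2 + (p[2] - qy)^2)
    j <- which.min(dist)
    if (dist[j] < best$distance) {
      crossp <- d[j, 1] * (p[2] - qy[j]) - d[j, 2] * (p[1] - qx[j])
      best <- list(distance = dist[j], point = c(qx[j], qy[j]),
                   side = sign(crossp), section = si, segment = j)
    }
  }
  best
}

# earliest parameter in [0,1] along p -> p + r at which it crosses segment
# a -> b, or NA
segment_cross_param <- function(p, r, a, b) {
  s <- b - a
  den <- r[1] * s[2] - r[2] * s[1]
  if (abs(den) < 1e-15) return(NA_real_)
  q <- a - p
  t <- (q[1] * s[2] - q[2] * s[1]) / den
  u <- (q[1] * r[2] - q[2] * r[1]) / den
  if (t >= 0 && t <= 1 && u >= 0 && u <= 1) t else NA_real_
}
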