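# Independent oracles used to cross-check the package's geometry and the
# collection engine. These deliberately re-derive results by brute force or
# via an unrelated library so they never share code with the implementation
# they verify.

# even-odd point-in-polygon by explicit ray casting (horizontal ray, +x)
oracle_pip <- function(pts, poly) {
  n <- nrow(poly)
  apply(pts, 1, function(p) {
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      yi <- poly[i, 2]; yj <- poly[j, 2]
      if ((yi > p[2]) != (yj > p[2])) {
        xint <- poly[i, 1] + (p[2] - yi) / (yj - yi) * (poly[j, 1] - poly[i, 1])
        if (p[1] < xint) inside <- !inside
      }
      j <- i
    }
    inside
  })
}

# point-to-polyline distance by dense sampling of every segment, with one
# local refinement pass around the best coarse sample
oracle_polyline_dist <- function(p, polyline, n_samp = 4000) {
  best <- Inf
  for (j in seq_len(nrow(polyline) - 1)) {
    a <- polyline[j, ]; b <- polyline[j + 1, ]
    seg_d <- function(tt) {
      sqrt((p[1] - (a[1] + tt * (b[1] - a[1])))^2 +
           (p[2] - (a[2] + tt * (b[2] - a[2])))^2)
    }
    tt <- seq(0, 1, length.out = n_samp)
    d <- seg_d(tt)
    k <- which.min(d)
    lo <- tt[max(k - 1L, 1L)]
    hi <- tt[min(k + 1L, n_samp)]
    d2 <- seg_d(seq(lo, hi, length.out = n_samp))
    best <- min(best, min(d2))
  }
  best
}

# polygon area by 1 m rasterization (cell-centre occupancy)
oracle_raster_area <- function(poly, cell = 1) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  xs <- seq(xr[1] + cell / 2, xr[2], by = cell)
  ys <- seq(yr[1] + cell / 2, yr[2], by = cell)
  g <- as.matrix(expand.grid(xs, ys))
  sum(oracle_pip(g, poly)) * cell^2
}

# do two closed segments properly intersect (shared endpoints excluded)?
oracle_segments_cross <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-14) return(FALSE)
  s <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
  u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
  s > 1e-10 && s < 1 - 1e-10 && u > 1e-10 && u < 1 - 1e-10
}

# is a closed ring simple (no self-intersection)? brute force over pairs
oracle_ring_simple <- function(ring) {
  n <- nrow(ring)
  idx <- cbind(seq_len(n), c(2:n, 1))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent segments (they share a vertex)
      if (abs(i - j) <= 1 || (i == 1 && j == n)) next
      if (oracle_segments_cross(ring[idx[i, 1], ], ring[idx[i, 2], ],
                                ring[idx[j, 1], ], ring[idx[j, 2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# random convex polygon (guaranteed simple) with ~n vertices
random_convex_polygon <- function(n = 10, scale = 400) {
  pts <- matrix(runif(2 * n * 3, 0, scale), ncol = 2)
  hull <- pts[chull(pts), , drop = FALSE]
  hull
}

# small synthetic kinematics log: two straight ropes, given per-frame
# y-offsets, all on the seabed, joined at a net; vessel off to the +x side
make_test_log <- function(times = 0:5, half_gap = 10 - 0.5 * (0:5),
                          n_nodes = 5, x0 = 0, x1 = -40, net_x = -45,
                          tow_duration = 0) {
  nf <- length(times)
  stopifnot(length(half_gap) == nf)
  r1 <- array(0, c(3, n_nodes, nf))
  r2 <- array(0, c(3, n_nodes, nf))
  vessel <- matrix(0, 3, nf)
  net <- matrix(0, 3, nf)
  xs <- seq(x0, x1, length.out = n_nodes)
  for (k in seq_len(nf)) {
    r1[1, , k] <- xs; r1[2, , k] <- half_gap[k]; r1[3, , k] <- 0
    r2[1, , k] <- xs; r2[2, , k] <- -half_gap[k]; r2[3, , k] <- 0
    vessel[, k] <- c(x0 + 5, 0, 100)
    net[, k] <- c(net_x, 0, 0)
  }
  kinematics_log(times, r1, r2, vessel, net,
                 meta = list(pattern = "synthetic", tow_duration = tow_duration,
                             rope_radius = 0.018))
}

# snapshot of an ideal square layout with every node on the seabed
make_square_snapshot <- function(lifted = FALSE) {
  lay <- make_layout("square")
  asm <- discretize_ropes(lay, 10)
  z <- if (lifted) 10 else 0
  nf <- 2
  n <- nrow(asm$rope1$pos) + 1  # nodes plus the net point
  r1 <- array(0, c(3, n, nf)); r2 <- array(0, c(3, n, nf))
  p1 <- rbind(asm$rope1$pos, c(lay$net_position, 0))
  p2 <- rbind(asm$rope2$pos, c(lay$net_position, 0))
  for (k in 1:nf) {
    r1[, , k] <- t(p1); r2[, , k] <- t(p2)
    r1[3, , k] <- z; r2[3, , k] <- z
  }
  log <- kinematics_log(c(0, 1), r1, r2, matrix(c(0, 0, 100), 3, nf),
                        matrix(c(lay$net_position, 0), 3, nf),
                        meta = list(rope_radius = 0.018, tow_duration = 0))
  gear_at_time(log, 0)
}
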