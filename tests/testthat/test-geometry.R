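test_that("shoelace area handles canonical and degenerate polygons", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_area(sq[4:1, ]), 1)              # orientation-free
  expect_equal(polygon_area(rbind(sq, sq[1, ])), 1)     # closed ring tolerated
  rect <- rbind(c(0, 0), c(1600, 0), c(1600, 400), c(0, 400))
  expect_equal(polygon_area(rect), 6.4e5)
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 1), c(2, 2))), 0)
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 1))), 0)
})

test_that("even-odd point-in-polygon matches an independent ray caster", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      poly <- random_convex_polygon(10, 400)
      pts <- cbind(runif(200, -50, 450), runif(200, -50, 450))
      expect_identical(points_in_polygon(pts, poly, boundary = FALSE),
                       oracle_pip(pts, poly))
    }
  })
})

test_that("boundary points count as inside", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  on_edge <- rbind(c(0.5, 0), c(1, 0.5), c(0, 0), c(0.5, 1))
  expect_true(all(points_in_polygon(on_edge, sq)))
  # a vertex is never strictly interior under the plain even-odd rule
  expect_false(points_in_polygon(rbind(c(1, 1)), sq, boundary = FALSE))
})

test_that("polygon area agrees with 1 m rasterization within 0.5 %", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      poly <- random_convex_polygon(12, 400)
      expect_equal(oracle_raster_area(poly), polygon_area(poly),
                   tolerance = 5e-3)
    }
  })
})

test_that("nearest rope point: foot, clamped endpoint, side sign", {
  seg <- list(rbind(c(-1, 0), c(1, 0)))
  np <- nearest_rope_point(c(0, 1), seg)
  expect_equal(np$distance, 1)
  expect_equal(np$point, c(0, 0))
  expect_equal(np$side, 1)
  expect_equal(nearest_rope_point(c(0, -1), seg)$side, -1)
  # beyond the endpoint the distance clamps to the endpoint
  np2 <- nearest_rope_point(c(3, 4), seg)
  expect_equal(np2$distance, sqrt(2^2 + 4^2))
  expect_equal(np2$point, c(1, 0))
  expect_equal(nearest_rope_point(c(0, 0), list())$distance, Inf)
})

test_that("nearest rope point matches dense-sampling brute force", {
  withr::with_seed(23, {
    for (rep in 1:8) {
      pl <- cbind(cumsum(runif(6, -10, 10)), cumsum(runif(6, -10, 10)))
      p <- runif(2, -20, 20)
      np <- nearest_rope_point(p, list(pl))
      expect_equal(np$distance, oracle_polyline_dist(p, pl), tolerance = 1e-6)
    }
  })
})
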