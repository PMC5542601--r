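straight_section <- function() list(rbind(c(-50, 0), c(50, 0)))

test_that("no reaction beyond l_min; herding moves exactly l_move away", {
  par <- reaction_params()
  fish <- list(x = 0, y = 2, raised = FALSE, herded_dist = 0)
  out <- react_fish(fish, straight_section(), par)
  expect_equal(attr(out, "event"), "none")
  expect_equal(out$x, 0)
  expect_equal(out$y, 2)
  # within l_min: 1.0 m -> 1.0 + 3.0 = 4.0 m from the same segment
  fish$y <- 1
  out <- react_fish(fish, straight_section(), par)
  expect_equal(attr(out, "event"), "herd")
  expect_equal(out$y, 4)
  expect_equal(out$x, 0)
  expect_equal(out$herded_dist, 3)
  # same law below the rope
  fish$y <- -1
  expect_equal(react_fish(fish, straight_section(), par)$y, -4)
})

test_that("herding is perpendicular, l_move long, and away on random geometry", {
  par <- reaction_params()
  withr::with_seed(5, {
    for (rep in 1:25) {
      a <- runif(2, -10, 10)
      b <- a + runif(2, -20, 20)
      sec <- list(rbind(a, b))
      np <- NULL
      # rejection-sample a fish within l_min of the segment
      repeat {
        p <- a + runif(1) * (b - a) + runif(2, -1, 1)
        np <- nearest_rope_point(p, sec)
        if (np$distance > 1e-3 && np$distance < par$l_min) break
      }
      out <- react_fish(list(x = p[1], y = p[2], raised = FALSE, herded_dist = 0),
                        sec, par)
      moved <- c(out$x - p[1], out$y - p[2])
      expect_equal(sqrt(sum(moved^2)), par$l_move, tolerance = 1e-9)
      # along the outward normal from the closest point
      expect_equal(moved / par$l_move, (p - np$point) / np$distance,
                   tolerance = 1e-9)
      # strictly further from the rope afterwards
      expect_gt(nearest_rope_point(c(out$x, out$y), sec)$distance, np$distance)
    }
  })
})

test_that("the raise branch keeps the planar position and clears when far", {
  par <- reaction_params(p_herd = 0, p_raise = 1)
  fish <- list(x = 0.3, y = 1, raised = FALSE, herded_dist = 0)
  out <- react_fish(fish, straight_section(), par)
  expect_equal(attr(out, "event"), "raise")
  expect_true(out$raised)
  expect_equal(c(out$x, out$y), c(0.3, 1))
  # raised fish stays raised while the rope is near, returns when it is not
  still <- update_raised(out, straight_section(), par)
  expect_true(still$raised)
  far <- update_raised(out, list(rbind(c(-50, 30), c(50, 30))), par)
  expect_false(far$raised)
  expect_error(update_raised(fish, straight_section(), par), "raised")
  expect_error(react_fish(out, straight_section(), par), "non-raised")
})

test_that("a blocked jump stops short of the rope and deflects along it", {
  par <- reaction_params()
  # fish between a straight rope and an oblique one 2-3 m above it
  sec <- list(rbind(c(-50, 0), c(50, 0)), rbind(c(-50, 2), c(50, 4)))
  fish <- list(x = 0, y = 0.8, raised = FALSE, herded_dist = 0)
  out <- react_fish(fish, sec, par)
  # jump away from the lower rope stops barrier_margin short of the oblique
  # one and the remainder slides along it; the path crosses neither rope
  expect_lt(out$y, 3 + 0.02 * out$x)            # still below the oblique rope
  for (s in sec) {
    expect_false(oracle_segments_cross(c(fish$x, fish$y), c(out$x, out$y),
                                       s[1, ], s[2, ]))
  }
  expect_gt(abs(out$x - fish$x), 0.5)           # deflected tangentially
  expect_equal(out$herded_dist, par$l_move, tolerance = 1e-9)
  # a perpendicular blocked jump (no tangential component) just stops short
  sec2 <- list(rbind(c(-50, 0), c(50, 0)), rbind(c(-50, 2), c(50, 2)))
  out2 <- react_fish(fish, sec2, par)
  expect_equal(out2$y, 2 - par$barrier_margin)
  expect_equal(out2$x, 0)
})

test_that("encircled counts match an independent ray-casting oracle", {
  withr::with_seed(31, {
    poly <- random_convex_polygon(9, 300)
    pop <- tibble::tibble(id = 1:200,
                          x = runif(200, -30, 330), y = runif(200, -30, 330),
                          raised = FALSE, herded_dist = 0)
    expect_equal(count_encircled(pop, poly), sum(oracle_pip(cbind(pop$x, pop$y), poly)))
    # raised fish are off the seabed and never counted
    pop$raised <- TRUE
    expect_equal(count_encircled(pop, poly), 0L)
  })
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  onb <- tibble::tibble(id = 1:2, x = c(5, 15), y = c(0, 5),
                        raised = FALSE, herded_dist = 0)
  expect_equal(count_encircled(onb, sq), 1L)  # boundary in, outside out
  expect_equal(count_encircled(onb, sq[1:2, ]), 0L)
})

test_that("collection run: zero fish, static gear, haul coverage check", {
  log <- make_test_log()
  empty <- generate_population(population_spec(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                                               fish_dens = 0))
  res <- run_collection(log, empty)
  expect_true(all(res$indicators$fish_encircled == 0))
  expect_true(all(res$indicators$area_m2 > 0))
  # static gear: no approach events, constant count
  static_log <- make_test_log(half_gap = rep(10, 6))
  pop <- tibble::tibble(id = 1:20, x = runif(20, -35, -5), y = runif(20, -7, 7),
                        raised = FALSE, herded_dist = 0)
  res <- run_collection(static_log, pop)
  expect_equal(length(unique(res$indicators$fish_encircled)), 1L)
  expect_equal(res$counters$n_herd_events, 0)
  # a log that ends before winching starts is rejected
  short <- make_test_log(tow_duration = 99)
  expect_error(run_collection(short, pop), "shorter than the haul")
})

test_that("the C++ engine and the plain-R reference engine agree", {
  log <- make_test_log(times = 0:5, half_gap = 10 - 0.8 * (0:5))
  withr::with_seed(13, {
    pop <- tibble::tibble(id = 1:40, x = runif(40, -38, -2), y = runif(40, -9, 9),
                          raised = FALSE, herded_dist = 0)
  })
  par <- reaction_params(dt_fish = 0.2)
  a <- run_collection(log, pop, par, engine = "cpp")
  b <- run_collection(log, pop, par, engine = "r")
  expect_equal(a$indicators$fish_encircled, b$indicators$fish_encircled)
  expect_equal(a$indicators$area_m2, b$indicators$area_m2)
  expect_equal(a$indicators$entry_width_m, b$indicators$entry_width_m)
  expect_equal(a$population$x, b$population$x, tolerance = 1e-9)
  expect_equal(a$population$y, b$population$y, tolerance = 1e-9)
  expect_equal(a$counters$n_herd_events, b$counters$n_herd_events)
})

test_that("identical seed and configuration give bit-identical results", {
  log <- make_test_log(times = 0:5, half_gap = 10 - 1.6 * (0:5))
  pop <- tibble::tibble(id = 1:30, x = seq(-38, -2, length.out = 30),
                        y = rep(c(-4.5, 0, 4.5), 10), raised = FALSE, herded_dist = 0)
  par <- reaction_params(p_herd = 0.7, p_raise = 0.3, seed = 99)
  a <- run_collection(log, pop, par)
  b <- run_collection(log, pop, par)
  expect_identical(a$indicators, b$indicators)
  expect_identical(a$population, b$population)
  # raise events occur under p_raise > 0 and raised fish are uncounted
  expect_gt(a$counters$n_raise_events, 0)
})

test_that("reaction parameter validation enforces the probability identity", {
  expect_error(reaction_params(p_herd = 0.9, p_raise = 0.3), "equal 1")
  expect_silent(reaction_params(p_herd = 0.9, p_raise = 0.1))
  expect_error(reaction_params(l_min = 0), "positive")
  expect_error(reaction_params(l_move = -1), "positive")
  expect_equal(reaction_params()$l_move, 3)
})
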