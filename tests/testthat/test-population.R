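test_that("grid placement tiles exactly on square and rectangular grounds", {
  sq <- generate_population(population_spec(make_layout("square")))
  expect_equal(nrow(sq), 10000L)
  rect <- generate_population(population_spec(make_layout("rectangle")))
  expect_equal(nrow(rect), 6400L)
  expect_false(any(sq$raised))
  expect_true(all(sq$herded_dist == 0))
})

test_that("grid counts agree with an independent point-in-polygon count", {
  skip_if_not_installed("mgcv")
  lay <- make_layout("diamond")
  pop <- generate_population(population_spec(lay))
  # rebuild the same lattice and count with mgcv's in.out instead
  ring <- rbind(lay$loop, lay$loop[1, ])
  ours_inside <- mgcv::in.out(ring, cbind(pop$x, pop$y))
  expect_true(all(ours_inside))
  expect_equal(nrow(pop), round(layout_area(lay) * 0.01), tolerance = 2e-3)
})

test_that("realized density is the nominal 100 fish per 10000 m^2", {
  lay <- make_layout("square")
  pop <- generate_population(population_spec(lay))
  expect_equal(nrow(pop) / layout_area(lay) * 1e4, 100)
})

test_that("random placement draws round(area x density) reproducible points", {
  region <- rbind(c(0, 0), c(500, 0), c(500, 400), c(0, 400))
  sp <- population_spec(region, placement = "uniform_random", seed = 42)
  p1 <- generate_population(sp)
  p2 <- generate_population(sp)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), round(0.01 * 500 * 400))
  p3 <- generate_population(population_spec(region, placement = "uniform_random",
                                            seed = 43))
  expect_false(identical(p1$x, p3$x))
  expect_true(all(points_in_polygon(cbind(p1$x, p1$y), region)))
})

test_that("degenerate population specs are rejected or empty", {
  region <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  expect_error(population_spec(region, fish_dens = -1), "non-negative")
  expect_error(population_spec(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
  empty <- generate_population(population_spec(region, fish_dens = 0))
  expect_equal(nrow(empty), 0L)
})

test_that("the scenario region covers the layout and the towing corridor", {
  lay <- make_layout("square")
  plan <- make_haul_plan(15)
  reg <- scenario_region(lay, plan)
  expect_true(all(points_in_polygon(lay$loop, reg)))
  expect_gte(max(reg[, 1]), plan$tow_speed * plan$tow_duration)
})
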