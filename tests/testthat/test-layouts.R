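test_that("every layout deploys 2 x 2000 m of rope as a simple closed loop", {
  for (pat in c("rectangle", "square", "triangle", "diamond")) {
    lay <- make_layout(pat)
    l1 <- seinesim:::polyline_length(lay$vertices_rope1)
    l2 <- seinesim:::polyline_length(lay$vertices_rope2)
    expect_equal(l1, 2000, tolerance = 1e-6)
    expect_equal(l2, 2000, tolerance = 1e-6)
    # ropes share the vessel and net endpoints
    expect_equal(unname(lay$vertices_rope1[1, ]), c(0, 0))
    expect_equal(lay$vertices_rope1[nrow(lay$vertices_rope1), ],
                 lay$vertices_rope2[nrow(lay$vertices_rope2), ])
    expect_true(oracle_ring_simple(lay$loop))
  }
})

test_that("enclosed areas order square > diamond > triangle > rectangle", {
  a <- vapply(c("square", "diamond", "triangle", "rectangle"),
              function(p) layout_area(make_layout(p)), numeric(1))
  expect_true(all(diff(a) < 0))
  expect_equal(a[["square"]], 1e6, tolerance = 1e-9)
  expect_equal(a[["rectangle"]] / a[["square"]], 0.64, tolerance = 1e-9)
})

test_that("layouts scale with rope length and reject degenerate input", {
  lay <- make_layout("square", 1000)
  expect_equal(seinesim:::polyline_length(lay$vertices_rope1), 1000, tolerance = 1e-9)
  expect_equal(layout_area(lay), 2.5e5, tolerance = 1e-6)
  expect_error(make_layout("hexagon"), "arg")
  expect_error(make_layout("square", 0), "positive")
  v <- layout_vertices(make_layout("rectangle"))
  expect_s3_class(v, "tbl_df")
  expect_named(v, c("rope_id", "vertex_index", "x_m", "y_m"))
})

test_that("haul plans convert minutes, default to reference speeds, validate", {
  plan <- make_haul_plan(15)
  expect_equal(plan$tow_duration, 900)
  expect_equal(plan$tow_speed, 1.0289)
  expect_equal(plan$winch_speed, 0.9)
  expect_equal(make_haul_plan(0)$tow_duration, 0)
  expect_error(make_haul_plan(-1), "non-negative")
  expect_error(make_haul_plan(35, tow_speed = 0), "positive")
  expect_silent(make_haul_plan(0, tow_speed = 0))
})
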