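test_that("kinematics logs round-trip bit-exactly through the JSONL file", {
  log <- make_test_log(times = c(0, 0.5, 1.7), half_gap = c(10, 9 + pi * 1e-9, 8.123456789012345))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_kinematics(log, path)
  back <- read_kinematics(path)
  expect_identical(back$times, log$times)
  expect_identical(back$rope1, log$rope1)
  expect_identical(back$rope2, log$rope2)
  expect_identical(back$vessel, log$vessel)
  expect_identical(back$net, log$net)
})

test_that("malformed kinematics are rejected with named errors", {
  log <- make_test_log()
  expect_error(kinematics_log(c(0, 1, 1), log$rope1, log$rope2, log$vessel, log$net),
               "strictly increasing")
  expect_error(kinematics_log(numeric(0),
                              array(0, c(3, 5, 0)), array(0, c(3, 5, 0)),
                              matrix(0, 3, 0), matrix(0, 3, 0)),
               "no frames")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_kinematics(log, path)
  lines <- readLines(path)
  # drop one node from a frame -> ragged node count
  bad <- sub('\\],\\[[^]]*\\]', ']', lines[3])
  writeLines(c(lines[1], lines[2], bad), path)
  expect_error(read_kinematics(path), "ragged|malformed")
  writeLines(c('{"version":99,"n_nodes":[2,2],"meta":{}}', lines[-1]), path)
  expect_error(read_kinematics(path), "version")
})

test_that("time interpolation is exact at frames and linear between them", {
  log <- make_test_log(times = 0:5)
  for (k in c(1, 3, 6)) {
    snap <- gear_at_time(log, log$times[k])
    expect_equal(snap$rope1, t(log$rope1[, , k]))
    expect_equal(snap$rope2, t(log$rope2[, , k]))
  }
  # node at (0,0,0) then (2,0,0): query halfway
  r1 <- array(c(0, 0, 0), c(3, 1, 2)); r1[, 1, 2] <- c(2, 0, 0)
  lg <- kinematics_log(c(0, 2), r1, r1, matrix(0, 3, 2), matrix(0, 3, 2))
  expect_equal(gear_at_time(lg, 1)$rope1[1, ], c(2 / 2, 0, 0))
  expect_error(gear_at_time(log, -1), "outside")
  expect_error(gear_at_time(log, 99), "outside")
  # randomized times: interpolated position lies on the frame-to-frame segment
  withr::with_seed(3, {
    for (t in runif(10, 0, 5)) {
      k <- findInterval(t, log$times)
      al <- (t - log$times[k]) / (log$times[k + 1] - log$times[k])
      snap <- gear_at_time(log, t)
      manual <- (1 - al) * t(log$rope1[, , k]) + al * t(log$rope1[, , k + 1])
      expect_equal(snap$rope1, manual)
    }
  })
})

test_that("arc-length interpolation along a rope hits endpoints and knots", {
  snap <- gear_at_time(make_test_log(), 0)
  expect_equal(point_on_rope(snap, 1, 0), snap$rope1[1, ])
  expect_equal(point_on_rope(snap, 1, 1), snap$rope1[nrow(snap$rope1), ])
  expect_equal(point_on_rope(snap, 1, 0.5)[1], -20)
  # two-segment polyline with lengths 3 and 1: s = 0.75 is the joint
  r <- array(0, c(3, 3, 2))
  r[1, , 1] <- r[1, , 2] <- c(0, 3, 3)
  r[2, , 1] <- r[2, , 2] <- c(0, 0, 1)
  lg <- kinematics_log(c(0, 1), r, r, matrix(0, 3, 2), matrix(0, 3, 2))
  sn <- gear_at_time(lg, 0)
  expect_equal(point_on_rope(sn, 1, 0.75), c(3, 0, 0))
  expect_error(point_on_rope(sn, 1, 1.2), "\\[0, 1\\]")
})

test_that("encirclement polygon, area and entry width on analytic snapshots", {
  snap <- make_square_snapshot()
  ring <- encirclement_polygon(snap)
  expect_equal(attr(ring, "area"), 1e6, tolerance = 1e-6)
  expect_true(oracle_ring_simple(ring))
  expect_equal(entry_width(snap), 0, tolerance = 1e-9)  # ropes meet at the vessel
  lifted <- make_square_snapshot(lifted = TRUE)
  expect_equal(attr(encirclement_polygon(lifted), "area"), 0)
  expect_equal(entry_width(lifted), 0)
  expect_length(seabed_sections(lifted), 0)
})

test_that("entry width is the gap between vessel-side contact points", {
  # both ropes fully on the seabed, vessel-side endpoints 50 m apart
  log <- make_test_log(times = 0:1, half_gap = c(25, 25))
  snap <- gear_at_time(log, 0)
  expect_equal(entry_width(snap), 50)
  # rope1 lifted before node 3, rope2 before node 2
  log$rope1[3, 1:2, ] <- 10
  log$rope2[3, 1, ] <- 10
  snap <- gear_at_time(log, 0)
  expect_equal(entry_width(snap),
               sqrt(sum((snap$rope1[3, 1:2] - snap$rope2[2, 1:2])^2)))
  # contiguous-run rule: an isolated touch-down near the vessel is ignored
  log$rope1[3, 1, ] <- 0   # node 1 touches down again but node 2 is lifted
  snap <- gear_at_time(log, 0)
  run <- seinesim:::contact_run(snap$contact1)
  expect_equal(run[1], 3)
})
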