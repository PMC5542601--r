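test_that("discretization lays nodes on the layout at the requested spacing", {
  lay <- make_layout("square")
  asm <- discretize_ropes(lay, 20)
  # 100 elements of 20 m: 100 rope nodes plus the net point = 101 positions
  expect_equal(nrow(asm$rope1$pos), 100)
  expect_length(asm$rope1$rest, 100)
  expect_equal(sum(asm$rope1$rest), 2000)
  expect_true(all(asm$rope1$pos[, 3] == 0))
  # every node sits on the layout polyline
  for (i in sample(nrow(asm$rope1$pos), 10)) {
    d <- nearest_rope_point(asm$rope1$pos[i, 1:2], list(lay$vertices_rope1))$distance
    expect_lt(d, 1e-6)
  }
  expect_error(discretize_ropes(lay, 5000), "exceeds")
  expect_error(discretize_ropes(lay, 0), "positive")
})

test_that("seabed contact force: clearance, static overlap, Coulomb slide", {
  par <- dynamics_params()
  expect_equal(seabed_contact_force(c(0, 0, 1), c(0, 0, 0), par), c(0, 0, 0))
  # static node with overlap delta: vertical k * delta, no friction
  r <- par$diameter / 2
  delta <- 0.005
  f <- seabed_contact_force(c(0, 0, r - delta), c(0, 0, 0), par, node_length = 10)
  expect_equal(f, c(0, 0, par$contact_stiffness * delta * 10))
  # sliding at 1 m/s: horizontal magnitude mu * N opposing the motion
  fs <- seabed_contact_force(c(0, 0, r - delta), c(1, 0, 0), par, node_length = 10)
  expect_equal(fs[1], -par$mu_seabed * fs[3])
  expect_equal(fs[2], 0)
})

test_that("a rope resting on the seabed stays put", {
  n <- 11
  par <- dynamics_params()
  # start at the static penetration equilibrium
  w <- par$linear_mass * par$gravity * (1 - par$water_density / par$rope_density)
  z_eq <- par$diameter / 2 - w / par$contact_stiffness
  pos <- cbind(seq(0, 100, length.out = n), 0, z_eq)
  out <- step_dynamics(pos, NULL, rep(10, n - 1), par,
                       boundary = list(head_fixed = TRUE, tail_fixed = TRUE,
                                       winch_speed = 0),
                       n_steps = 2000)
  expect_lt(max(abs(out$pos[, 1:2] - pos[, 1:2])), 5e-3)
  expect_lt(out$kinetic_energy, 1e-6)
})

test_that("a sinking free rope reaches the analytic terminal velocity", {
  par <- dynamics_params(dt = 0.001)  # full-fidelity step for the 1 % check
  w <- par$linear_mass * par$gravity * (1 - par$water_density / par$rope_density)
  v_t <- sqrt(2 * w / (par$water_density * par$cd_normal * par$diameter))
  n <- 5
  pos <- cbind(seq(0, 40, length.out = n), 0, 30)
  out <- step_dynamics(pos, NULL, rep(10, n - 1), par,
                       boundary = list(head_fixed = FALSE, tail_fixed = FALSE,
                                       winch_speed = 0),
                       n_steps = 40000)  # 40 s
  expect_gt(min(out$pos[, 3]), 1)       # still in the water column
  expect_equal(out$vel[3, 3], -v_t, tolerance = 0.01)
})

test_that("rest length is conserved while towing and drawn in while winching", {
  lay <- make_layout("square")
  par <- dynamics_params()
  # towing only: a 15-min plan truncated at 60 s never winches
  kin <- simulate_haul(lay, make_haul_plan(15, max_time = 60), par)
  expect_true(all(kin$remaining == 2000))
  # winching from the start removes exactly 0.9 m/s per rope
  kin <- simulate_haul(lay, make_haul_plan(0, max_time = 100), par)
  after <- kin$times >= 0
  expect_equal(kin$remaining[1, after], 2000 - 0.9 * kin$times[after],
               tolerance = 1e-9)
  expect_equal(kin$remaining[2, after], 2000 - 0.9 * kin$times[after],
               tolerance = 1e-9)
})

test_that("haul logs respect the frame contract and prescribed vessel motion", {
  lay <- make_layout("square")
  kin <- simulate_haul(lay, make_haul_plan(15, max_time = 950), dynamics_params())
  expect_true(all(diff(kin$times) > 0))
  expect_equal(dim(kin$rope1)[2], 201)
  expect_true(all(is.finite(kin$rope1)))
  # towing-phase displacement = tow_speed x 900 s
  v0 <- gear_at_time(kin, 0)$vessel[1]
  v900 <- gear_at_time(kin, 900)$vessel[1]
  expect_equal(v900 - v0, 1.0289 * 900, tolerance = 0.5)
})

test_that("symmetric layouts stay mirror-symmetric about the tow axis", {
  lay <- make_layout("square")
  kin <- simulate_haul(lay, make_haul_plan(0, max_time = 200), dynamics_params())
  flip <- kin$rope2
  flip[2, , ] <- -flip[2, , ]
  expect_equal(kin$rope1, flip, tolerance = 1e-6)
  expect_equal(max(abs(kin$net[2, ])), 0, tolerance = 1e-6)
})
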