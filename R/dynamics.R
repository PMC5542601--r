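#' Rope-dynamics solver parameters
#'
#' Physical constants and numerical settings for the lumped-mass rope
#' solver. Defaults describe a 36 mm combination seine rope on a flat sandy
#' seabed in 100 m of water, with the desk-scale integration profile
#' (semi-implicit Euler, dt = 0.005 s, 10 m elements, 2 s output frames).
#' The classical forward Euler profile (`integrator = "euler"`,
#' `dt = 0.001`) is available for full-fidelity runs.
#'
#' Stability of the explicit integration is governed by the axial mode:
#' `dt * sqrt(EA / element_length / (linear_mass * element_length)) <= ~1`
#' for the semi-implicit scheme. The defaults give 0.71.
#'
#' @param dt Integration time step (s).
#' @param integrator `"semi_implicit"` (symplectic Euler, default) or
#'   `"euler"` (forward Euler).
#' @param element_length Nominal rope element length (m).
#' @param frame_interval Output frame spacing (s).
#' @param diameter Rope diameter (m), default 0.036.
#' @param linear_mass Rope mass per metre in air (kg/m).
#' @param rope_density Effective rope material density (kg/m^3); with
#'   `water_density` it sets the submerged weight
#'   `linear_mass * g * (1 - water_density / rope_density)`.
#' @param water_density Seawater density (kg/m^3).
#' @param EA Axial stiffness (N); the rope is tension-only.
#' @param axial_damping Axial viscous damping (N s/m).
#' @param contact_stiffness,contact_damping Seabed penalty stiffness (N/m)
#'   and damping (N s/m) per metre of rope.
#' @param mu_seabed Transversal seabed Coulomb friction coefficient: the
#'   normal contact force resists sideways (plowing) sliding of the rope
#'   across the seabed.
#' @param mu_longitudinal Longitudinal friction coefficient for sliding
#'   along the rope's own axis; much smaller than the transversal one.
#' @param slide_eps Sliding-velocity regularization (m/s): friction ramps
#'   viscously below this speed to avoid stick-slip chatter.
#' @param cd_normal,cd_tangential Normal and tangential drag coefficients
#'   (tangential referenced to the wetted surface `pi * d`).
#' @param gravity Gravitational acceleration (m/s^2).
#' @param depth Water depth (m): the vessel tow point sits this high above
#'   the seabed, which controls how much rope hangs off the bottom near the
#'   vessel and hence the entry width.
#' @param settle_time Pre-haul settling phase (s) during which the vessel
#'   attachment is raised from the seabed to the surface and the rope finds
#'   its catenary; the haul clock starts at the end of settling.
#' @param max_speed Node speed (m/s) above which the solver aborts with a
#'   diagnostic (divergence guard).
#' @param net_mass,net_weight,net_mu,net_drag Net body point mass (kg),
#'   submerged weight (N), seabed friction coefficient, and quadratic drag
#'   factor (N s^2/m^2).
#' @param net_contact_stiffness,net_contact_damping,net_radius Net seabed
#'   contact penalty parameters.
#' @param n_log Number of resampled points per rope in each output frame.
#' @return A `dynamics_params` list.
#' @export
dynamics_params <- function(dt = 0.005,
                            integrator = c("semi_implicit", "euler"),
                            element_length = 10,
                            frame_interval = 2,
                            diameter = 0.036,
                            linear_mass = 1.0,
                            rope_density = 1800,
                            water_density = 1025,
                            EA = 1e6,
                            axial_damping = 500,
                            contact_stiffness = 500,
                            contact_damping = 20,
                            mu_seabed = 0.5,
                            mu_longitudinal = 0.1,
                            slide_eps = 0.02,
                            cd_normal = 1.2,
                            cd_tangential = 0.02,
                            gravity = 9.81,
                            depth = 100,
                            settle_time = 180,
                            max_speed = 50,
                            net_mass = 300,
                            net_weight = 1000,
                            net_mu = 0.3,
                            net_drag = 500,
                            net_contact_stiffness = 1e4,
                            net_contact_damping = 2000,
                            net_radius = 0.5,
                            n_log = 201L) {
  integrator <- match.arg(integrator)
  p <- list(
    dt = dt, integrator = integrator, element_length = element_length,
    frame_interval = frame_interval, diameter = diameter,
    linear_mass = linear_mass, rope_density = rope_density,
    water_density = water_density, EA = EA, axial_damping = axial_damping,
    contact_stiffness = contact_stiffness, contact_damping = contact_damping,
    mu_seabed = mu_seabed, mu_longitudinal = mu_longitudinal,
    slide_eps = slide_eps, cd_normal = cd_normal,
    cd_tangential = cd_tangential, gravity = gravity, depth = depth,
    settle_time = settle_time, max_speed = max_speed, net_mass = net_mass,
    net_weight = net_weight, net_mu = net_mu, net_drag = net_drag,
    net_contact_stiffness = net_contact_stiffness,
    net_contact_damping = net_contact_damping, net_radius = net_radius,
    n_log = as.integer(n_log)
  )
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (mu_seabed < 0) stop("`mu_seabed` must be non-negative", call. = FALSE)
  class(p) <- "dynamics_params"
  p
}

#' Seabed contact and friction force on a rope node
#'
#' Penalty contact: zero force when the node's bottom clearance (height of
#' the rope centreline minus the rope radius) is positive; otherwise a
#' normal force `stiffness * overlap + damping * penetration_rate` (clamped
#' at zero), plus a Coulomb friction force opposing horizontal sliding with
#' magnitude at most `mu * normal`, regularized below `slide_eps`.
#'
#' @param position Length-3 node position (m); the seabed is z = 0.
#' @param velocity Length-3 node velocity (m/s).
#' @param params A [dynamics_params()] object.
#' @param node_length Rope length (m) lumped at this node.
#' @return Length-3 force vector (N).
#' @export
seabed_contact_force <- function(position, velocity, params = dynamics_params(),
                                 node_length = params$element_length) {
  z <- position[3]
  clearance <- z - params$diameter / 2
  if (clearance > 0) return(c(0, 0, 0))
  pen <- -clearance
  normal <- (params$contact_stiffness * pen + params$contact_damping * (-velocity[3])) *
    node_length
  normal <- max(normal, 0)
  vh <- velocity[1:2]
  sp <- sqrt(sum(vh^2))
  scale <- params$mu_seabed * normal / max(sp, params$slide_eps)
  c(-scale * vh[1], -scale * vh[2], normal)
}

#' Discretize a layout into a lumped-mass rope assembly
#'
#' Nodes are laid along the layout polylines at the seabed (z = 0), spaced
#' at equal rest lengths as close to `element_length` as divides the rope
#' evenly.
#'
#' @param layout A [make_layout()] object.
#' @param element_length Target element length (m); must be positive and no
#'   longer than the rope.
#' @param params A [dynamics_params()] object supplying rope properties.
#' @return A `rope_assembly` list with per-rope node position/velocity
#'   matrices and rest lengths (the final rest element joins the last node
#'   to the net), the net position and rope properties.
#' @export
discretize_ropes <- function(layout, element_length = 10,
                             params = dynamics_params(element_length = element_length)) {
  stopifnot(inherits(layout, "seine_layout"))
  L <- layout$rope_length_each
  if (!is.numeric(element_length) || element_length <= 0) {
    stop("`element_length` must be positive", call. = FALSE)
  }
  if (element_length > L) {
    stop("`element_length` exceeds the rope length", call. = FALSE)
  }
  n_elem <- max(2L, round(L / element_length))
  rest <- rep(L / n_elem, n_elem)
  sample_rope <- function(v) {
    seg <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
    cum <- c(0, cumsum(seg))
    s <- cum[length(cum)] * (0:(n_elem - 1L)) / n_elem   # nodes 0..n_elem-1; net closes
    j <- pmin(pmax(findInterval(s, cum, rightmost.closed = TRUE), 1L), length(seg))
    a <- (s - cum[j]) / pmax(seg[j], 1e-12)
    cbind(v[j, 1] + a * (v[j + 1L, 1] - v[j, 1]),
          v[j, 2] + a * (v[j + 1L, 2] - v[j, 2]),
          0)
  }
  structure(
    list(
      rope1 = list(pos = sample_rope(layout$vertices_rope1),
                   vel = NULL, rest = rest),
      rope2 = list(pos = sample_rope(layout$vertices_rope2),
                   vel = NULL, rest = rest),
      net = c(layout$net_position, 0),
      diameter = params$diameter,
      linear_mass = params$linear_mass,
      layout = layout
    ),
    class = "rope_assembly"
  )
}

#' Advance a single rope by explicit time stepping
#'
#' Low-level stepper over one rope chain, mainly for physics verification:
#' force inventory is submerged weight, tension-only axial elasticity,
#' seabed contact and friction, and hydrodynamic drag. Ends can be pinned
#' (e.g. vessel and net attachment) or free; winching removes rest length
#' from the head (vessel-side) end.
#'
#' @param pos,vel Node position and velocity matrices (n x 3).
#' @param rest Element rest lengths, length n - 1.
#' @param params A [dynamics_params()] object.
#' @param boundary List with `head_fixed`, `tail_fixed` (logicals) and
#'   `winch_speed` (m/s, applied at the head when fixed).
#' @param n_steps Number of `params$dt` steps to take.
#' @return List with updated `pos`, `vel`, `rest` (possibly fewer nodes
#'   after winching) and the final `kinetic_energy` (J). Aborts with a
#'   diagnostic naming the offending node if the state diverges.
#' @export
step_dynamics <- function(pos, vel, rest, params = dynamics_params(),
                          boundary = list(head_fixed = TRUE, tail_fixed = TRUE,
                                          winch_speed = 0),
                          n_steps = 1L) {
  pos <- as.matrix(pos)
  if (is.null(vel)) vel <- matrix(0, nrow(pos), 3)
  vel <- as.matrix(vel)
  stopifnot(nrow(pos) >= 3, ncol(pos) == 3, all(rest > 0))
  boundary$head_fixed <- isTRUE(boundary$head_fixed)
  boundary$tail_fixed <- isTRUE(boundary$tail_fixed)
  boundary$winch_speed <- boundary$winch_speed %||% 0
  storage.mode(pos) <- storage.mode(vel) <- "double"
  rope_step_cpp(pos, vel, as.numeric(rest), unclass(params), boundary,
                as.integer(n_steps))
}

#' Simulate the haul: rope dynamics for a layout and haul plan
#'
#' Runs the coupled two-rope + net system through a settling phase, the
#' towing phase (vessel moving at `tow_speed` along +x) and the winching
#' phase (vessel still moving; both ropes retrieved at `winch_speed`),
#' recording frames every `params$frame_interval` seconds. The run ends
#' when the unwinched rope falls below `plan$min_rope` or `plan$max_time`
#' is reached; frames after the encirclement area first drops below
#' `plan$min_area` are truncated.
#'
#' @param layout A [make_layout()] object.
#' @param plan A [make_haul_plan()] object.
#' @param params A [dynamics_params()] object.
#' @return A `seine_kinematics` log; time 0 is the start of towing.
#' @export
simulate_haul <- function(layout, plan, params = dynamics_params()) {
  stopifnot(inherits(layout, "seine_layout"), inherits(plan, "haul_plan"))
  asm <- discretize_ropes(layout, params$element_length, params)
  raw <- simulate_haul_cpp(
    asm$rope1$pos, asm$rope2$pos,
    asm$rope1$rest, asm$rope2$rest,
    as.numeric(asm$net), unclass(params), unclass(plan)
  )
  meta <- list(
    pattern = layout$pattern,
    rope_length_each = layout$rope_length_each,
    rope_radius = params$diameter / 2,
    tow_minutes = plan$tow_minutes,
    tow_duration = plan$tow_duration,
    tow_speed = plan$tow_speed,
    winch_speed = plan$winch_speed,
    element_length = params$element_length,
    dt = params$dt,
    integrator = params$integrator,
    end_reason = raw$end_reason
  )
  log <- kinematics_log(raw$times, raw$rope1, raw$rope2, raw$vessel, raw$net,
                        raw$remaining, meta)
  truncate_by_area(log, plan$min_area, plan$tow_duration)
}

# drop frames after the encirclement area first falls below min_area; the
# rule only engages once winching has begun (during towing a squeezed
# encirclement keeps collecting through the entry)
truncate_by_area <- function(log, min_area, winch_start = 0) {
  nf <- length(log$times)
  cutoff <- nf
  for (k in seq_len(nf)) {
    if (log$times[k] < winch_start) next
    snap <- gear_at_time(log, log$times[k])
    a <- attr(encirclement_polygon(snap), "area")
    if (a < min_area && k > 1) {
      cutoff <- k
      break
    }
  }
  if (cutoff < nf) {
    log$times <- log$times[1:cutoff]
    log$rope1 <- log$rope1[, , 1:cutoff, drop = FALSE]
    log$rope2 <- log$rope2[, , 1:cutoff, drop = FALSE]
    log$vessel <- log$vessel[, 1:cutoff, drop = FALSE]
    log$net <- log$net[, 1:cutoff, drop = FALSE]
    if (!is.null(log$remaining)) log$remaining <- log$remaining[, 1:cutoff, drop = FALSE]
    log$meta$end_reason <- "area_closed"
  }
  log
}
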