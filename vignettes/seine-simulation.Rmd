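---
title: "Simulating demersal seine fishing: rope dynamics and fish herding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating demersal seine fishing: rope dynamics and fish herding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(seinesim)
```

## The fishing process being modelled

Demersal seining encircles fish on the seabed with two long ropes (here
2 x 2000 m of 36 mm combination rope, the legal maximum in the Norwegian
coastal fishery) joined to a comparatively small seine net. The gear is laid
out in a closed loop; the vessel then either starts winching immediately
(anchor/Danish seining) or first tows the gear forward for some minutes at
about two knots (fly-dragging/Scottish seining) before winching both ropes
at 0.9 m/s. Catch performance is driven by three coupled quantities:

* the area of seabed enclosed by the rope sections still in contact with
  the bottom (`area_m2`),
* the entry width (`entry_width_m`), the gap between the vessel-side
  lift-off points of the two ropes -- the only opening through which new
  fish can join the encircled school, and
* the number of fish inside the encirclement (`fish_encircled`).

`seinesim` couples two models to predict these: a time-domain lumped-mass
simulation of the ropes, and an agent-based model of cod reacting to the
approaching rope. The chain is
`make_layout()` + `make_haul_plan()` -> `simulate_haul()` (gear kinematics)
-> `generate_population()` + `run_collection()` (fish reaction and
indicator logging), wrapped by `run_scenario()` and `run_scenario_suite()`.

## Rope model

Each rope is a chain of point masses joined by tension-only axial springs
with viscous axial damping. The force inventory per node is

* submerged weight, `linear_mass * g * (1 - water_density / rope_density)`
  per metre (defaults 1 kg/m and an effective rope density of 1800 kg/m^3,
  i.e. 0.43 kg/m submerged -- a sinking steel-core combination rope);
* seabed contact as a penalty force, `stiffness * overlap + damping *
  penetration_rate`, acting when the rope centreline is within one radius
  of the bed;
* Coulomb seabed friction, deliberately anisotropic: the normal force
  resists *transversal* (plowing) sliding with `mu_seabed = 0.5`, while
  sliding along the rope's own axis is only weakly resisted
  (`mu_longitudinal = 0.1`). This distinction matters enormously: with
  isotropic friction the 2 km of rope dragged lengthwise generates several
  kilonewtons of spurious tension, lifting hundreds of extra metres of rope
  off the bottom and straightening the wings into a degenerate corridor;
* Morison-type quadratic drag, decomposed about the local tangent
  (`cd_normal = 1.2`, `cd_tangential = 0.02` on the wetted perimeter).

The two ropes share a prescribed vessel attachment at the surface
(`depth = 100` m above the bed) and a net body: a point mass with its own
weight, contact, friction and drag. The net is deliberately mobile
(submerged weight 1000 N, friction 0.3): a seine net dragged by two
2000 m ropes is a comparatively small resistance, and a sticky net makes
the gear elongate instead of translating, which destroys the encirclement.

Integration is explicit. Weight, tension and the contact normal are
stepped with symplectic (semi-implicit) Euler at `dt = 0.005` s by default
(`integrator = "euler"` with `dt = 0.001` s gives the classical
forward-Euler profile); quadratic drag is applied as a semi-implicit
velocity divisor and friction as a stick-slip impulse projection (the
frictional impulse is clamped at the stopping impulse), both of which are
unconditionally stable. The axial mode sets the step bound:
`dt * sqrt(EA / element_length / (linear_mass * element_length))` must stay
around one; the defaults (EA = 1e6 N, 10 m elements) give 0.71. Winching
shortens the vessel-side element's rest length at `winch_speed` and merges
it into its neighbour when it falls below three quarters of the nominal
element length, which conserves the remaining-rope budget exactly.

Every run starts with a settling phase (`settle_time = 180` s, logged at
negative times): the vessel attachment is raised from the bed to the
surface so the near-vessel rope finds its catenary, and -- for plans with a
towing phase -- the vessel then ramps up and holds towing speed, so that
`t = 0` is the start of the tow proper with working tension already
developed. Without that convention every layout's entry width spends the
first tenth of the haul merely opening from the slack laid-out state,
masking the layout contrasts the indicators are meant to show. The first
logged frame (start of settling) is the gear exactly as laid out, which is
what the "initial" summary instant refers to. Anchor-style plans
(`tow_minutes = 0`) skip the ramp.

During winching the vessel holds station by default
(`winch_tow_speed = 0`). This is a deliberate deviation from naive
fly-dragging: at the reference speeds (vessel 1.03 m/s, winches 0.9 m/s
each) a continuously steaming vessel outruns the recovered rope, pulls the
gear taut, lifts it off the seabed and dumps nearly all encircled fish
through the retreating entry. Holding station gives the classical closure
in which the wings converge and the encircled school is retained; a
positive `winch_tow_speed` restores the steaming behaviour for
experimentation.

## Fish model

Fish are independent agents on the seabed that react only to the
seabed-contacting rope sections. When the nearest rope point comes within
`l_min = 1.5` m (cod keep one to two metres ahead of approaching ground
gear), one of two responses triggers, drawn from a per-agent
counter-based RNG stream:

* with probability `p_herd` (default 1) the fish is herded: an
  instantaneous jump of `l_move = 2 * l_min = 3` m along the unit normal
  from the closest rope point towards the fish;
* with probability `p_raise = 1 - p_herd` it rises off the bed on the
  spot, is excluded from the encircled count, ignores the rope, and
  returns to the bottom at the same planar position once the rope has
  cleared `l_min`.

A herding jump may not cross a rope: the jump stops `barrier_margin =
0.1` m short of any seabed section it would cross, and the blocked
remainder deflects along the obstructing segment in the direction of the
jump's tangential component (wall-following). Pure truncation is not
enough: a fish wedged in the closing V between the wings would otherwise
freeze in place and be swept over by the moving rope, violating the
no-crossing invariant the truncation exists to protect. With
wall-following the engine reports zero barrier crossings over all twelve
reference hauls. When a fish sits exactly on the rope line the side is
drawn from its RNG stream (a measure-zero event in floating point).

The collection loop advances in `dt_fish = 0.2` s steps. At each step the
gear is interpolated linearly in time between kinematics frames (the outer
interpolation; the inner, along-rope interpolation is available as
`point_on_rope()`), the contiguous seabed-contact section of each rope is
extracted (isolated touch-downs near the vessel are ignored), every agent
reacts at most once to the nearest point over both sections, and the three
indicators are logged. The encirclement polygon is the contact section of
rope 1, the net position, the reversed contact section of rope 2, closed
by the straight entry chord; fish are counted by the even-odd rule with
boundary points inside. The same rules are implemented twice: a fast
spatial-hashed C++ engine and a plain-R reference engine built from the
exported per-fish operations, and the test suite checks they agree.

## The virtual population

The fishing ground is a rectangle covering the initial layout and the
corridor the vessel sweeps; density is `fish_dens = 0.01` fish/m^2 (100
fish per 10,000 m^2, realistic for coastal cod grounds). The default grid
placement puts one fish at the centre of each 10 m cell tiling the ground
in the region's own frame, so a square or rectangular ground tiles
exactly: the 1000 m square layout encloses exactly 10,000 fish, the
1600 x 400 m rectangle exactly 6,400. (A world-axis-aligned lattice would
put 10,011 points in the 45-degree-rotated square -- the frame convention
is what makes the count exact.) Uniform random placement with a seed is
available for stochastic studies. Because every scenario uses the same
deterministic population, encircled counts are directly comparable across
layouts and haul plans, which is the point of the exercise: the absolute
counts share whatever bias the uniform-density assumption carries, but
their ratios do not.

What the generator does *not* emulate: schooling and patchiness, diel or
tidal movement, swimming endurance (a fish can be herded indefinitely),
size-dependent reaction distances, or any escape response to the net
itself. Passing tests therefore demonstrate the internal consistency of
the gear-plus-reaction model under idealized conditions, not field catch
rates.

## Layout geometry

The four idealized patterns are fixed by the rope-length constraint (each
rope traverses half the loop) plus conventional shape choices: square of
side 1000 m (vessel and net at opposite corners), 1600 x 400 m rectangle
(vessel and net at the short-side midpoints, preserving the mirror
symmetry the solver is tested against), equilateral triangle of side
1333.3 m (vessel at the apex, net at the base midpoint), and a rhombus of
side 1000 m with an 82-degree apex angle. Enclosed areas order
square (1.00e6) > diamond (0.99e6) > triangle (0.77e6) >
rectangle (0.64e6) m^2; the rectangle encircles 64 % of the square's fish
initially, and the rectangle/square contrast in entry width (wide but
quickly narrowing vs narrow but widening) emerges from the dynamics.

## End of the collection phase

The record ends when the unwinched rope falls below 50 m, at
`max_time = 5000` s, or -- once winching has begun -- when the encircled
area first drops below `min_area = 1e5` m^2 (10 % of the square's initial
area). Below that the encirclement is a sliver narrower than both the
herding jump and the population grid spacing, the wings are closing onto
the net path, and the remaining evolution belongs to the closing phase
(net capture), which this package deliberately does not model. The
threshold is a user parameter of `make_haul_plan()`.

## Problem sizes and determinism

The reference suite (four layouts x three haul plans) uses the desk-scale
profile: 10 m elements (200 per rope), dt = 0.005 s, 2 s output frames,
0.2 s fish steps, and populations of 10-70 thousand agents over the swept
corridor; the twelve hauls complete in a few minutes on one core. Identical
configuration and seed give bit-identical results: the solver is
deterministic and the fish engine uses per-agent counter-based streams, so
results are independent of agent iteration order.

## Known limitations

* The rope constitutive model is a lumped-mass approximation with
  penalty contact; the published end-of-process counts for this fishery
  were produced with a validated hinged-rigid-body cable code whose
  constants (contact stiffness, drag, friction, net resistance, depth) are
  not public. Scenario-level *orderings* -- square best, rectangle worst,
  longer towing never worse, losses without towing -- are robust
  reproductions; absolute counts agree only to within roughly 5-10 %.
* Long tows (35 min) stretch the encirclement until its area passes the
  end-of-collection threshold at the moment winching starts, so the
  winching phase contributes nothing there; the reference behaviour shows
  a small further gain.
* The fish model is the deliberately simple herding rule described above;
  see the generator caveats for everything it omits.
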