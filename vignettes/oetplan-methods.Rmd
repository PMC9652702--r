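---
title: "Planning and simulating multi-particle transport with optoelectronic tweezers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning and simulating multi-particle transport with optoelectronic tweezers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oetplan)
```

## The problem

Optoelectronic tweezers trap dielectric microparticles inside projected
annular light patterns ("virtual electrodes") and move them by moving the
light. Arranging many particles at once — beads of two sizes, or
fibroblast cells being patterned into a tissue-like layout — requires each
particle to be routed to a goal position without colliding with free
impurities or with the other targets, under Brownian noise and an
imperfectly predictable trap response. `oetplan` implements the full
control stack for this task and couples it to a stochastic simulator of
the microworld, so every component, and the closed loop as a whole, can be
exercised and tested on a desk.

## Coordinates, grid, and the decision process

The field of view is a 32 × 32 grid of square cells (the planner's state
space). The physical cell size is a package choice — nothing in the
underlying method fixes it — and defaults to 15 µm, which makes one cell
slightly larger than the largest handled particle (20 µm beads) and gives
a 480 µm field, the scale of a typical OET view. Coordinates are
continuous, in micrometres, origin at the top-left corner with y downward
(image convention); cells are half-open and indexed row-major starting at
1 (R convention).

Transport is discretized into single-step moves between adjacent cells:
the action set is the 8 unit moves plus "stay", in a fixed documented
order (stay last) that also serves as the tie-break order everywhere a
tie can occur.

Because the trap response is not perfectly predictable, the intended move
succeeds only with probability `1 − slip_prob` (default slip 0.1); the
remainder splits between the two moves 45° to either side. Moves off the
boundary fold back onto "stay". Position knowledge is a belief b(s) over
cells, maintained by an exact Bayes filter: predict through the
transition model, then multiply by a discretized Gaussian observation
likelihood (σ = 0.5 cell, truncated at 2 cells) and renormalise. An
observation that contradicts the whole predicted support (it can happen
after an unmodelled event such as a trap escape) reinitialises the belief
around the observation, with a warning.

## Value iteration and the QMDP policy

Per particle and per control period, the goal cell is clamped at value
100; every cell carrying obstacle belief is clamped at −50 times that
belief. All other cells start at 0, immediate rewards default to 0, and
values propagate purely through discounting (η = 0.95 by default):

V(s) = max_a [ r(s,a) + η Σ_s′ V(s′) p(s′|s,a) ].

Sweeps are Jacobi (double-buffered), so each sweep is a sup-norm
contraction with modulus ≤ η — a property the test suite checks directly.
The standalone solver iterates to a residual of 1e−6 by default with a cap
of `10 (nx + ny)` sweeps and raises an error on non-convergence. Inside
the control loop the tolerance is 1e−4 instead: the policy argmax is
insensitive to value errors far below the cell-to-cell value differences,
which are of order (1 − η)·V, and the loop re-solves every period anyway;
at 1e−6 the multi-particle scenarios spend most of their runtime
polishing decimals that cannot change a decision. Clamped (goal and
obstacle) cells are treated as terminal throughout, which keeps the
iteration well-defined; their Q rows are still computed so the policy is
defined everywhere, including on weakly-blocked cells a particle may
find itself in.

The control decision is the QMDP rule, `argmax_a Σ_s b(s) Q(s,a)`: the
underlying MDP is solved exactly and the belief enters only at policy
extraction. This deliberately ignores the value of information (a full
POMDP solver is out of scope by design); with the tight observation model
of a microscope feed the approximation is benign.

## Goal assignment

Assignment of targets to goals runs once, at task start. The cost of
sending particle i to goal j is the Manhattan grid distance plus two
penalty families, both in cell units:

* an obstacle detour term: each free obstacle within perpendicular offset
  L < R_sys of the straight segment, with its foot inside the segment,
  contributes the exact arc-minus-chord length
  2[R_sys·acos(L/R_sys) − √(R_sys² − L²)], scaled by λ (default 1). The
  printed form of this term is typeset ambiguously in the source
  literature (one grouping can go negative); the exact detour geometry is
  non-negative, decreasing in L, and zero at L = R_sys, and the penalty
  function is pluggable.
* a mutual-avoidance term γ·R_sys·(π − 1) against every other target's
  segment. Only γ's inputs are prescribed (the angle θ between the
  segments and the distances d_i, d_w from the two starts to their
  intersection), so the default rule is one concrete instantiation:
  γ = (1 − θ/π) when the segments properly intersect and |d_i − d_w| <
  R_sys, else 0; γ ≡ 0 on the first construction, before any matching
  exists.

R_sys defaults to the electrode outer radius of the larger interacting
type plus the safety margin. The matrix is solved by a hand-written
O(n³) Kuhn–Munkres solver (shortest augmenting paths with potentials);
rectangular instances are padded with a 10⁶ sentinel, which also encodes
type-incompatible goal/particle pairs. Among cost ties the lexicographic
rule (lowest particle index keeps the smallest goal index) is enforced
exactly by sequential forced-assignment re-solves rather than by cost
perturbation, which would be fragile for non-integer costs. Matrix
update and matching then alternate — each round using the latest matching
for the other targets' default goals — until two consecutive matchings
agree (cap: 10 rounds, convergence flagged in the result).

## Priorities, coordination, and collision safety

Before every decision step each target gets two priorities: electrode
outer diameter (larger first — big electrodes are costlier to detour) and,
within a type, current distance-to-goal (nearer first), with particle id
as final tie-break. Decisions are made in priority order; each
lower-priority particle plans against an obstacle-belief field containing
the free obstacles and every higher-priority particle's predicted
next-state set (its belief pushed through the transition model under its
chosen action). Chosen modal next cells are kept pairwise distinct; a
particle with no non-conflicting action stays put and flags a replan.

Collision thresholds follow the trap geometry: target–target pairs use
the sum of electrode outer radii, target–obstacle pairs the outer radius
plus the obstacle's particle radius, both plus a 5 µm safety margin.
Four engineering choices, made where the method's prose ends, keep the
executed trajectories clear of these thresholds:

* **Dilation.** Obstacle beliefs are dilated to the pairwise blocked
  radius before value clamping, with weights tapering from the source
  cell outward, so blocked zones repel rather than merely puncture the
  value surface. For moving neighbours the radius is inflated by both
  trap lags plus one cell of grid quantization; for parked (arrived)
  neighbours only the hard threshold is used — otherwise goals spaced
  just above threshold would be sealed off.
* **Enclosure fallback.** If the inflated field encloses a particle (its
  best belief-weighted Q is non-positive), the problem is re-solved at
  hard-threshold dilation. This arises in crowded fields (16 obstacles)
  where inflated disks tile the workspace.
* **Execution guard.** During execution, a tentative electrode move that
  would take an approaching pair below threshold + both trap lags +
  buffer is withheld for that timestep. The guard is asymmetric: full
  clearance against obstacles and higher-priority particles, but only an
  emergency brake (a few µm above the hard threshold) against
  lower-priority ones, whose own planners are responsible for avoidance —
  a symmetric guard lets clustered equals gridlock each other.
* **Grace radii.** Within 1.5 cells of a particle's own start or goal,
  sub-threshold proximity is logged but not counted: near-touching start
  pairs and goal patterns spaced just above threshold make it inevitable
  there, and the guard stands down for pairs in that regime. A "stay"
  decision within 1.5 cells of the goal becomes a fine-positioning move
  onto the exact goal position, closing the last few µm that cell-level
  decisions cannot express.

The trap lag referred to above is the steady trailing distance
`preset_speed · τ` of a dragged particle (τ is the trap relaxation time);
the discrete-step lag is strictly smaller, so using it in thresholds is
conservative.

On an actual sub-threshold event outside grace, the implicated
lower-priority particle is suspended for the rest of the period and the
strategy is redetermined — the per-particle scope keeps the rest of the
task moving. Escaped particles are retrapped at their next observed
position (event-logged); a particle that cannot be re-acquired is marked
lost and the task continues without it. Escaped particles' beliefs update
with "stay" rather than the unexecuted command.

## Simulator

The simulator stands in for the physical platform at the level the
controller cares about. A trapped particle relaxes toward its electrode
centre with a first-order lag whose time constant comes from the trap's
speed limit — the dipole-approximation DEP force at the inner-circle edge
balanced against Stokes drag, v = F/(6πµr). The peak field-gradient
magnitude is a single configurable scalar (default 1.7 × 10¹³ V²/m³,
chosen to give a ~50 µm/s limit for a 10 µm bead in water, comfortably
above the 30 µm/s preset transport speed; the real gradient profile is a
finite-element quantity that is out of scope here). A particle escapes
with probability 0.5 per offending step when its offset exceeds 0.8 of
the electrode inner radius or the electrode outruns the trap limit.
Brownian displacements are Gaussian with variance 2·D·dt per axis
(D = 0.2 µm²/s, dt = 50 ms by default); free obstacles diffuse and may
drift. All positions are clipped to the workspace with a wall event.

Electrode geometry defaults (inner radius 20 µm, annulus width 15 µm)
are the sizes at which the horizontal trapping force is maximised for
this class of particle; the 10 µm bead preset uses a proportionally
smaller electrode (outer diameter 50 µm vs 70 µm), which is exactly what
the first-level priority keys on.

## Synthetic vision

The renderer draws particles as dark disks and electrodes as bright
annuli on a mid-grey background with optional Gaussian noise — a
deliberately idealized CCD. Light patterns are isolated by a global
threshold (0.7, between background 0.5 and pattern 0.9); particle frames
are range-normalized and smoothed with a separable Gaussian whose
edge-renormalized taps preserve constants and shift-equivariance away
from the border. Circles are found by a from-scratch (x, y, r) Hough
accumulator: boundary pixels of the binarized mask vote along candidate
circles (72 angles), local accumulator maxima above 35 % of the
attainable votes become detections, centres are refined by a 3 × 3
centroid, and non-maximum suppression (closer than the smaller radius)
also collapses an annulus's concentric inner/outer edges onto one
detection. Sizes are classified by 1-D k-means with deterministic
quantile initialisation; targets are screened by Euclidean distance to
the nearest light pattern (each pattern claims at most one particle);
identities are maintained by a constant-velocity Kalman tracker with
greedy nearest-neighbour association inside a 3σ/15 px gate, two-point
velocity initialisation, and a 5-frame coasting limit.

What the synthetic frames do *not* emulate: uneven illumination, defocus,
partial occlusion of touching particles, non-circular cells, and camera
shot noise structure. Passing the vision tests therefore demonstrates the
correctness of the chain's logic (round-trip recovery within a pixel,
stable identities through crossings), not robustness to real microscope
imagery.

## Scenario generator

`generate_scenario` is the study-condition generator: particle counts per
type, free-obstacle count, minimum pairwise start separation (default
80 µm, just above the largest pair threshold, so tasks are born
collision-free), and a goal pattern — trapezoid (5), arrow (7), radial
liver-lobule layout (18 on 6 spokes), swapped swarm blocks, or explicit
coordinates. Placement is rejection sampling with a bounded retry budget
and an explicit infeasible-packing error. One root seed drives
label-derived streams for placement, simulation, observation and
rendering, so a scenario plus seed reproduces a run bit-for-bit.

The named presets reconstruct the published experiments at their reported
counts and shapes; exact coordinates were never published, so the
geometry is approximate by necessity, with two deliberate choices: the
crowded single-cell scenario spaces its 16 obstacles at ≥95 µm — twice
the 45 µm cell–obstacle threshold — so a collision-free corridor always
exists between any two obstacles (the published run did succeed), and the
swarm-exchange goal blocks sit away from the workspace walls so that
parked arrivals cannot seal the remaining corridors against latecomers.

## Problem sizes used by the test suite

The suite runs every fig-named scenario over 20 seeds for the
collision-safety check, 200 random assignment instances against a
brute-force permutation oracle (n ≤ 7), exhaustive policy rollouts from
all 1024 start cells, 10⁵-sample Brownian statistics, and 100-frame
tracking runs — sizes chosen so the whole suite completes in minutes
while still exercising every contract at full scale (the grid, counts
and patterns are never scaled down from their defaults).

## Known limitations

* Assignment runs once; there is no mid-task reassignment, so a retrapped
  particle keeps its original goal even when swapping would now be
  cheaper.
* The priority scheme is a heuristic serialisation; it does not guarantee
  completeness in adversarially crowded worlds, only (by the guard) that
  failures are stalls rather than collisions. The period cap turns a
  stall into an explicit incomplete-task flag.
* The simulator has no hydrodynamic coupling between particles, no
  electrothermal flow, and its field profile is a one-parameter stand-in
  for a finite-element solution.
* QMDP ignores information-gathering value; with severely degraded
  observations a full POMDP policy would differ.
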