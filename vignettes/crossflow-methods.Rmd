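---
title: "Methods: flow, tracing and surrogate models for cross-junction particle sorting"
author: "crossflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow, tracing and surrogate models for cross-junction particle sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modeling problem

Microfluidic cell sorters are, to a good approximation, networks of straight
rectangular channels joined at right-angle cross junctions. In a straight
channel a small particle rides its streamline at a fixed lateral position,
so all of the interesting routing happens at the junctions: which arm a
particle leaves through, and where across that arm, depends on the particle
diameter, the channel width, the seed position, and the balance of port flow
rates. `crossflow` models this unit — a four-port cross with the West port
fixed as inlet-only — end to end: a finite-difference Stokes solver and a
drag-law particle tracer provide the physics; a randomized case generator
turns traced trajectories into training records; a chained dense network
learns to predict trajectories instantly; and a resistor-network composer
assembles whole-chip paths from per-unit predictions.

Sign conventions: port rates are signed mean velocities in cm/s, positive
into the junction. With equal arm widths, mass conservation is `qW + qN +
qE + qS = 0`. Because the West port never carries outflow, the outflow
pattern of the other three ports determines the fluid behavior; of the
`2^3` sign patterns the all-inflow one is impossible, leaving exactly seven
flow cases. Only the case with North as the sole outlet has a fixed
conventional id (case 1); the remaining six are ordered by the binary value
of the (N, E, S) outflow flags. This internal ordering is a package
convention, not an externally fixed table.

## Flow solver

The channels are treated as a 2-D planar domain: width is the only
transverse dimension anywhere in the case parameterization, and depth never
enters the features or targets. The sampled ranges (port speeds up to
2 cm/s, widths 50–200 μm, water) put the Reynolds number below about 4, so
the solver drops inertia entirely and solves steady incompressible Stokes
flow. This is a deliberate modeling decision: at `Re <= 4` the neglected
convective term perturbs the field by a few percent at most in this
geometry, and the Stokes system is linear — which the implementation
exploits aggressively (below).

Discretization is a MAC staggered grid over a masked "+"-shaped domain:
pressures at cell centers, velocity components on faces, 5-point Laplacians
with ghost-cell reflection for tangential no-slip, and a direct sparse LU
factorization (`Matrix::lu`) of the coupled velocity–pressure system. With
velocities prescribed on every open boundary the pressure is only
determined up to a constant, so one reference cell is gauged to zero. Port
velocity profiles are fully developed parabolas with the prescribed mean —
a plug profile would contradict no-slip at the port corners — and each
discrete profile is rescaled so its *discrete* mean equals the prescribed
rate exactly, which makes global mass conservation exact rather than
`O(h^2)`.

Two structural facts collapse the cost of the data-generation campaign:

* **Scale invariance.** In Stokes flow the velocity field on a cross of
  width `W` is the unit-width solution with coordinates stretched by `W`.
  One factorization per grid resolution serves every sampled width.
* **Linearity in the boundary rates.** Any conserving rate vector is a
  linear combination of three conserving basis cases (W→E, N→E, S→E at
  unit rate). The solver factors once, solves three right-hand sides, and
  every subsequent case is a superposition — microseconds instead of a
  fresh solve per case.

The default grid for refinement checks is `h = W/40`; data generation uses
`h = W/24`, a documented desk-scale compromise validated by the
mesh-independence report (field changes decrease under refinement and the
observed convergence order against the plane-Poiseuille closed form
exceeds 1). Validation anchors: the two-port case reproduces plane
Poiseuille to well under 1% at `W/40`; discrete divergence is at direct-
solver rounding (~1e-10 of `U/W`); port fluxes are exact by construction.

## Particle tracer

Particles follow the Stokes-drag equation of motion
`dv/dt = (u(x) − v)/τ_p` with relaxation time `τ_p = ρ_p D_p² / (18 μ)`.
For 1–20 μm particles in water τ_p is 0.06–23 μs against transit times of
~0.1–10 s — Stokes numbers around 1e-6. An explicit Runge–Kutta scheme
would be stability-limited to microsecond steps, so the tracer instead
uses a second-order *exponential* integrator: over each step the fluid
velocity is frozen (then midpoint-corrected) and the stiff relaxation mode
is integrated exactly. In a uniform field this reproduces the closed-form
`1 − exp(−t/τ_p)` relaxation to machine precision, which is exactly what
the validation suite asserts. The adaptive step targets a fixed fraction
(default 0.2) of a grid cell per step.

Design choices the underlying physics does not pin down, and how they were
fixed:

* **Release velocity** defaults to the local fluid velocity; releasing
  from rest only adds a ~μs transient that is invisible at trajectory
  scale (the suite shows a density change from 1050 to 2000 kg/m³ moves
  the exit position by under 1e-4 relative). A `release = "rest"` control
  exposes the transient for validation.
* **Particle density** defaults to 1050 kg/m³, typical of biological
  cells; it is immaterial at these Stokes numbers.
* **Wall contact** is finite-size: a particle freezes where its
  center-to-wall distance reaches `D_p/2` (located by bisection), which is
  the mechanism by which diameter influences outcomes. Center-point
  contact was the alternative; surface contact was chosen as the
  physically meaningful reading of a freeze wall.
* **Seeding**: releases place `n = 10` particles evenly across the
  admissible span `[D_p/2, W − D_p/2]` of the inlet, endpoints included.
  Endpoint particles start exactly at contact distance and freeze whenever
  the local flow curves them wallward; frozen counts are reported so this
  bias stays visible.

## Dataset generator

Each random case draws width uniform on 50–200 μm, diameter uniform on
1–20 μm, an outlet count of 1–3 with outlet ports drawn among {N, E, S},
inflow rates uniform on 0–2 cm/s, all but one outflow uniform on 0–2 cm/s,
and closes the last outlet by conservation; closures that are negative or
exceed 2 cm/s are rejected and redrawn. Every inlet port releases 10
particles. Exited trajectories are split at their two crossings of the
junction square into entrance, middle and exit parts. "The first ten
points" of each part is not well defined for an adaptive integrator, so
the package resamples each part to 10 points at equal arc-length fractions
(endpoints included) — resolution-independent, idempotent, and exactly 60
coordinates per record. Frozen and timed-out trajectories are excluded
from records (their exit segment is undefined) and counted.

Features are `(D_p, W, x0, y0, qW, qN, qE)`; `qS` is recoverable by
conservation. Features and targets are min–max scaled by the *fixed*
sampling ranges (coordinates by the 500 μm half-extent of the widest
domain), never by realized data, so any two datasets share one scale and
the mapping inverts exactly.

What the generator emulates — randomized rectangular cross junctions under
creeping flow with finite-size drag-coupled particles — and what it does
not: Brownian motion, lift forces, particle–particle interaction, 3-D
depth effects, fabrication roughness, and polydisperse mixtures. Passing
tests therefore demonstrate fidelity to the stated transport model, not to
any particular wet-lab device.

## The chained surrogate

The surrogate is three fully connected blocks in a chain, each with five
hidden layers of 400 units and linear input/output layers: block 1 maps
the 7 features to the 10-point entrance segment (20 outputs); blocks 2 and
3 take the features concatenated with the upstream segment (27 inputs) and
emit the middle and exit segments, for 60 outputs in total.

Training choices, and why:

* **Loss and metric.** Summed MSE of the three blocks in normalized
  coordinates; accuracy is the pooled coefficient of determination R² over
  all 60 output dimensions of the evaluation set (a per-dimension-averaged
  R² is also reported). Because all 60 targets share one coordinate scale,
  pooled R² is identical in normalized and physical units.
* **Chained training.** The chain could be trained with teacher forcing
  (downstream blocks fed ground-truth segments) or chained (fed their own
  upstream predictions, with gradients flowing through the whole chain).
  Teacher forcing optimizes a regime the model never sees at inference,
  and at desk scale the exposure mismatch costs several R² points on the
  held-out set; the default is therefore fully chained training, with
  teacher forcing and a warmup curriculum exposed as options.
* **Optimizer.** Minibatch Adam (batch 256, learning rate 1e-3 with cosine
  annealing) in single precision — the standard arithmetic for dense
  network training; ~6000 parameter updates at the default budget. The
  split is 70/30 at the *case* level, stratified by flow case, so no
  intersection contributes records to both sides — the stricter reading of
  a train/test split.
* **Determinism.** One seed fixes initialization, split and batch order;
  identical configurations give identical histories.

### Desk-scale study conditions

The reference accuracy study at full scale uses hundreds of thousands of
simulated trajectories and a 50,000-epoch budget. The package's study —
what `scripts/acceptance.R` and the acceptance tests run — uses 1500
random intersections (~22,000 trajectory records after exclusions) and 80
minibatch epochs per activation arm, the largest campaign that runs
comfortably on a single desktop core; the activation comparison covers
Leaky ReLU, ReLU, Sigmoid and Tanh under matched data, seeds and budget.
At this scale the held-out pooled R² of the Leaky ReLU arm lands within a
couple of percentage points of the full-scale figure, with the same
activation ordering; the residual gap is a genuine small-data effect
(hundreds rather than many thousands of distinct intersections to
generalize across, and exit-segment targets that jump discontinuously when
a seed crosses an outlet separatrix).

## Chip composition

A chip is an orthogonal channel graph. Straight runs joined at degree-2
nodes merge into straight units; internal nodes of degree 3–4 are
intersections (T-junctions are crosses with the missing arm's rate pinned
to 0). Segment flow rates come from the electrical analogy: hydraulic
resistance `R = 12 μ L / W³` per unit depth (planar Poiseuille, consistent
with the 2-D flow model), Kirchhoff balance at nodes with prescribed
terminal fluxes, and a gauged node pressure.

Whole-chip trajectories alternate straight transport (the lateral fraction
ξ, measured from the left wall facing the flow, is preserved — the
defining property of a straight unit) with per-intersection predictions.
At each intersection the particle's arrival arm is relabeled as the local
West port, honoring the West-inlet convention; the local rate vector is
read off the network solution; and the predictor — either the trained
surrogate or the physics oracle, which share one interface — returns the
local 30-point trajectory whose exit arm and position carry the particle
onward. If the predicted exit arm carries *inflow* in the network solution
the composer raises an error rather than silently rerouting; this
inconsistency has no defined physical continuation. Composed paths carry
unit provenance per vertex and report their largest inter-piece gap
(required under 2% of W).

The local intersection model extends each arm 2 widths from the junction
square. Chip edges shorter than 2.5 W are still composable — straight
transport is the identity, so the hand-off lateral position is unchanged —
but the drawn local trajectory can overshoot a short edge's true extent;
the H-chip validation keeps edges at or above this scale.

## Numerical and degenerate-input policy

* Grid coarser than `W/20` is refused; `W/24` is the generation default,
  `W/40` the validation default.
* Junction-square boundary points belong to the square (tie-break).
* Zero-rate ports are treated as closed walls hydraulically (their
  prescribed profile is identically zero) and release no particles.
* A trace in an all-stagnant field terminates at the time cap
  (`50 × domain length / smallest nonzero port speed`) and is flagged
  `MAX_TIME`, never silently dropped.
* Rejection sampling of conservation closures is bounded (1e6 draws)
  and errors loudly if exhausted.
* `R²` on a zero-variance truth set is an error, not NaN.

## Known limitations

Rectangular, 90-degree, equal-width intersections only; creeping flow only
(no turbulence, no inertial migration); 2-D planar transport; trajectory
resolution fixed at 30 points per intersection; surrogate validity bounded
by the sampled ranges (the predictor warns on extrapolation). The
composer's straight-transport identity ignores the lateral redistribution
that occurs within a development length of a junction; the H-chip
composition check against a monolithic whole-chip simulation bounds the
resulting exit-position error at a few percent of the channel width.
At the desk-scale training budget the surrogate's pointwise accuracy is set
by its overall convergence level (residuals of roughly 1.5–3% of the
coordinate scale), so per-point guarantees tighter than that — for example
recovering the seed position to a few percent of one channel width —
require longer training than the default study performs.
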