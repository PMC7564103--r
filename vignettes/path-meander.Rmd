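---
title: "Estimating path meander from trap-grid catch decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating path meander from trap-grid catch decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmeander)
```

## The model

A correlated random walker moves in continuous, unbounded 2-D space in
steps of fixed length (1 unit by default). Its first step follows an
initial heading drawn uniformly on [0°, 360°); before every later step the
heading changes by a turn angle drawn independently from a zero-mean
Gaussian whose standard deviation is the **circular standard deviation
(c.s.d.)** of the walk, in degrees. The c.s.d. is the single behavioural
parameter of interest: it measures path meander, from ranging
(c.s.d. → 0°, near-straight paths that cover distance) to intensive local
search (large c.s.d., tortuous paths that stay put). Draws are wrapped
into (−180°, 180°]; for the c.s.d. range used here (≤ 80°) wrapping is a
negligible correction and the wrapped and unwrapped circular s.d. agree to
well under 1%, so the Gaussian parameter and the circular s.d. are used
interchangeably.

Traps are closed axis-aligned squares (side 2 units by default) that
absorb: a mover whose step segment touches a trap is held there for the
rest of the run and counted against that trap. The capture test is
segment–square intersection, not endpoint membership, so a step that
clips a trap corner still captures; when one segment crosses two traps the
entry point nearest the segment start — the first physical contact — wins.
An endpoint-only mode (`capture_mode = "endpoint"`) is retained for
sensitivity comparisons; it can only miss captures relative to the
segment test. There is no outer boundary of any kind: movers that leave
the trapped region keep walking in open space.

## From catch pattern to meander

Releasing a population just outside one corner of a square trapping grid
makes the *spatial decay of catch* informative about meander. Only the
edge traps on the two edges adjacent to the release corner are used: the
corner trap is T1, and the i-th trap along each adjacent edge joins its
mirror-image partner in index T(i+1) (the release point sits on the grid
diagonal, so the two edges are statistically exchangeable and each pair is
averaged). Catch declines close to exponentially in trap index; ordinary
least squares of ln(mean catch) on index gives the **decay constant k**
(per trap interval). Zero-catch bins are dropped rather than imputed —
ln 0 is undefined and any pseudocount would bias k — and at least three
positive bins are required, otherwise the profile is reported unfittable.
A direct nonlinear fit of a·exp(k·index) to the raw means
(`method = "nls"`) exists for sensitivity analysis; the log-linear fit is
the default because it is the standard "exponential trendline" slope and
the two coincide exactly on noise-free exponentials.

Replicating the corner-release simulation across a grid of c.s.d. values
(default {15, 20, ..., 50}°, 10 replicates of 400 movers × 400 steps
each) and regressing every replicate k on c.s.d. yields the **standard
curve** k = b + m·c.s.d., which is close to linear over this range with
m < 0. The default c.s.d. grid brackets both the band an optimal forager
is expected to occupy (30–50°) and the spread seen in per-replicate field
determinations; the regression uses all replicate points rather than
per-c.s.d. means so that the coefficient covariance reflects replicate
noise (in a balanced design the slope is identical either way). Because
replicate scatter deflates the replicate-point coefficient of
determination even when the mean relationship is almost perfectly linear,
the curve reports both: `r_squared` for the regression of per-c.s.d.
*mean* k (the linearity diagnostic, typically ≥ 0.97) and
`r_squared_replicates` for the all-points regression (typically ~0.8 at
the default noise level).

A measured decay constant k* inverts to ĉ = (k* − b)/m. Its standard
error combines, by first-order propagation, the measurement error of k*
(through 1/m) and the sampling covariance of (b, m); the two components
are reported separately and combined, and estimates outside the calibrated
c.s.d. range are flagged as extrapolated rather than refused.

## Study designs built in

* `scenario_corner_release()` — 5 × 5 grid, spacing 15 units, release on
  the grid diagonal 10 units outside the corner trap's centre. This
  mirrors a mark-release-recapture design in which batches of ~800 marked
  moths are released 10 m outside a 15-m-spaced pheromone-trap grid, with
  1 simulation unit ≈ 1 m and one nightly trapping period equated to a
  400-step run (the same run length the standard curve is built from —
  an assumption of the method, surfaced as the `n_steps` parameter,
  not a derived quantity).
* `scenario_center_release()` — 7 × 7 grid, spacing 20 units, release
  half a spacing along +x from the central trap ("near the centre" but
  outside every trap; the offset is a configurable choice since no exact
  coordinate is defined). About one trap per 300 square units under the
  tight bounding box (294) or 400 under the half-spacing-margin lattice
  convention; `target_density()` reports both conventions since "one per
  300" is itself approximate.
* `scenario_low_density()` — a single trap at the centre of a 1000 × 600
  seeding rectangle (one target per 600,000 square units, a 2000-fold
  dilution), movers seeded uniformly with rejection of the trap square.

`run_capture_sweep()` replicates whole-population simulations across a
c.s.d. grid; `find_optimal_csd()` summarises a sweep as the smallest
tested c.s.d. whose mean capture is within one pooled SEM (root mean
square of the per-point SEMs) of the sweep maximum. That rule reads a
saturating capture curve as "onset of the plateau" while remaining
well-defined for an interior peak; a sweep whose whole range is under one
pooled SEM is reported as having no detectable optimum.

## Randomness, determinism, numerics

All randomness flows through R's RNG, including inside the compiled
stepping loop, so a single integer seed fixes a run bit-for-bit. Wrapper
functions that run many simulations (`build_standard_curve()`,
`run_capture_sweep()`, `generate_field_fixture()`) derive one child seed
per run from the master seed via `sample.int()` under a locally scoped
RNG state, and store the child seeds in their outputs so any replicate can
be replayed in isolation. Turn draws occur mover-by-mover within each
step. Trap intersection uses slab clipping of the step segment against
each trap's closed square; entry parameters are exact to floating point,
and captured movers are frozen at the entry point (so a captured mover's
recorded position always lies on or inside its trap). Inversion refuses
curves with |m| < 1e-12.

## The synthetic field generator

`generate_field_fixture()` emulates the field design: each replicate
releases `release_size` (default 800) walkers at the corner release point
of the 5 × 5 grid for 400 steps, records per-trap integer catches, and
labels replicates with release corners cycling through NW/NE/SW/SE, as
field crews rotate release corners; `orient_to_release_corner()` maps any
corner back to the canonical NW orientation before analysis. Optional
per-trap binomial thinning (`recapture_p`) emulates overall recapture
below 100%; the default is 1 because no field recapture rate is available
to calibrate it. The generator reproduces the sampling structure
(multinomial allocation of catch across traps, integer counts,
corner-rotated bookkeeping) but deliberately not orchard realities —
weather, lure aging, trap saturation, between-night behavioural drift —
so recovery tests on these fixtures demonstrate that the *estimator* is
consistent under the model, not that field data satisfy the model.

## Problem sizes used in tests and the acceptance script

The test suite exercises the full corner-release design (400 × 400, 10
replicates), the full standard curve (8 c.s.d. values × 10 replicates),
end-to-end recovery with 39 synthetic replicates at three true c.s.d.
values, a full-size 12 × 1000 × 2000 saturation check at c.s.d. 50°, and
scaled sweeps (200-mover centre-release, 1000-mover low-density) for the
optimum-location checks. The acceptance script runs the centre-release
sweep at full size (12 runs × 1000 movers × 2000 steps per c.s.d. value)
and the low-density sweep with 10 seeds per point (5000 movers × 3000
steps), a replication level chosen to match the 10-replicate convention
of the standard curve.

## Known limitations

* **Far-field behaviour.** In unbounded space a small fraction of movers
  (~0.5–1% at c.s.d. 50–80° in the centre-release design) crosses the
  grid, drifts beyond ~100 units and never returns within 2000 steps.
  Capture therefore saturates near 99–99.5% rather than at exactly 100%,
  and keeps creeping upward with c.s.d. past 50°. Historical
  monitor-bound simulators may confine or quantize far-field movement;
  this implementation makes the unbounded assumption explicit and
  consistently. Consequences: the plateau-onset rule applied to the
  centre-release sweep typically lands at 60–70° rather than 50°, and no
  c.s.d. achieves literally full capture of 12,000 movers. (Reflecting
  boundaries and modestly enlarged traps were examined and do not change
  this conclusion.)
* **Low-density optimum.** Under the 1000 × 600 single-trap design the
  capture-vs-c.s.d. curve has a broad interior maximum spanning roughly
  20–30°, with the 20° mean slightly above the 30° mean (≈55 vs ≈51
  catches of 5000, SEMs ≈1); the smallest-tied-with-max rule then reports
  20°. Estimates of this optimum are design- and rule-sensitive, and
  lengthening runs or enlarging the arena pushes it lower still.
* The decay analysis ignores interior traps by construction; designs
  whose release is not on the grid diagonal break the edge-pair symmetry
  and are not supported.
* The standard curve is linear by construction over its calibrated range;
  inversion outside [min, max] of the calibration grid is flagged, not
  modelled.
* Two-dimensional movement only: vertical structure, wind and odour-plume
  anisotropy are outside the model; a unit step is a fixed length, with
  no Lévy or variable-speed component.
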