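# pathmeander

Indirect quantification of path meander for small, hard-to-track movers —
insects foraging by correlated random walks — from the spatial pattern of
their catches in a trapping grid.

## The problem and the method

Path meander is the spread of the turn-angle distribution between
consecutive segments of a mover's track, summarised as the circular
standard deviation (c.s.d., degrees) of a zero-centred Gaussian: small
c.s.d. means near-straight "ranging", large c.s.d. means tortuous local
search. For a 1-cm moth flying at dusk, directly videotaping enough track
to histogram its turns is impractical. The indirect route implemented
here:

1. **Simulate** populations of correlated random walkers (unit steps,
   turn ~ N(0, c.s.d.²)) released a fixed distance outside the corner of
   an R x C grid of small square absorbing traps.
2. **Fit** the decay of catch across the edge traps adjacent to the
   release corner: with the corner trap as T1 and equidistant edge pairs
   averaged as T2..Tn, catch falls off exponentially with trap index, and
   the slope of ln(mean catch) on index is the decay constant *k*. High
   meander concentrates catch near the release point (more negative *k*).
3. **Calibrate**: repeating this across a c.s.d. grid yields a linear
   standard curve k = b + m·c.s.d. (m < 0).
4. **Invert** a *k* measured from a real mark-release-recapture grid
   through the curve to estimate the animals' c.s.d., with delta-method
   standard errors combining measurement and calibration uncertainty.

The package also sweeps capture against c.s.d. in two reference designs —
a centre release inside a 7 x 7 grid (high target density, capture
saturating at high meander) and a single trap in a 1000 x 600 seeding
arena (low density, interior optimum) — to frame where an optimal
forager's meander should sit.

## Worked example

```r
library(pathmeander)

# one corner-release experiment: 400 movers, 400 unit steps, c.s.d. 30 deg
sc  <- scenario_corner_release()          # 5x5 grid, spacing 15, release 10 out
sim <- simulate_walkers(sc, csd_deg = 30, n_movers = 400, n_steps = 400,
                        seed = 7)
fit <- decay_from_catches(tidy(sim))
glance(fit)
#> # A tibble: 1 × 5
#>        k intercept r_squared n_bins_used method
#>    <dbl>     <dbl>     <dbl>       <int> <chr>
#> 1 -0.903      4.99     0.979           5 loglinear

# calibrate and invert a field-style decay constant
curve <- build_standard_curve(seq(15, 50, 5), n_reps = 10, seed = 42)
glance(curve)[, 1:3]
#> # A tibble: 1 × 3
#>         m      b r_squared
#>     <dbl>  <dbl>     <dbl>
#> 1 -0.0222 -0.138     0.994
invert_csd(curve, k = -0.99, k_se = 0.02)
#> # A tibble: 1 × 5
#>   csd_deg se_deg se_meas_deg se_curve_deg extrapolated
#>     <dbl>  <dbl>       <dbl>        <dbl> <lgl>
#> 1    38.4   1.13       0.900        0.682 FALSE
```

The fitted `k` of a single 400-mover run scatters around −0.86 with a
replicate s.d. near 0.1; the standard curve's slope says each degree of
extra meander deepens the decay by about 0.022 per trap interval, and a
field decay constant of −0.99 reads back as a meander of roughly 37–38°
with about a degree of standard error.

`autoplot()` methods draw the decay profile, the standard curve, capture
sweeps and field c.s.d. histograms. `generate_field_fixture()` +
`analyze_field()` run the whole loop on synthetic mark-release-recapture
tables, and `inst/cli/meander.R` exposes `simulate`, `sweep`, `calibrate`,
`invert`, `analyze-field` and `make-fixtures` subcommands for shell use.

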