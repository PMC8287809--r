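# mtflex

Measuring the flexural rigidity of microtubules (and other semiflexible
filaments) from thermally fluctuating shapes, for researchers who track
cantilevered filaments by fluorescence microscopy and want to know how
much localization precision, filament length, and stiffness bias the
measurement.

A filament tethered at one end fluctuates like a clamped–free beam. Its
transverse deflection is expanded in the cantilever eigenmodes,

y(s) = Σₙ √(1/L) · aₙ · Wₙ(s/L),

with eigenvalues qₙ solving cos(q)·cosh(q) = −1 (1.875, 4.695, 7.855,
then (n − ½)π). Equipartition fixes the thermal variance of each mode
amplitude,

var(aₙ) = (k_B·T / κ) · (L / qₙ)⁴,

so L⁴/var(aₙ) is proportional to qₙ⁴ with slope κ / k_B·T: fitting that
slope over the low-order modes yields the flexural rigidity κ (N·m²;
persistence length l_p = κ / k_B·T). The package provides

* the mode basis (printed or exact eigenvalues, numerically stable mode
  shapes),
* a fluctuation simulator with defined κ that digitizes coordinates at
  a chosen localization precision (rounding to the nearest 1, 10, or
  100 nm, as sub-pixel trackers and pixel-level tracking do),
* the rigidity estimator: arc-length geometry, midpoint-quadrature mode
  decomposition, and the origin-constrained equipartition slope fit,
* the precision study: the relative measurement error
  1 − κ_meas/κ_set over the L × κ_set × precision design,
* growth statistics: growth-rate fitting from tip traces, Steel–Dwass
  all-pairs rank comparison, and phase segmentation of ordered groups.

## Worked example

Simulate 500 frames of a 10 µm filament with κ = 0.3 × 10⁻²³ N·m²
tracked at 1 nm localization precision, and re-estimate its rigidity:

```r
library(mtflex)
ens <- simulate_ensemble(sim_config(length = 10e-6, kappa = 0.3e-23,
                                    n_frames = 500, precision = 1e-9,
                                    seed = 1))
fit <- fit_rigidity(ens)
summary(fit)
#> Flexural rigidity fit (equipartition mode-variance estimator)
#>   kappa = 3.086e-24 N m^2  (0.309 x 1e-23 N m^2)
#>   modes 1..4, log-space origin fit, T = 298 K
#>   effective length L' = 10 um, 500 frames
#>   R^2 of the equipartition line: 0.99706
#>
#> Per-mode diagnostics:
#>  n      q       q4       var L4_over_var    fitted
#>  1  1.875    12.36 1.058e-18    0.009453  0.009271
#>  2  4.695   485.89 2.551e-20    0.392057  0.364477
#>  3  7.855  3807.02 3.688e-21    2.711282  2.855702
#>  4 10.996 14617.45 9.497e-22   10.529515 10.964777

relative_error(fit, 0.3e-23)
#> [1] -0.02874193
```

The per-mode table shows the equipartition line L⁴/var(aₙ) against qₙ⁴
(the `plot()` method draws it on log–log axes); the recovered κ of
0.309 × 10⁻²³ N·m² is within 3% of the set value. Repeating the same
run at `precision = 100e-9` (one camera pixel) underestimates this
filament's κ by tens of percent — the bias the precision study maps
out. `run_precision_grid(grid_spec())` reproduces the full study, and
`summarize_grid()` reports the per-cell errors with the three
qualitative trends (error grows with the precision grid size, grows
with κ_set, shrinks with L).

For the statistics side:

```r
groups <- list(low = rnorm(20, 1.37, 0.1),
               mid = rnorm(20, 5, 0.1),
               high = rnorm(20, 10.1, 0.1))
cmp <- steel_dwass(groups)
phase_partition(names(groups), cmp)
```

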