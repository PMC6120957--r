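# spindletwist

Tools for quantifying the chirality of the mitotic spindle and estimating
the torques that shape its microtubule bundles.

Microtubule bundles in human metaphase spindles follow left-handed helical
paths around the spindle axis. Helical shapes cannot be produced by linear
forces alone — they require torques. This package is for cell biologists
and biophysicists who trace bundle contours in 3D microscopy stacks and
want to (a) measure each bundle's **helicity** — the average change of its
azimuthal angle per unit height along the spindle axis, in deg/µm, negative
meaning left-handed — and (b) estimate the **twisting moment** `Mx` and
**bending moment** `M = sqrt(My² + Mz²)` acting on each bundle, by fitting
an elastic-rod model to its traced shape.

## The model in brief

A bundle is a thin elastic rod of flexural rigidity κ (default 900 pN µm²,
i.e. ~30 microtubules × 30 pN µm² with free sliding) spanning two pole
spheres of radius *d* = 1 µm whose centres are *L* apart (measured per
spindle). Static force/torque balance of the symmetric two-bundle spindle
fixes the pole reaction force `F = (0, 0, −Mx/d_y)`, the attachment point
`d_y = Mx·L/(2·My)`, `d_z = −d_y·My/Mz`, and one constraint among the
torque components,

    (2d / (Mx·L))² = 1/My² + 1/Mz²,

leaving `Mx`, the attachment `d_y` (equivalently `My`), the sign of `d_z`
and the orientation of the trace about the axis as the free parameters of a
fit. In the small-angle approximation the rod equations are linear with
closed-form solutions (planar C- and S-shapes when `Mx = 0`, twisted 3D
shapes otherwise); an independent numerical boundary-value solver is
included as a correctness oracle. A fit is accepted when the mean squared
transverse residual (the *discrepancy*) is below 0.1 µm².

## Worked example

Build a feasible torque, sample its shape with localization noise, and
recover the moments by fitting:

```r
library(spindletwist)

params <- rod_params(kappa = 900, L = 12, d = 1)
tq <- torque_from_attachment(Mx = -10, d_y = 6/7, dz_sign = 1, params = params)
round(tq$M, 1)
#> [1] -10.0 -70.0 116.5
twist_per_length(tq$M, params)
#> [1] -2.884425   # deg/um, left-handed

set.seed(1)
xs <- seq(0, 12, by = 0.5)                      # 0.5 um plane spacing
yz <- rod_shape(tq$M, params)$f(xs)
trace <- data.frame(x_um = xs,
                    y_um = yz[, 1] + rnorm(length(xs), 0, 0.05),
                    z_um = yz[, 2] + rnorm(length(xs), 0, 0.05))
fit <- fit_bundle(trace, L = 12)
summary(fit)
#> Bundle fit [general]: Mx = -9.89, My = -68.90, Mz = 116.92 pN um
#>   bending moment 135.7 pN um, discrepancy 0.003284 um^2 (pass)
#>   attachment (d_y, d_z) = (0.862, 0.508) um, orientation 0.0 deg
#>   twist -2.83 deg/um over the central window; n = 25 points
#>   small-angle bias estimate: moments overestimated by ~13%
```

The fitted twisting moment (−9.9 pN µm) and bending moment (136 pN µm)
recover the generating torque within the noise, the fit passes the 0.1 µm²
discrepancy criterion, and the per-bundle twist matches the model's
−2.9 deg/µm.

A whole-cohort analysis — synthetic control spindles versus spindles with
the twist-generating motor switched off — runs through the pipeline:

```r
ctrl <- sim_config(n_cells = 3, bundles_per_cell = 20, torque_mode = "twist",
                   twist_mean = -2.5, condition = "control", seed = 1)
stlc <- sim_config(n_cells = 3, bundles_per_cell = 20, torque_mode = "twist",
                   twist_mean = 0, condition = "kinesin5_off", seed = 1)
report <- run_pipeline(pipeline_config(list(ctrl, stlc), seed = 7,
                                       stages = c("helicity", "compare")))
report
#> Spindle chirality report (seed 7 )
#>   [control] Helicity: -2.53 +/- 0.13 deg/um (mean +/- s.e.m.; 60 bundles, 3 cells)
#>   [kinesin5_off] Helicity: 0.01 +/- 0.11 deg/um (mean +/- s.e.m.; 60 bundles, 3 cells)
#>   control vs kinesin5_off: t = -15.16, df = 116.0, p = 2.73e-29 ***
```

Each cell is aligned so its poles sit on the z axis, only points between
0.3 and 0.7 of the normalized spindle length on bundles with mean radial
distance > 1.35 µm enter the helicity statistic, and conditions are compared
with a two-tailed unequal-variance Welch test.

Real trace tables (CSV with columns `cell_id, condition, bundle_id,
point_index, x_um, y_um, z_um` and pole rows `POLE1`/`POLE2` per cell) are
read with `read_traces()`; a `column_map` adapts external layouts.

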