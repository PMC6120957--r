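---
title: "Quantifying spindle chirality: the elastic-rod model, the helicity statistic, and the moment-fitting procedure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spindle chirality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindletwist)
```

## The scientific problem

Metaphase spindles of human cells are chiral: microtubule bundles do not lie
in planes through the spindle axis but follow left-handed helical paths
around it. Linear forces alone cannot produce helical shapes; torques can.
This package implements the quantitative machinery needed to (i) measure the
helicity of traced bundles from 3D microscopy data, (ii) model bundle shapes
as thin elastic rods under pole torques, and (iii) estimate the twisting and
bending moments acting on each bundle by fitting the model to its trace.

## The mechanical model

A bundle is a thin elastic rod of flexural rigidity $\kappa$ spanning two
spheres of radius $d$ (the spindle poles) whose centres are a distance $L$
apart. The coordinate frame is right-handed with $x$ along the pole--pole
axis and the origin at the left pole centre. The left pole exerts a force
$\mathbf{F}$ and a torque $\mathbf{M} = (M_x, M_y, M_z)$ on the rod at its
attachment point $\mathbf{d} = (0, d_y, d_z)$ on the sphere; $M_x$ is the
twisting moment, $(M_y, M_z)$ the bending moments.

Static equilibrium of a minimal two-bundle spindle with two-fold rotational
symmetry about the axis and left/right exchange symmetry fixes everything
except three degrees of freedom. The force reduces to a pure $z$-component
$\mathbf{F} = (0, 0, -M_x/d_y)$ whose lever arm about the axis balances the
twisting moment, the attachment follows from the torque through
$d_y = M_x L / (2 M_y)$ and $d_z = -d_y M_y / M_z$, and, because the
attachment must lie on the sphere ($d_y^2 + d_z^2 = d^2$), the three torque
components satisfy one constraint,
$$\left(\frac{2d}{M_x L}\right)^2 = \frac{1}{M_y^2} + \frac{1}{M_z^2}.$$
A torque with $|M_x L / (2 M_y)| \ge d$ cannot be balanced on the sphere;
`attachment_from_torque()` rejects it as infeasible.

In the small-angle approximation (arc length $\mathrm{d}s \approx
\mathrm{d}x$) the rod equations become linear and admit closed-form
solutions with boundary conditions $y(0) = y(L) = d_y$ and $z(0) = -z(L) =
d_z$; `rod_shape()` implements them, and two twist-free special cases: a
planar C-shape (symmetric, bending $M_z$ only) and a planar S-shape
(antisymmetric, bending $M_y$ only). The torsional rigidity $\tau$ only
rotates the rod cross-section ($\mathrm{d}\phi/\mathrm{d}x = -M_x/\tau$) and
never moves the contour, so it plays no role in fitting; `rod_shape()`
computes $\phi(x)$ when $\tau$ is supplied, for completeness.

Two numerical points deserve mention. First, the trigonometric part of the
general solution is evaluated through product identities
($\cos a - \cos b$ rewritten as a product of sines), which keeps the
evaluation accurate as $M_x \to 0$; below $|M_x| = 10^{-3}$ pN um the code
switches to the planar special cases (the switch value is a pure numerics
choice; shapes are continuous across it to better than $10^{-4}$ um).
Second, `linear_bvp_oracle()` solves the same linear boundary-value problem
by superposition of high-accuracy initial-value integrations, entirely
independent of the closed forms; the two routes agree to better than
$10^{-6}$ um, which is the package's primary correctness check.

### Default parameter values

* $\kappa = 900$ pN um$^2$: a bundle of $\sim$30 microtubules of 30 pN um$^2$
  each, assuming free inter-microtubule sliding. If microtubules were rigidly
  cross-linked the rigidity would scale with the number squared; `kappa` is
  exposed everywhere for that variant.
* $d = 1$ um: the centrosome plus the adjacent region where bundles are
  anchored.
* $L$: measured per spindle as the distance between the two traced pole
  positions, never assumed.

## The helicity statistic

For a traced bundle in the aligned spindle frame (poles on the $z$ axis),
the azimuth $\theta_j = \mathrm{atan2}(y_j, x_j)$ of each point is unwrapped
so successive differences lie in $(-180^\circ, 180^\circ]$, and the helicity
is the least-squares slope of $\theta$ against height $z$, in deg/um.
Negative slopes are left-handed. "Average change of angle with height" could
equally be read as the endpoint angle difference divided by the axial span;
both estimators are implemented (`method = "regression"` /
`method = "endpoint"`), regression being the default because it is robust to
localization noise. The same azimuth-slope estimator, applied to the
analytic shape on a dense grid, defines the model twist
(`twist_per_length()`), so model curves and data are directly comparable;
the end-on angle between the two attachment vectors is exposed separately
(`attachment_twist_angle()`) as a diagnostic.

Only the central part of the spindle, between 0.3 and 0.7 of the normalized
pole--pole distance, enters the statistic, and only bundles whose retained
points keep a mean distance above 1.35 um from the axis (azimuths of
near-axis points are unstable; a hard floor of 0.2 um raises an error).
Interval bounds are closed; the radius thresholds are strict. One subtlety
is worth knowing: a perfectly straight but skew bundle also has a nonzero
azimuth slope. This is not an artefact -- a skew chord genuinely winds
around the axis -- but it means "zero twisting moment" and "zero helicity"
coincide only for bundles whose plane contains the spindle axis, which is
what the symmetric model solutions produce at $M_x = 0$.

Cohort summaries are means with standard errors over bundles (the bundle is
the observation unit; per-cell aggregation is available), and conditions are
compared with the two-tailed unequal-variance Welch test, starred at 0.05,
0.01 and 0.001 with no multiplicity correction.

## Fitting moments to traced shapes

`fit_bundle()` minimizes the discrepancy
$$\frac{1}{N}\left[\sum_j \big(y(X_j) - Y_j\big)^2 + \sum_j \big(z(X_j) -
Z_j\big)^2\right],$$
the mean squared transverse residual at the measured axial positions, and a
fit is accepted when the discrepancy is below 0.1 um$^2$. Free parameters
are $M_x$ and the attachment $d_y$ -- the bending components then follow
from the balance relations, so the sphere constraint holds by construction
-- plus the sign of $d_z$ as a discrete choice and the orientation of the
trace about the spindle axis. For any candidate shape the optimal
orientation has a closed form (the discrepancy is a sinusoid in the
orientation angle), so the optimizer works on the two continuous parameters
with the orientation profiled out. The landscape is multimodal, hence a
coarse grid over $(M_x, d_y, \mathrm{sign}\, d_z)$ seeds Nelder--Mead
refinements of the best starts; the planar C and S branches are linear
least-squares problems solved exactly and compete with the twisted branch,
with ties (within $10^{-10}$ um$^2$) resolved towards the smaller $|M_x|$.
The procedure is deterministic given the configuration. Axial coordinates
slightly beyond the poles (tracking jitter) are clamped to $[0, L]$ with a
warning rather than dropped, so the point counts stay consistent with the
selection rules: bundles enter the fit only with a maximal distance from the
axis above 1 um, at least 12 points, and at least 3 points on each side of
the equatorial plane (taken at normalized height 0.5, the midpoint between
the poles). Whether the original analysis allowed a full 3D re-orientation
rather than a rotation about the axis only is not documented; the package
fits the axial rotation only, which is the degree of freedom the imaging
geometry leaves free after pole alignment.

Cohort moments (`cohort_moments()`) are means with standard errors of $M_x$
and of the bending moment $M = \sqrt{M_y^2 + M_z^2}$ over passing fits.

### The small-angle bias

Linearizing arc length inflates the fitted moments of strongly curved
bundles. The exact solution for a rod under pure bending $(0, 0, M_z)$ with
vanishing forces is a circle of radius $R = \kappa/M_z$;
`small_angle_error_estimate()` therefore generates the small-angle planar
C-shape for a given fitted $M_z$, fits a circle to it (algebraic
least-squares by default; the endpoint/apex three-point circle is available
as `circle = "three_point"`), and reports the relative excess of the fitted
moment over the exact-circle moment $\kappa/R$. The direction of the
comparison matters: fitting the parabola to a given arc, rather than the
arc to a given parabola, weights the mismatch differently and roughly
doubles the apparent error at high curvature; the package fits the circle to
the model shape because the model shape is what the fit actually produced,
and the circle is its exact-solution reinterpretation. At the typical
mid-spindle bending moment (the median $M_z \approx 110$ pN um of the
representative cohort in `example_bundle_torques()`, deflection roughly 2 um
over a 12 um spindle) the overestimate is about 11%; at the curvature of the
outermost C-shaped bundles ($M_z \approx 180$ pN um, deflection 3.6 um) it
reaches about 29%. Fitted moments are reported uncorrected, with the bias
estimate alongside (`$bias_estimate`). Published torque triplets are often
rounded and need not satisfy the sphere constraint exactly;
`torque_constraint_residual()` quantifies the violation instead of
force-fitting such triplets.

## Trace processing and calibration

Stacks of horizontally oriented spindles are brought into the vertical frame
by the cyclic index permutation $I'(i,j,k) = I(k,i,j)$ -- a rotation of the
volume, never a mirroring, which matters because mirroring would flip every
helicity sign. Voxel indices are 0-based and convert to physical coordinates
as $(i \cdot \mathrm{pixel}, j \cdot \mathrm{pixel}, k \cdot \Delta z \cdot
0.81)$: the 0.81 factor corrects the axial step for the refractive-index
mismatch between immersion oil and the aqueous sample and applies to the
acquisition optical axis, i.e. before any reorientation. Pole alignment is a
proper rigid motion (rotation determinant exactly +1) placing the first pole
at the origin and the second on the positive axial axis; pole positions are
required inputs of the trace table (they are determined manually during
tracking), never estimated.

## The synthetic-spindle generator

`generate_spindle_traces()` emulates the deposited data: per cell, a spindle
length drawn from $\mathcal{N}(12, 1)$ um, bundles built from the analytic
shapes at sampled torques, rotated to uniform azimuths, sampled every 0.5 um
along the axis (the acquisition z-spacing), perturbed with isotropic
Gaussian localization noise of $\sigma = 0.05$ um (sub-pixel at 83 nm
pixels; the real tracking-noise structure is unknown, isotropic Gaussian is
a convention), and optionally subjected to a random rigid motion per cell so
pole alignment is exercised. Default cohort sizes (10 cells $\times$ 40
bundles) mimic the experimental cohorts of roughly 400 bundles. Two torque
samplers are provided: `"moment"` draws $M_x \sim \mathcal{N}(-8.4, 5)$
pN um with the attachment $d_y \sim \mathcal{U}(0.3, 0.9)\,d$ (reproducing
the fitted cohort scale, with bending moments near 140 pN um), and
`"twist"` draws a target twist rate (default $\mathcal{N}(-2.5, 1)$ deg/um)
and inverts the model's twist-rate curve for $M_x$. In twist mode the target
is drawn once and only the attachment is resampled when the target is
unreachable there; resampling the pair jointly would silently skew the
realized twist distribution towards stronger twists, a bias the package's
own cohort-recovery checks would (and, during development, did) detect.
The true per-bundle torque, attachment, azimuth and twist rate are returned
alongside the traces.

What the generator does *not* emulate: point-spread-function blur and
photon noise (spots in `generate_voxel_fixture()` are ideal Gaussians),
tracking failures and outliers, bundle-to-bundle interactions, or any
drug-treatment dynamics (conditions differ only through their sampling
parameters). Passing the recovery checks therefore shows that the
estimators and the fitting procedure are correct and unbiased under the
stated noise model, not that they are robust to every pathology of real
microscopy data.

## Validation problem sizes

The shipped test-suite exercises: 50 random feasible torques for the
closed-form/BVP agreement, boundary conditions, balance residuals and
symmetry; noise-free fit round-trips and $\sigma = 0.05$ um per-bundle
recovery on a handful of random torques plus a 60-bundle cohort for the
cohort mean; 10 cells $\times$ 40 bundles for helicity-cohort recovery, and
three further seeded replicates of $\sim$300 bundles; end-to-end mirror
tests on smaller two-cell cohorts. These sizes were chosen so the whole
suite runs in well under a minute while keeping the cohort standard errors
close to the experimental ones.

## Known limitations

* The full nonlinear Kirchhoff boundary-value problem in 3D is out of scope;
  the circular-arc construction above is the only exact-solution contact,
  and fitted moments carry the quantified small-angle bias.
* The reader for the deposited external tables is configurable
  (`read_traces(column_map = ...)`) because their exact layout, and whether
  they include pole rows and condition labels, is not fixed; reproduction of
  the published cohort numbers requires that download.
* Helicity values are treated as linear quantities after unwrapping; no
  circular statistics beyond that, and no multiple-testing correction, are
  applied.
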