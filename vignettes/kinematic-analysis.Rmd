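---
title: "Kinematic analysis of monocot leaf growth zones with growkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematic analysis of monocot leaf growth zones with growkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growkin)
```

## The model

A steady-state growing monocot leaf is treated as a one-dimensional flow of
cells along the axis `x` (cm from the leaf base). Cells are born in the
meristem, expand through the elongation zone and exit the growth zone at
their mature length. During steady-state growth the cell-length profile
`l(x)` (um) is stationary and the flux of mature tissue out of the growth
zone equals the leaf elongation rate (LER, mm/h). Three measured datasets
determine everything else:

* **leaf lengths over time** give LER; under steady state any interval mean
  estimates it;
* **cell lengths vs position** give, after smoothing, `l(x)` and hence the
  linear cell density `1/l(x)`;
* **meristem length** `L_mer` (um, measured by nuclear staining) locates
  the boundary between division and pure expansion -- it is an input, never
  an inference.

The derived parameters follow the classical chain. With `x_gz` the
growth-zone end and `l_mat` the mature cell length:

* cell numbers are integrals of the density,
  `N_[a,b] = \int_a^b dx / l(x)`; `N_mer` over `[0, L_mer]`, `N_el` over
  `[L_mer, x_gz]`;
* cell production rate `P = LER / l_mat` (cells/h): every `l_mat` of new
  mature tissue is one cell;
* cell division rate `D = P / N_mer` (cells/cell/h): at steady state the
  meristem's `N_mer` cells jointly produce the entire flux;
* cell cycle duration `T_c = ln 2 / D`;
* time in the meristem `T_mer = T_c log2(N_mer)`: a cell traverses a
  meristem of `N` cells in `log2 N` doublings;
* time in the elongation zone `T_el = N_el / P`;
* mean relative elongation rate `R_el = ln(l_mat / l_div) / T_el`, where
  `l_div = l(L_mer)` is the length of cells leaving the meristem.

These definitions force a set of identities (`L_gz = L_mer + L_el`,
`N_gz = N_mer + N_el`, `P = D N_mer`, `T_c D = ln 2`, `T_el P = N_el`,
`R_el T_el = ln(l_mat / l_div)`) that every output row satisfies to
floating-point accuracy; the test suite asserts them across hundreds of
random scenarios.

## Leaf elongation rates

`calculate_ler()` forms one rate per interval between consecutive
*non-missing* measurements: a missing value merges its two bracketing
intervals, so the merged rate is automatically the duration-weighted mean
of the rates it replaces. Time is exact minute arithmetic in hours; nothing
is rounded to whole days.

The per-plant mean uses the first `n_LER_for_mean` intervals (default 2,
matching a design with three daily measurements before dissection). The
default mean is the plain arithmetic mean of the interval rates, which for
equal intervals coincides with total growth over total time; for unequal
intervals the two differ, and `time_weighted = TRUE` switches to total
growth over total elapsed time. We default to the arithmetic mean because
the per-interval rates are the quantity the user is asked to inspect for
steady-state behaviour, and their plain mean is what a table of those rates
suggests.

Negative rates are computed as-is but flagged: they are physically
impossible and almost always indicate data-entry error. Plants with fewer
than two usable measurements appear in the output with a missing mean
rather than vanishing silently.

## Smoothing the cell-length profile

`fit_cell_profiles()` fits, per plant, a local-linear kernel regression
(Gaussian kernel) of cell length on position, evaluated on the regular grid
`0, d, 2d, ...` (default `interval_in_cm = 0.1`, i.e. a fitted value every
millimetre) up to the largest measured position rounded down to the grid.
Local-linear regression is used because it reproduces linear trends exactly
at any bandwidth and has no first-order boundary bias -- both properties
matter at the leaf base, where the kinematics needs the meristem region.

The bandwidth is selected per plant by the direct plug-in method of
Ruppert, Sheather and Wand (1995): blockwise quartic pilot fits (block
count by Mallows' Cp) estimate the residual variance and the derivative
functionals; a pilot bandwidth tuned for second-derivative estimation gives
a kernel estimate of `theta_22 = \int m''(x)^2 f(x) dx`; the variance is
re-estimated from a local-linear fit with its own plug-in bandwidth; and
the final bandwidth is `h = (sigma^2 (b-a) / (2 sqrt(pi) theta_22 n))^(1/5)`.
The implementation solves the weighted least squares problem directly at
each evaluation point (no binning) and agrees with the binned reference
implementation in the KernSmooth package to a few percent on typical data;
the test suite cross-checks the two.

Tunables, with units and defaults:

* `bw_multiplier` (dimensionless, default 1) scales the selected bandwidth.
  Whether a fit is too strict or too smooth is a judgement made from the
  diagnostic PDF (`render_fit_report()`), not automated: multipliers below
  1 track local variation (noise) more, above 1 smooth more, and the
  report's per-plant pages are the instrument for choosing.
* `alternative_bw` (cm, default 0.5) is the fallback for plants whose
  selection degenerates (too few points, zero residual variance, singular
  pilot fits). Failure is a first-class return value, not an error. The
  multiplier is deliberately **not** applied to the fallback: it replaces
  the *calculated* value, so it is taken as the user's final choice.
  `mean_bandwidth()` of the successful plants is usually a good value.
* `interval_in_cm` (cm, default 0.1) sets the evaluation grid.

Numerical choices:

* **Effective-bandwidth floor.** The Gaussian-kernel fit is undefined where
  the kernel covers fewer than two distinct positions, so evaluation uses
  an effective bandwidth no smaller than half the largest gap between
  adjacent distinct sampling positions. The floor only engages when the
  selected bandwidth is below the sampling resolution -- in practice for
  (near-)noise-free data, where it makes the fit interpolatory, which is
  the correct limit.
* **Derivative.** The first derivative shown in the report and stored in
  the profile is obtained by central finite differences of the fitted grid
  values (one-sided at the ends). On the default 1 mm grid this is stable
  and directly testable against the grid values; a degree-2
  local-polynomial derivative estimator is available via
  `derivative = "local_quadratic"` for users who want a smoother estimate.
* **Grid anchors and extrapolation.** The grid starts at 0 (the kinematics
  needs the meristem region, and the first measurements typically sit
  within a millimetre of the base) and grid points outside the measured
  range are flagged `extrapolated`. Fitted values that come out
  non-positive (possible far into an extrapolated tail) are set to missing
  with a warning rather than poisoning the density integral silently.
* **Report semantics.** Plants whose selection failed are drawn as raw data
  without a curve in the PDF (and produce a gap in the final
  bandwidth-per-plant page); the fallback bandwidth is an extraction
  convenience, not a fit worth evaluating. One caution on reading the
  plots: total variation of the fit decreases with the bandwidth over the
  practical range, but not indefinitely -- in the infinite-bandwidth limit
  the fit is the global least-squares line, whose total variation can
  exceed that of a moderately smoothed monotone profile.

## The kinematic step

`kinematic_analysis()` joins the three per-plant inputs by plant ID and
runs the chain above. Its two conventions are pinned in
`kinematic_config()`:

* `mature_fraction` (default 0.95): the growth zone ends at the first grid
  position whose fitted cell length reaches 95% of the profile maximum,
  and the mature cell length is the mean of the fitted values from there
  on. The 95%-of-maximum criterion is the convention of the kinematic
  methodology literature; it is configurable because shallow profiles can
  warrant a stricter fraction.
* `integration_rule` (default `"trapezoid"`, alternative `"midpoint"`):
  the quadrature for `\int dx / l(x)` on the grid, with linear
  interpolation of `l` at non-grid endpoints (the meristem boundary is
  rarely a grid point). On the default 1 mm grid the two rules agree to
  well under 0.1% for realistic profiles, which is far below biological
  variation between plants.

Degenerate cases are handled explicitly: a profile already mature at the
base has no growth gradient and errors; a meristem longer than the growth
zone names the plant in its error; `N_mer < 1` or a non-positive
production rate reports the division-related parameters as missing (with a
warning) instead of emitting infinities. Per-plant failures are collected
in a `failures` attribute while the remaining plants are still computed.

## The simulator and what passing tests mean

`growth_zone_scenario()` fixes a true profile `l*(x)` (logistic by
default, rising from `l_init` through `l_div` at the meristem boundary
towards `l_mat`; piecewise-exponential and step shapes are available), a
true LER, a meristem length, and the measurement design.
`ground_truth()` evaluates the same equation chain on the analytic
profile, using adaptive quadrature split at profile breakpoints, so
piecewise profiles are integrated exactly; it is the independent oracle
for every end-to-end test.

The default scenario mirrors a maize-like setting chosen once as
realistic: 7 dissected plants; LER 2.5 mm/h; meristem 15 mm; cell lengths
15 -> 45 -> 120 um with the growth zone ending near 5 cm of a 10 cm
sampled region; 5 cells measured every millimetre with additive Gaussian
noise of SD 6 um (floored at 1 um so lengths stay positive; a
multiplicative log-normal option exists); five daily leaf-length
measurements with additive SD 2 mm. Treatment-comparison checks use 15
plants per group, the typical number of plants tracked per treatment.

The simulator emulates measurement noise, irregular and missing time
points, and per-plant bandwidth failure -- it does not emulate real
features such as between-plant profile variability, non-steady growth,
position-registration error in the microscopy, or the epidermis/inner
tissue discrepancy. Passing recovery tests therefore demonstrates that the
estimation chain is unbiased and accurate under its own assumptions, not
that those assumptions hold for any particular dataset.

Problem sizes used by the validation suite, chosen to keep every oracle
comparison sharp: 200 random scenarios for the identity suite; 50
instances of up to 30 points for the brute-force fit comparison; sample
sizes 100--3200 for the bandwidth-decay check (the plug-in rate
`h ~ n^(-1/5)` appears as a log-log slope near -0.2); and a step-profile
worked example evaluated on a 2e-7 cm grid, where the discretisation error
of the density integral is below 1e-6 relative, so the full 15-parameter
chain can be checked against closed forms.

## Limitations

* Steady state only: time-dependent profiles (non-steady growth) are out
  of scope; for such organs the LER and profile-fitting steps remain
  useful but the kinematic step is not valid.
* The meristem length is a measured input; no attempt is made to infer it
  from the profile.
* The analysis represents the leaf by a single cell file (typically
  epidermal); zone sizes may differ slightly from whole-tissue readouts
  because inner tissues keep dividing after the epidermis stops.
* Statistical comparison across treatments (means, standard errors,
  tests) is presentation-level work left to the user;
  `ler_inhibition()` covers only the common percent-inhibition summary of
  elongation rates.
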