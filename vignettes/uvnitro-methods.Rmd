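---
title: "Methods: UV spectroscopic nitrate, nitrite and salinity by PLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UV spectroscopic nitrate, nitrite and salinity by PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvnitro)
```

## The measurement problem

Nitrate, nitrite and the major sea-salt ions all absorb in the deep UV
(roughly 200–240 nm), with heavily overlapping bands, and chromophoric
dissolved organic matter (CDOM) adds a smooth quasi-exponential background
on top. A single-wavelength reading therefore cannot separate the species;
`uvnitro` treats the whole 200–300 nm scan (1 nm grid, 3 cm cuvette by
default) as a multivariate measurement and deconvolves it.

The forward picture is Beer–Lambert mixing:

$$A_\lambda = b\,(\varepsilon_{NO_3^-\!,\lambda} C_{NO_3^-} +
\varepsilon_{NO_2^-\!,\lambda} C_{NO_2^-} +
\varepsilon_{sal,\lambda}\, S) + A_{CDOM}(\lambda) + \epsilon_\lambda,$$

with pathlength $b$ (cm), molar absorptivities $\varepsilon$
(L mol⁻¹ cm⁻¹ for the ions, psu⁻¹ cm⁻¹ for salt), and the CDOM term
*outside* the pathlength factor because it is an empirical absorbance of
the sample, fitted rather than dosed. Concentrations are user-facing in
μM and converted to mol L⁻¹ internally.

## CDOM background correction

CDOM absorbance is modelled as
$A_{CDOM}(\lambda) = A_{CDOM}(\lambda_0)\,e^{S(\lambda_0-\lambda)} + k$
with reference wavelength $\lambda_0 = 300$ nm, spectral slope $S$
(nm⁻¹) and an offset $k$ collecting cuvette scattering and instrument
drift. The parameters are estimated per spectrum over 275–295 nm — where
the analytes are spent — and the fitted curve is subtracted across the
spectrum (`correct_cdom()`); equivalently, only the modeling window
matters for the downstream regression. The correction is applied uniformly
to calibration standards and unknowns: standards prepared from natural
seawater contain CDOM too. The full fitted curve, including $k$, is
subtracted.

Numerical choices that matter here:

* The additive $k$ breaks log-linearity, so the fit is true nonlinear
  least squares (Levenberg–Marquardt via `minpack.lm`), initialized from a
  log-linear regression of $\log A$ that treats $k \approx 0$. Initializing
  instead from the window minimum grossly overestimates $S$ (the 295 nm
  absorbance is nowhere near the asymptote) and strands the optimizer on a
  ridge.
* Over a 21-point window the three parameters are nearly collinear:
  families with large $S$, small amplitude and a big offset reproduce the
  window to within ordinary photometric noise but explode when
  extrapolated 60–80 nm to the analytical window. The slope is therefore
  bounded to $[0.001, 0.1]$ nm⁻¹ and the offset to $|k| \le$ `k_max`
  (default 0.01 AU — a scattering/drift term is a few mAU, not a free
  baseline). Degenerate windows (no positive dynamic range) raise an error
  telling the caller to skip the correction; `correct_cdom()` does exactly
  that, per spectrum, with a warning.
* Extrapolation amplifies whatever error the fit retains by roughly the
  factor $e^{S(\lambda_{fit}-\lambda)}$, i.e. ~30× at 215–240 nm. At the
  default noise (5×10⁻⁴ AU) the corrected spectra carry a smooth residual
  of order 0.01 AU there. This residual is structured (a low-dimensional
  family of near-exponentials) and is largely rejected by the PLS factors;
  it is the dominant error floor of the whole method, which is why the
  detection limit is set by replicate scatter rather than photon noise.

## PLS calibration and factor selection

Mean-centered spectra $X$ and compositions $Y$ are decomposed by NIPALS
($X = TP^\top + E$, $Y = UQ^\top + F$), each factor maximizing the
covariance between the $X$ and $Y$ scores. No variance scaling is applied
to $Y$: the pooled cross-validation error of the joint model must equal
the sum of the per-response errors in original units, which variance
scaling would destroy. PLS2 fits the three responses jointly; PLS1 fits
one model per response. The NIPALS inner loop converges the weight vector
to 1e-12 (500 iteration cap) and starts deterministically from the
largest-variance response column, so fits are reproducible bit for bit.

The factor count is chosen by leave-one-out cross-validation
(`loo_cv()`). Every fold refits from scratch, *including the centering
means* — anything else leaks the held-out sample. Per factor count $h$ we
report PRESS$_h$ (cross-validated error sum of squares), RESS$_h$ (the
full-data fitted residual), and
$Q^2_h = 1 - \mathrm{PRESS}_h/\mathrm{RESS}_{h-1}$ (undefined at $h=1$).
A factor is significant while $Q^2_h \ge 0.0975$; the threshold is
$1 - 0.95^2$, i.e. the cross-validated error must undercut 95 % of the
previous residual on the RMS scale.

The scan over $h = 2, 3, \dots$ tolerates sub-threshold $Q^2$ values
*before* the first significant factor and stops at the first failure
*after* one. The tolerance clause matters in practice: with three strongly
overlapping absorbers the first one or two factors can be individually
"insignificant" by the ratio test while the model is still far from
complete (the published cross-validation sequences for this chemistry show
exactly that pattern: $Q^2_2 = 0.02$ for nitrite, yet four factors are
clearly supported and selected). A sequence that never reaches the
threshold selects one factor.

```{r factors}
selected <- vapply(table2_cv(), function(m) select_factors(m$q2), integer(1))
selected
```

Four factors for all three single-response models and the joint model —
three chemical components plus one factor absorbing the residual CDOM
structure.

## Wavelength selection

`ipls_screen()` scores sliding 16-point windows advancing by 10 nm over
200–300 nm (the final window is clipped to end at 300 nm, reproducing the
conventional irregular last interval). Each window gets its own
cross-validated factor count, and is scored on a prediction set by RMSEP,
R² and mean relative error per response; the pooled score averages RMSEP
normalized by each response's calibration range, since μM and psu are not
commensurable. `refine_window()` then hill-climbs the two boundaries in
1 nm steps, accepting only strict improvements, with a full audit trail.
Scoring against the prediction set mirrors standard practice for this
chemistry; `use_cv = TRUE` offers the leakage-free alternative that scores
by calibration LOO error instead.

## The CLS baseline

`fit_cls()` fits the full forward model — three known absorptivity curves
plus the CDOM exponential — to one spectrum at a time. Only the CDOM slope
enters nonlinearly, so the problem is solved by variable projection: scan
the slope over [0.005, 0.05] nm⁻¹, solve the remaining five linear
parameters exactly at each slope, and polish the best slope by
golden-section search. No multistart, no randomness. Concentrations are
deliberately not constrained non-negative, matching the PLS side (a
near-zero true concentration legitimately predicts slightly negative).

The CLS window defaults to 200–240 nm, not the 215–240 nm PLS window: with
five free parameters the narrow window's design matrix has condition
number ~1.6×10⁵ and ordinary noise then dominates the solution, while
200–240 nm anchors both the analyte bands and the CDOM curve.
Absorptivity curves come from single-component standards
(`build_library_from_standards()`), estimated per wavelength by
zero-intercept least squares against concentration.

## The synthetic-data generator

No spectra are deposited for this chemistry, so validation runs on a
forward simulator (`simulate_dataset()`) that emulates the statistical
structure the analysis assumes:

* surrogate absorptivity shapes (`default_library()`): Gaussian bands for
  nitrate (205 nm, σ 11 nm, peak 9600 L mol⁻¹ cm⁻¹) and nitrite (210 nm,
  σ 13 nm, peak 5400), and an exponential sea-salt edge (0.02 psu⁻¹ cm⁻¹
  at 200 nm, decay 8 nm). These are generator plumbing chosen to overlap
  strongly over 200–240 nm, not calibrated constants; every acceptance
  claim is about recovering known simulated truth, never about these
  numbers;
* per-sample CDOM drawn uniformly from a0 ∈ [0.01, 0.1] AU at 300 nm,
  S ∈ [0.014, 0.03] nm⁻¹, k ∈ [0, 5] mAU — typical coastal magnitudes and
  275–295 nm slopes; these ranges are configuration, not fact;
* additive homoscedastic Gaussian noise, default 5×10⁻⁴ AU (typical
  dual-beam photometric noise), fully seed-controlled;
* the published 34 + 20 sample composition design (`table1_design()`).

What the simulator deliberately omits: stray light and detector
nonlinearity (absorbance saturation), temperature dependence of the
bromide band, turbidity, and any departure of CDOM from a perfect
exponential. Two consequences for interpreting green tests:

* On synthetic data the information-optimal wavelength window hugs the
  band maxima (~200–225 nm), because nothing punishes the short
  wavelengths. On real seawater the 200–215 nm region is degraded by
  very high salt/bromide absorbance and saturation, which pushes the
  practical optimum to ~215–240 nm. Window-screening results on the
  simulator therefore validate the *mechanics* of interval screening, not
  the field-optimal window.
* The simulated CDOM is exactly the family the CLS model fits, so CLS is
  unrealistically strong here: its real-world weakness against unknown
  absorbers and imperfectly exponential CDOM is only partially reproduced
  by injecting a synthetic interferent band.

## Degenerate inputs and other conventions

* Grids must be strictly increasing and uniform; descending instrument
  exports are re-sorted on read with a message. Window bounds must lie on
  the grid — no silent snapping.
* Pathlength is a property of the spectrum; mixed-pathlength operations
  require an explicit `rescale_pathlength()`.
* Mean relative error uses per-term absolute values by default (it is a
  minimized quantity in window screening); a signed mode is kept for bias
  analysis. Samples with a true value of zero are excluded from the ratio
  and counted in the report.
* Replicate precision statistics (LOD = 3×SD, RSD) use the n−1 sample
  standard deviation, the analytical-chemistry convention.
* Cross-validation problem sizes in the test suite follow the published
  design (34 calibration, 20 prediction samples, up to 7 factors);
  screening studies use 20 noise seeds and the method-comparison study 50
  paired simulations.

## Known limitations

* The CDOM extrapolation from 275–295 nm to the analytical window is the
  method's Achilles heel: its error is ~30× the fit-window error and
  becomes the accuracy floor for salinity and nitrite. A spectrometer
  noise below ~1 mAU is assumed.
* PLS1 model bundles are not JSON-serializable (calibrate with PLS2 for
  deployment; the two give the same factor count and near-identical
  predictions on this chemistry).
* Only the exponential CDOM form is implemented; linear or quadratic
  baselines used elsewhere in the literature are out of scope.
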