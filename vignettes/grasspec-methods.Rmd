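---
title: "Methods: spectroscopic biomass estimation in grasspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectroscopic biomass estimation in grasspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grasspec)
```

## The estimation problem

A field spectroradiometer over a grass/clover sward records reflectance
R(λ) on a 1 nm grid from 350 to 2,500 nm, with many repeated readings per
plot; destructive harvest gives each plot a total dry aboveground biomass
(TAGB, g/m²), the dry weight of its green fraction (GAGB) and the percent
green fraction (%GAGB = 100·GAGB/TAGB). With ~30 plots and ~1,900 usable
bands the regression problem is massively collinear, which drives every
design choice here: latent-variable regression (PLSR), regularised linear
SVR, per-spectrum pre-processing to strip scatter and baseline effects, and
dimension reduction to a handful of physically interpretable
absorption-feature indices.

## Pre-processing

Repeated readings are averaged per plot (mean or median, both carried
through the whole analysis as alternatives). Three detector windows are
discarded as noise — around the atmospheric water vapour bands
(1,360–1,385 nm and 1,800–1,930 nm) and the far SWIR2 end (beyond
2,399 nm) — leaving 1,893 one-nm bands. Membership is decided by wavelength
value, not index, so decimated grids work unchanged. The three nested
subsets VNIR (350–1,000 nm), VNIR+SWIR1 and VNIR+SWIR1+SWIR2 let a model be
restricted to better-behaved detectors.

Eighteen one-shot transformations are available (`transform_codes()`).
Conventions that the literature leaves open were fixed as follows:

* **Baseline offset (BLO)** subtracts the per-spectrum minimum (no formula
  is standard; the corrected spectrum touches zero).
* **De-trending** fits the least-squares polynomial of order 1–3 in
  wavelength to the whole spectrum and keeps the residuals. The grid is
  internally mapped to [−1, 1] for conditioning; residuals are unaffected.
* **Normalisations** act per spectrum (the usual chemometric convention,
  not per band): division by the trapezoidal area over wavelength, the
  maximum, the mean, the range max − min (no re-centering), or the ℓ₂
  norm.
* **Norris gap derivative** uses the symmetric form
  D(λᵢ) = (x(λᵢ₊g) − x(λᵢ₋g)) / (λᵢ₊g − λᵢ₋g), dropping g bands per edge;
  it annihilates constants and is exact for quadratics, which the tests
  exploit.
* **MSC** regresses each spectrum on the dataset mean spectrum
  (x = a + b·ref) and applies only the named correction: x − a, x/b, or
  (x − a)/b. Because the reference is the dataset mean it is recomputed
  whenever the dataset changes — in particular inside every
  cross-validation fold (see below).
* **SNV** uses the n − 1 standard deviation; a constant spectrum is an
  error, not a silent zero-division.

Transformations are never composed: each model sees exactly one.

## Continuum removal and the MBD / AOM indices

Five zones, each holding one absorption feature, are fixed at
Z1 [440–567], Z2 [554–762], Z3 [916–1,120], Z4 [1,079–1,297] and
Z5 [1,265–1,676] nm. The continuum is the straight chord joining the
reflectance at the two zone endpoints (grid wavelengths snapped inward to
the printed bounds) — not a convex hull: with zone limits already placed at
local maxima, the chord is deterministic and cannot jump between anchor
points as the spectrum varies.

The continuum-removed reflectance CRR = R/C is exactly 1 at the endpoints.
Band depth is BD(λ) = 1 − CRR(λ); the **maximum band depth** is
MBD = max(0, max BD). Computing depth on the CRR scale (rather than as a
raw reflectance difference, which the band-depth literature also admits)
makes MBD invariant under multiplicative illumination/scatter changes — the
property the tests verify — and was chosen for that reason. A zone whose
spectrum never dips below the chord is flagged `degenerate` with MBD = 0
rather than reporting a negative depth.

The **area over the minimum** is AOM = MBD × W, where W is the feature
width measured where BD = MBD/2. Numerical choices:

* Among equal minima the smallest wavelength is the deepest point; the
  half-depth crossings are the ones *nearest* to it on each side, which
  makes the width robust to secondary dips in the same zone.
* Between two grid wavelengths both R and C are linear, so the crossing
  solves the linear equation R(λ) − (1 − MBD/2)·C(λ) = 0 in closed form.
  The CRR ratio is monotone between grid points (a Möbius function), so
  this is exact for piecewise-linear spectra — the brute-force 0.01 nm
  oracle in the tests agrees to 10⁻⁶.
* If BD never falls to half depth on one side within the zone, that side
  is truncated at the zone edge (only possible for boundary-truncated
  features; the chord construction guarantees BD = 0 at the endpoints
  otherwise).
* Width is measured on the BD curve; on the CRR curve it is the same
  quantity up to sign.

## Regression and validation

**PLSR** is PLS1 by NIPALS on mean-centred X and y; no variance scaling
(autoscaling ~1,900 reflectance bands would inflate noise bands — spectral
data are already on one scale). Factor models are nested, so one NIPALS
pass yields predictions for every factor count. At full rank PLSR equals
OLS on the training data, and with one predictor it equals simple least
squares; both identities are tested, plus agreement with an independent
reference implementation.

**Cross-validation** is leave-one-out throughout (n ≈ 30 makes k-fold
unnecessary and noisy). Everything data-dependent — centering, min-max
scaling, the MSC reference — is recomputed inside each fold; a pure-noise
response therefore scores mean CV R² ≤ 0 (tested over 20 seeds). R² is
defined as 1 − PRESS/SStot, the chemometric "explained variance", not a
squared correlation: it penalises bias and can go negative. %RMSE divides
by the mean of the response by default, with `center = "median"` as a
switch, since the source convention mixes both.

**Parsimony.** Factor F + 1 is admitted only while
RMSE_cv(F+1) < 0.98 · RMSE_cv(F); an exactly-2 % reduction does *not*
qualify (strict rule, and a tested tie-break). The factor cap defaults to
10. The same 2 % logic ranks models: A beats B only if
RMSE_A ≤ 0.98 · RMSE_B. As an overfitting telltale, each CV result carries
a flag when calibration and CV RMSE disagree by more than 2 %; it is a
warning flag, never a hard failure.

**SVR** is linear ε-insensitive regression with ε = 0.1 and features
min-max scaled to [0, 1] (per fold). The dual is solved by exact
coordinate descent after absorbing the intercept into the kernel
(K = XsXsᵀ + 1, the regularised-bias formulation); this removes the
equality constraint, gives closed-form soft-threshold updates, and is
implemented in C++. It differs from the libsvm dual only through the tiny
b²/2 penalty; since the cost scale of the original software is unknown
anyway, no attempt is made to match foreign C values. The cost grid
defaults to 2⁻¹⁰…2³ and the chosen C is the *smallest* one whose LOOCV
RMSE is within 2 % of the grid minimum — the support-vector parsimony rule
applied at model choice, not inside the optimiser.

**OLSR** (with intercept) is the baseline for single-index inputs;
continuous spectra are deliberately not offered to it (n ≪ p would make it
an exercise in overfitting). Exactly determined fits (n = p + 1) are
allowed because the smallest leave-one-out folds produce them.

## The model grid

`build_model_grid()` enumerates, per response: PLSR and SVM on the three
raw subsets × two averagings (12); PLSR on 18 transformations × 3 subsets
× 2 (108); PLSR on the CRR of each zone × 2 (10); PLSR on the all-zone MBD
and AOM index sets × 2 (4); PLSR on the full noisy-band-excluded spectrum
× 2 (2); and OLSR for MBD and AOM × 2 (4), each internally scanning the
five zones and reporting the best — 140 in total, 420 over the three
responses. The 124-model transformation/index block is a reconstruction:
the source states the total but not the itemisation, and
108 + 10 + 4 + 2 is the unique composition consistent with its five input
data sets. Counting OLSR as 4 top-level models (rather than 20 per-zone
fits) matches the stated totals while still reporting every zone
internally.

`explore_zone_combinations()` runs factor-selected PLSR on every subset of
the optional zones unioned with a mandatory zone (default Z4, the
1,079–1,297 nm water feature): 15 combinations of sizes 2–5.

Failures are recorded per grid row, never aborting the run, and the whole
grid is deterministic given the data.

## The synthetic world

The generator exists so that every operator — and the full grid — can be
exercised with known ground truth. It is a *stated world*, not a tuned
one:

* Sampling design: 30 plots × 15 readings, 1 nm grid 350–2,500 nm.
* Biomass: TAGB ~ Normal(45.05, 15.40) g/m² truncated to (5, 80); %GAGB ~
  Normal(68.34, 13.57) truncated to (25, 95); GAGB = TAGB·%GAGB/100
  exactly. The moments are the field campaign's sample statistics.
* Reflectance: a deterministic template (visible floor 0.05, green-peak
  bump at 550 nm, sigmoid red edge at 715 nm to a 0.45 NIR plateau, linear
  SWIR decline past 1,500 nm) times one Gaussian dip per zone (centres
  490, 670, 980, 1,200, 1,450 nm) plus a fixed 1,940 nm water dip. Dips
  are multiplicative, so a dip amplitude is (approximately, up to the
  chord sitting on the Gaussian shoulders) the continuum-removed depth the
  pipeline should recover.
* Links: pigment depths follow %GAGB (Z1, Z2: 0.10 + 0.003·%GAGB); water
  depths follow TAGB (Z4: 0.05 + 0.004·TAGB as stated; Z3:
  0.03 + 0.003·TAGB and Z5: 0.04 + 0.0035·TAGB chosen once so the two
  secondary water features carry correlated but weaker signal — no
  re-tuning after seeing test results). Depth jitter sd 0.01, clipped to
  [0, 0.95].
* Noise: per-reading Gaussian, sd 0.004 (VNIR), 0.008 (SWIR1), 0.012
  (SWIR2), ×10 inside the excluded windows; per-plot multiplicative
  scatter slope ~ N(1, 0.05) and offset ~ N(0, 0.01); readings clamped to
  the physical [0, 1.2].
* Seeding: one root seed; each plot draws from a derived substream, so
  growing `n_plots` leaves earlier plots bit-identical.

What a green test does *not* establish: the template is parametric, not
radiative transfer (no PROSAIL); there is no soil background, BRDF or
illumination geometry, no spatial autocorrelation between plots, and the
depth–biomass links are linear by construction. Recovery results on this
world demonstrate that the *pipeline* is correct and leak-free, not that
the regression accuracies transfer to any particular field campaign —
indeed the synthetic world is cleaner than real swards, and its
cross-validated accuracies are higher than typical field values.

## Degenerate inputs and tolerances

Constant spectra are errors for SNV and range normalisation (zero
denominator) and produce degenerate-slope errors in MSC; reflectance ≤ 0
is an error for absorbance and for continuum anchoring; zones must cover
at least three grid wavelengths. Reflectance is accepted up to 1.2
(reference-panel calibration can exceed unity). Orthogonality and
equivalence identities are asserted at 10⁻⁸, round-trips at 10⁻¹²,
oracle agreement for continuum geometry at 10⁻⁶, and the SVR coordinate
descent iterates to a 10⁻¹⁰ relative dual change (cap 20,000 sweeps).

## Known limitations

* Transform composition (e.g. SNV after de-trending) is unsupported by
  design; one transformation per model.
* The SVR cost values are not comparable to those of other software
  because the bias is regularised and the feature scaling convention
  differs; only the selection *rule* is portable.
* Savitzky–Golay smoothing is deliberately absent from the transformation
  set.
* Continuum removal is chord-based within fixed zones; a convex hull over
  the full spectrum is out of scope, as is continuum removal in the
  low-signal 1,800–2,100 nm region.
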