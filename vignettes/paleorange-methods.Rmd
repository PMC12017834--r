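---
title: "Models and methods in paleorange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in paleorange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleorange)
```

paleorange implements the four quantitative stages used to reconstruct the
foraging and home range of an extinct herbivore from cave deposits:
phylogenetic home-range allometry, single-grain luminescence burial-dose
statistics and ages, open-system U-Th dating of enamel, and strontium-isotope
provenance against a geological baseline. This vignette is the package's own
account of those models: their assumptions, the tunable parameters and why
their defaults are what they are, the numerical choices, and what the
synthetic-data tests do and do not demonstrate.

## Phylogenetic allometry

`pgls_allometry()` fits `log10(home range, km2)` on `log10(body mass, kg)` by
generalised least squares with error covariance `s2 * C`, where `C` is the
Brownian-motion expectation implied by the phylogeny (shared root-to-ancestor
branch length; `bm_covariance()`). Base-10 logarithms are used throughout:
the conventional macropodid allometry is quoted in that base, and published
point predictions only reproduce under base 10.

Design choices that were genuinely open:

* **Weighted trait averaging.** Species with several published body-mass or
  home-range estimates are collapsed by `weighted_trait_average()`. "In
  proportion to error" is read as inverse-variance weighting (`1/e^2`), the
  statistically standard choice; `weighting = "inverse_error"` (`1/e`) is
  available because the verbal description admits both.
* **Covariance model.** Pagel's lambda is fixed at 1 (pure Brownian motion)
  by default. Comparative-methods packages differ in their defaults (some
  profile lambda by maximum likelihood), so `lambda = "ML"` is provided; with
  `lambda = 0` or an identity `C` the fit reduces, verified to 1e-10, to OLS.
* **GLS R-squared.** Defined against the GLS-weighted intercept-only model,
  so it is invariant under uniform rescaling of branch lengths. The overall
  F statistic is `(n-2) R2 / (1-R2)` on (1, n-2) df.
* **Intervals.** `predict()` propagates the coefficient covariance in log10
  space and reports `10^(fit +/- 2 se)`: the "+/- 2SE" convention used when
  such range predictions are mapped. `mean_home_range()` averages point
  predictions over a set of candidate masses and reports twice the standard
  error of that mean; a genus-level "mean +/- 2SE" figure can equally be
  read as averaging over a species list, a mass grid, or the mass-range
  endpoints, and the function accepts any mass vector so all three
  conventions are expressible.

The GLS estimator `(X' C^-1 X)^-1 X' C^-1 y` is computed through the
Cholesky root of `C` (whitening + QR), not by explicit inversion.

## Luminescence burial doses and ages

All dose models work in natural-log dose space: `z_i = log(De_i)` with
relative error `s_i = se_i / De_i` (plus `sigma_b` in quadrature where
applicable). Grain acceptance flags are inputs: the laboratory quality
criteria that produce e.g. 40/500 accepted grains are not re-derived.

* **Central age model** (`central_age_model()`): `z_i ~ N(delta,
  sigma_OD^2 + s_i^2)`. For fixed `sigma_OD` the ML central dose is the
  weighted mean, so the implementation profiles the likelihood and optimises
  only over `sigma_OD` (bounded at 0; a boundary solution is reported as
  overdispersion 0). Standard errors come from the observed information
  matrix; when the matrix is numerically singular at the boundary its
  eigenvalues are floored at 1e-8 of the largest before inversion.
* **Minimum age model** (`minimum_age_model()`): the truncated-normal
  mixture with parameters (gamma, p, mu, sigma), `mu = gamma` for MAM-3.
  `sigma_b` defaults to 0.10, the conventional minimum overdispersion added
  for single grains, and is recorded on the fit object so reported results
  always state it. Optimisation is Nelder-Mead on (gamma, logit p, log
  sigma[, log(mu - gamma)]) from a deterministic grid of data-quantile
  multistarts (24 for MAM-3); likelihood ties break toward the smallest
  minimum dose, and `p` outside (0.001, 0.999) raises a boundary flag.
  Both likelihood maxima are verified in the tests against nested
  grid-refinement oracles (1e-6 for CAM, 1e-4 for MAM on small instances).
* **Model selection** (`select_age_model()`): the maximum-log-likelihood
  comparison is implemented as a likelihood-ratio chi-squared test at
  alpha = 0.05 between nested pairs, keeping the simpler model otherwise
  (parsimony fallback; exact ties go to CAM). `criterion = "raw"` compares
  raw maxima for users who want the unpenalised rule.
* **Weighted skewness** (`weighted_skewness_test()`): precision-weighted
  (`1/s_i^2`) skewness of log De against `c * sqrt(6/n)`; the critical
  multiplier defaults to `c = 2` (a 2-sigma criterion), with `c = 1`
  available.
* **Dose-rate budget** (`dose_rate_budget()`): beta, gamma, cosmic and
  internal components are inputs in Gy/ka (conversion factors from
  radionuclide concentrations are out of scope); the total is the sum of
  means with uncertainties combined in quadrature, and every component must
  be passed explicitly (`c(0, 0)` for absent) to prevent silent omissions.
  `water_attenuation()` uses `wet = dry / (1 + k W)` with the standard
  coefficients `k = 1.25` (beta) and `1.14` (gamma), both overridable.
* **Ages** (`luminescence_age()`): `age = De / dose rate`; the random
  relative error is the quadrature of the De and dose-rate relative errors,
  and a systematic fraction (default 2%, the beta-source calibration term)
  is added in quadrature. Setting it to 0 reproduces pure quadrature
  propagation exactly.

## U-Th dating

Decay constants (`uth_decay_constants()`) default to the modern consensus
half-lives (230Th 75.584 ka, 234U 245.62 ka) and are configurable, since
published ages rarely state their constants.

`closed_system_age()` inverts the standard 230Th ingrowth equation with
`uniroot` (inverse-consistent to 1e-10 in the tests) and propagates the
input 2-sigma errors by the delta method with numerical partials. Ratios at
or beyond the secular-equilibrium bound return "no finite age".

`idad_forward()` solves the open-system diffusion–adsorption–decay problem
for a planar enamel slab with both faces held at a fixed water composition:
uranium (238U and 234U, same effective diffusivity) diffuses in with
retardation, 230Th is immobile and grows in from the local 234U activity.
The solution is an eigenfunction series (cosines `cos((2n+1) pi x / 2)`
with decay-shifted rates); the 230Th convolution integral is evaluated in
closed form per mode with an `expm1`-stable kernel for near-degenerate
rates. The series is truncated at 50 terms with a 1e-8 tail bound flag.
238U decay is neglected in the transport balance (relative effect < 1e-4
over the < 1 Ma ages of interest). Assumptions worth stating: symmetric
planar geometry (no cylindrical/spherical variants), constant boundary
composition over burial, and a single effective diffusion parameter
`kappa = D/(R L^2)` (default 0.002 1/ka, which produces the moderately
curved, surface-high profiles typical of Middle Pleistocene enamel; it is
an argument everywhere it appears).

`idad_age()` inverts the forward model by weighted least squares over
(age, boundary 234U/238U), jointly over both ratio profiles by default.
Whether both profiles or only 230Th/238U should enter the misfit is not
settled usage, so `joint = FALSE` is provided. Minimisation is Nelder-Mead
on log-transformed parameters from 16 fixed multistarts; asymmetric
2-sigma bounds are read off the profile chi-squared at `delta chi2 = 4`,
searching each side with `uniroot`. Profiles whose bounds hit the search
range are flagged non-identifiable (flat, very old, or very noisy
transects), and any result with relative 2-sigma above 50% is flagged
`excluded`, mirroring the treatment of a single anomalous transect in the
source study's table. No detrital-Th correction is applied (232Th/238U is
carried but the published treatment applies none).

## Sr isotope reduction

`reduce_session()` runs the full chain per spot: per-spot baseline
subtraction (mean of the leading gas-blank cycles; a linear-in-time option
removes drifting baselines — whether baselines should be per-spot or
session-wide is not stated in reduction-scheme descriptions, and per-spot
is implemented), Kr stripping of masses 84 and 86 from the 82Kr monitor
(natural abundances; a config option averages the 82Kr- and 83Kr-based
predictions), exponential-law mass bias `beta =
ln(R_canonical/R_measured)/ln(m88/m86)` computed per cycle and summarised
by the median to stabilise low beams, Rb stripping of mass 87, and internal
normalisation of 87Sr/86Sr, 84Sr/86Sr and 87Rb/86Sr.

One algebraic point deserves emphasis: with `beta` defined as the exponent
that corrects measured ratios *to* true ratios, the measured (fractionated)
87Rb beam predicted from the 85Rb monitor is `m85 * (87Rb/85Rb)_nat *
(m87/m85)^(-beta)` — note the negative exponent. Using `+beta` here is a
sign error that leaves a several-percent residual on the Rb correction;
the package's end-to-end recovery test (truth restored to within 5e-5 with
Rb, Kr, bias, baseline and drift all active) pins the convention down.

Bracketing multiplies each spot by `accepted / standard`, with the
standard's internally corrected ratio interpolated linearly in time between
the blocks before and after; with a single standard the session mean is
used, and a session with no bracketing standard is an error. The corrected
84Sr/86Sr is compared against its natural value (0.0565) as the per-spot
quality flag. A single-spot transect falls back to twice the internal
cycle-scatter SE for its "2SE", a convention the package states because
published tables rarely do. Group comparisons wrap the standard tests
(Welch t, Kruskal-Wallis with tie correction); Dunn's pairwise z tests are
computed from mean ranks with Holm adjustment by default (raw and
Bonferroni also reported, the adjustment being unstated in typical usage).

## Foraging classification

`build_baseline()` summarises plant 87Sr/86Sr per geological unit as mean
+/- 2SE; units with one sample get 2SE 0 and a `range_unknown` flag.
`classify_specimen()` tests the specimen's mean +/- 2SE against the local
units in priority order — host limestone first, then the broader formation
— using interval containment by default (the natural reading of a specimen
"falling within the range of values" of a unit); interval intersection is
available as `mode = "overlap"`. Single-sample units are compared by
absolute distance with tolerance `n1_tol = 3e-4`, the scale of the observed
multi-sample baseline 2SEs, because "similar to" judgements against an
n = 1 unit cannot be interval-based. If no local unit matches, the verdict
is extra-local and every unit is ranked by absolute distance with its match
flag, which is how near-misses against n = 1 units (reported, not
verdict-forming) surface. Containment is monotone: widening a local unit's
interval can only move verdicts toward local, a property the tests check.
Specimen-level means pool transect means unweighted.

## Synthetic data: what it does and does not show

Each generator draws from exactly the statistical model its consumer
assumes, with defaults set to the study conditions:

* `gen_traits()`: 17 tips, slope 1.4, intercept -1.82, Brownian traits on a
  unit-height coalescent tree; the residual tip SD of 1.2 (log10 km2) puts
  body mass at roughly a third of home-range variance, the regime observed
  in the extant panel.
* `gen_grains()`: log-normal true doses with overdispersion, log-normal
  measurement error. Per-grain relative error defaults to 0.30 — the value
  implied by the published n = 40 and n = 27 De standard errors — and the
  two dated-sample regimes (277 Gy / 30% OD / 40 grains; 375 Gy / 3% OD /
  27 grains) are the recovery test beds.
* `gen_useries_profile()`: forward model plus independent Gaussian ratio
  noise. The default 2-sigma levels (0.012 on 234U/238U, 0.06 on
  230Th/238U, 20 spots) were chosen so a 250 ka transect yields ~+/- 8 ka
  2-sigma age bounds, the scale of the published per-transect ages.
* `gen_beams()`: volt-scale beams with exponential-law bias (optionally
  drifting), Kr blank at natural abundance ratios (i.e. unfractionated,
  matching the correction's assumption), Rb fractionated like Sr, additive
  baseline, a slow mass-87 gain drift (what bracketing removes), and
  sqrt-intensity Gaussian noise.
* `gen_baseline_and_teeth("mt_etna")`: reconstructs plant samples that
  round-trip exactly to the published multi-sample unit means and 2SEs via
  a deterministic symmetric spread (published n = 1 entries carry internal
  analytical error, which scatter cannot reproduce), alongside the
  published specimen summaries.

Passing these tests shows the estimators are correct and calibrated *under
their own assumptions*. It does not show that real data satisfy those
assumptions: no partial bleaching or beta-dose heterogeneity beyond what
overdispersion absorbs, no non-exponential mass-bias behaviour, no
diagenetic overprint on enamel Sr or U profiles, no spatial structure in
the baseline beyond unit membership, and no instrument-specific artefacts
(dead time, pit geometry). Those must be screened upstream, as the source
study does with dose-recovery tests and trace-element diagenesis checks.

Test problem sizes (chosen to probe each regime while keeping the default
suite around half a minute, plus a few minutes for the full recovery
battery): 100 seeded replicates for CAM coverage at each grain regime and
for open-system age coverage, 200 for the PGLS coefficient-coverage and Sr
bias checks, 20 for MAM mixture recovery, and <= 20-grain instances for the
likelihood grid oracles.

## Known limitations

* The PGLS panel interface expects one trait value per species; intraspecific
  variance enters only through the pre-averaging weights.
* MAM standard errors are Wald-type from the observed information; profile
  intervals for `gamma` are not implemented.
* The open-system model fixes planar geometry and a constant boundary; U
  leaching (falling uptake) and cylindrical teeth are out of scope, and the
  diffusion parameter is fixed rather than co-estimated, so transects that
  violate these assumptions will show structured misfit rather than a
  warning.
* The Sr chain assumes the exponential law holds across the session up to a
  slowly drifting channel gain; isobaric interferences other than Kr and Rb
  (e.g. doubly charged REE) are not modelled.
* The baseline classifier is categorical per geological unit; it does not
  interpolate a continuous isoscape, and distances in ratio space are not
  distances in km.
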