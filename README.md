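# paleorange

Quantitative inference chain for reconstructing the foraging and home ranges
of extinct herbivores from cave fossil assemblages — built around the Mt Etna
(central Queensland) *Protemnodon* case: how far did a 50–170 kg rainforest
macropodid actually roam, and when did it live?

The package is aimed at palaeoecologists and geochronologists who need the
four quantitative stages of such a study as tested, reusable estimators
rather than one-off scripts:

1. **Phylogenetic allometry** (`pgls_allometry`). Home range scales with body
   mass as a power law, fitted on the log10 scale across extant relatives
   under a Brownian-motion phylogenetic error covariance:
   `log10 Y = b0 + b1 log10 X + e`, `e ~ N(0, s2 C)` with `C[i,j]` the shared
   root-to-ancestor branch length. `predict()` extrapolates to extinct body
   masses with coefficient-covariance intervals.
2. **Luminescence burial doses and ages** (`central_age_model`,
   `minimum_age_model`, `select_age_model`, `luminescence_age`). Single-grain
   equivalent-dose (De) distributions are modelled in log space with known
   per-grain errors: the central age model estimates the common dose `exp(d)`
   and overdispersion `s_OD` by maximum likelihood; the 3- and 4-parameter
   minimum age models isolate the lowest-dose population of a truncated
   mixture. `age = De / dose rate` with the dose-rate budget summed from
   beta, gamma, cosmic and internal components and a split random/systematic
   error budget.
3. **U-Th dating of enamel** (`closed_system_age`, `idad_forward`,
   `idad_age`). Closed-system ages invert the 230Th ingrowth equation;
   open-system ages invert a diffusion–adsorption–decay model in which
   uranium diffuses into an enamel slab from both faces while 230Th grows in
   immobile, fitting (age, boundary 234U/238U) to the measured activity-ratio
   transects by weighted least squares with profile-likelihood 2-sigma
   bounds.
4. **Sr isotope reduction and provenance** (`reduce_session`,
   `build_baseline`, `classify_specimen`). Raw Faraday beam cycles (masses
   82–88) are reduced to 87Sr/86Sr per ablation spot — baseline subtraction,
   Kr and Rb isobaric-interference stripping, exponential-law mass bias from
   88Sr/86Sr, standard–sample–standard bracketing — and specimens are
   classified as local or extra-local against a per-geological-unit
   bioavailable-Sr baseline measured in plants.

Seeded synthetic-data generators (`gen_traits`, `gen_grains`,
`gen_useries_profile`, `gen_beams`, `gen_baseline_and_teeth`) emulate each
stage's inputs with known truth, and the published Mt Etna summary tables are
packaged as fixtures (`mt_etna_dose_rates`, `mt_etna_useries_ages`,
`mt_etna_sr_baseline`, `mt_etna_specimens`).

## Worked example

```r
library(paleorange)

# --- allometry on a synthetic 17-species panel -----------------------------
g <- gen_traits(seed = 1)                 # tree + body mass / home range table
fit <- pgls_allometry(g$traits, g$tree)
fit
#> Phylogenetic GLS allometry (log10-log10)
#>   log10(home range) = -2.243 + 1.085 * log10(body mass)
#>   n = 17, lambda = 1, R^2 = 0.484, F(1, 15) = 14.059, p = 0.001933
predict(fit, c(50, 131, 170))[, 1:4]
#>   mass_kg   fit_km2    lwr_km2   upr_km2
#> 1      50 0.3981589 0.02748678  5.767518
#> 2     131 1.1319472 0.05319746 24.085821
#> 3     170 1.5017593 0.06304390 35.773180
```

The fitted line is the estimated power law; `fit_km2` is the point
prediction at each body mass and `lwr/upr` the +/- 2 SE interval propagated
from the coefficient covariance in log space (wide here because a 17-species
panel constrains extrapolation only loosely).

```r
# --- burial dose and age for a 40-grain De distribution --------------------
cam <- central_age_model(gen_grains(n = 40, central_gy = 277, od = 0.30,
                                    rel_se = 0.30, seed = 8))
cam
#> CAM fit (40 grains, sigma_b = 0)
#>   burial dose (Gy): 266 +/- 19.9
#>   overdispersion:   0.367 +/- 0.0684
budget <- dose_rate_budget(beta = c(0.50, 0.03), gamma = c(0.42, 0.02),
                           cosmic = c(0.01, 0.01), internal = c(0.03, 0.01))
luminescence_age(cam, budget)
#> Age: 277.3 +/- 24.23 ka  (random 23.6, systematic 5.5)
```

The central age model recovers the simulated 277 Gy / 30% overdispersion
regime within errors; dividing by the 0.96 Gy/ka budget gives the age, whose
total 1-sigma error combines the random part with a 2% systematic
calibration term.

```r
# --- closed-system U-Th age of a reference coral ---------------------------
closed_system_age(1.110, 0.764, a234_2sd = 0.002, a230_2sd = 0.007)$age_ka
#> [1] 123.4575

# --- Sr provenance of a fossil tooth ---------------------------------------
classify_specimen(0.706855, 0.000020, mt_etna_sr_baseline())
#> Specimen 0.706855 +/- 0.000020: extra-local (containment mode)
#> Nearest units:
#>                        unit mean_87_86    delta match
#>  Permian to Triassic Gabbro   0.706839 0.000016 FALSE
#>          Alton Downs Basalt   0.706728 0.000127 FALSE
#>          Chalmers Formation   0.706395 0.000460 FALSE
```

The tooth's 87Sr/86Sr interval falls inside neither local unit's range, so
the verdict is extra-local, with the gabbro and basalt as the nearest
candidate source substrates.

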