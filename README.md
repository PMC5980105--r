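# bearsecr

Spatially explicit capture–recapture (SECR) density estimation for grizzly
bear DNA hair-snag surveys, with habitat-driven density surfaces and
source–sink classification of the sampled landscape.

## The problem

Systematic hair-snag grids (one baited barbed-wire station per 7 × 7 km
cell, sampled over 4 sessions with sites moved between sessions) identify
individual bears from hair DNA. Classical closed-population estimators
pool detections per session and need radio-collared animals to correct for
bears that use the grid only partially. SECR instead models each
detection as a function of the distance between the snag site and the
animal's latent home-range center: detection probability follows a
half-normal kernel

    p(d) = g0 · exp(−d² / (2σ²))

with `g0` the detection probability at the center and `σ` the spatial
scale of movement. For detected animals with histories ω_i over a habitat
mask (a lattice of points x_m with cell area a), the full likelihood is

    log L = Σ_i log[ (a/1000) Σ_m D(x_m) · Pr(ω_i | x_m) ]
            − (a/1000) Σ_m D(x_m) · pdot(x_m) − log(n!)

where `D(x) = exp(β′z(x))` is an inhomogeneous Poisson density surface
(bears per 1000 km²) over covariates z — here resource-selection (RSF) and
mortality-risk scores — and `pdot` is the probability of at least one
detection. Model variants add session trends, site covariates (terrain
ruggedness, canopy closure), behavioural responses and 2-class finite
mixtures to `g0` and `σ`; candidate models are ranked by AICc with Akaike
weights. Downstream the package estimates per-animal home-range-center
posteriors, a Huggins closed-model + telemetry-residency density for
comparison, and classifies the mask into "safe harbor" (above-median RSF,
low risk) versus "attractive sink" (above-median RSF, high risk)
quadrants with mean density and relative abundance per category.

Because real survey data of this kind are access-restricted, the package
ships a synthetic-study generator (`simulate_study()`) with known truth —
autocorrelated RSF/Risk landscapes, moved detectors, Poisson-process
activity centers, Bernoulli half-normal detections, bivariate-normal
telemetry — so every stage is testable end to end.

## Worked example

```r
library(bearsecr)

st <- simulate_study(n_cells_x = 6, n_cells_y = 6, seed = 7,
                     detection = list(F = c(g0 = 0.25, sigma = 4),
                                      M = c(g0 = 0.12, sigma = 8)),
                     density = list(F = c(intercept = log(20), RSF = 0.4,
                                          Risk = -0.3),
                                    M = c(intercept = log(12), RSF = 0.4,
                                          Risk = -0.3)),
                     buffer = 15)
capF <- subset(st$captures, sex == "F")
attr(capF, "n_occasions") <- 4

fit <- fit_secr(capF, st$layout, st$mask)
predict(fit)
#>       parameter estimate      se    lcl     ucl
#> 1            g0   0.2738 0.06854 0.1609  0.4256
#> 2      sigma_km   4.0000 0.44332 3.2190  4.9705
#> 3 D_per_1000km2  12.4009 2.73924 8.0433 19.1195
```

The fitted `g0` (0.27) and `σ` (4.0 km) sit on the generating female
truth (0.25, 4 km). The density estimate, 12.4 bears per 1000 km²
(CI 8.0–19.1), covers this replicate's realized on-grid density of 13.6
— with only 24 detected females the realized Poisson draw matters as
much as the expectation. Phase 2 ranks the five density surfaces
(constant, RSF, Risk, RSF+Risk, RSF×Risk) on the same detection
structure:

```r
dm <- fit_density_models(capF, st$layout, st$mask)
dm$table
#>      model k    loglik     aicc    dAICc     weight tied_with_reference
#> 1 constant 3 -211.8208 430.8416 0.000000 0.46239527               FALSE
#> 2      RSF 4 -211.1314 432.3680 1.526474 0.21554788                TRUE
#> ...

surf <- predict_density(dm$fits[[dm$best]])
region_abundance(surf)          # abundance + CI on the sampled grid
category_summary(surf, categorize_mask(st$mask))   # safe harbor vs sink
```

With 24 detected females the constant model is (correctly, at this sample
size) competitive; larger simulated surveys rank the generating RSF model
first. `center_posterior(fit)` gives each animal's home-range-center
posterior over the mask, and `collapse_to_sessions()` / `fit_closed()` /
`fit_residency()` / `density_closed_telemetry()` reproduce the
closed-model + telemetry comparison estimator. `run_pipeline()` drives
the whole analysis from a config list or YAML file.

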