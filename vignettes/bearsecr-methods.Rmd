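---
title: "Methods: SECR density surfaces for hair-snag surveys"
author: "bearsecr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SECR density surfaces for hair-snag surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models the package implements, the
assumptions behind them, the numerical choices, and what the synthetic
data generator does and does not emulate.

## The observation model

A hair-snag survey identifies individual bears (with sex) at baited
stations over `S` sampling occasions. Detectors are *binary proximity*
devices: within one occasion an animal either leaves an identifiable hair
sample at a site or it does not, and repeated deposits at the same site in
the same occasion collapse to one record. Each animal is assumed to have
a latent activity (home-range) center and a circular, stationary pattern
of space use, so the per-occasion detection probability at a site a
distance `d` from the center is half-normal,

```
p(d) = g0 * exp(-d^2 / (2 sigma^2)),
```

with `g0` the probability at the center and `sigma` (km) the movement
scale. All coordinates are projected planar kilometres and distances are
Euclidean; no geographic CRS handling is attempted.

Detections are conditionally independent across animals, sites and
occasions given the centers. On the link scales (logit for `g0`, log for
`sigma`), the linear predictors can include:

* `trend` — a linear term in occasion index (centered at `(S+1)/2`),
* site covariates (`TRI_site`, `CC_landscape`, ...), z-scored over the
  detector rows before fitting so reported effects are per SD,
* `b` — a permanent learned response switching after the animal's first
  detection,
* `bk` — a site-specific learned response switching at a site after the
  animal's first detection there; of limited use when sites are moved
  between occasions, so it is excluded from default candidate sets,
* `h2` — a 2-class finite mixture for unstructured heterogeneity, with
  mixing weight estimated on the logit scale.

## The likelihood and the habitat mask

Density is an inhomogeneous Poisson intensity over activity centers,
log-linear in mask covariates and expressed in bears per 1000 km²:
`D(x) = exp(beta' z(x))`. Spatial integrals are approximated by sums over
a habitat mask, a regular lattice with spacing 3.5 km (half a grid cell)
and cell area `spacing^2` by default. The full likelihood of the `n`
detected animals includes the Poisson normalization and a `-log(n!)`
constant so values are comparable across models on the same data.

The density intercept has a closed-form conditional MLE (it profiles out
of the Poisson likelihood), so the optimizer — BFGS with numerically
differenced gradients, relative tolerance 1e-9, at most 500 iterations —
works on the detection parameters and non-intercept density coefficients
only.
Standard errors come from a central-difference Hessian of the full
(unconcentrated) likelihood at the optimum (relative step 1e-4);
confidence intervals are logit-based for probabilities and log-normal for
positive parameters. Starting values are data-driven: `sigma` from the
spread of each animal's detection locations, `g0` from the per-occasion
detection rate.

Numerical safeguards worth knowing about: detection probabilities are
capped at `1 - 1e-12` before `log(1-p)`; kernel terms with
`d^2/(2 sigma^2) > 30` (p below ~1e-13) are dropped from the no-detection
products, which changes log-likelihoods by less than 1e-10 while making
large-mask evaluation several times faster; per-animal mask sums use
streaming log-sum-exp, so center posteriors and likelihoods cannot
underflow. Ties in the center-posterior mode are broken by the lowest
mask-point index.

A fit with no animal detected at two distinct sites cannot identify
`sigma`; such fits are flagged and `sigma` is suppressed from reports.
Boundary estimates (`g0 -> 1`) raise a warning. AICc uses the number of
detected individuals as its sample size — the standard convention for
SECR — and refuses models with `n <= k + 1`. The model table flags
candidates whose AICc is within 2 units (strictly) of the constant
model's as "tied".

### Mask extent

`esa_curve()` reports the constant-density estimate as a function of
buffer width with detection parameters held fixed; `suggest_buffer()`
applies a 1%-per-step stability rule. Simulation work in the test suite
uses buffers of about 3 sigma, where the curve is flat to well under
0.5%. Mask spacing deserves care. For *point estimation* under constant
density a spacing moderately above sigma is tolerable (medians stay
within a few percent of truth even at 7 km for sigma = 4 km), but
interval coverage is more sensitive: the large parameter-recovery study
in the tests uses 5.25 km (1.3 sigma), where bias is a small fraction of
a standard error and 95% intervals are calibrated. For
*density-model comparison* the requirement is stricter: with spacing much
above ~0.9 sigma, the discretization lack-of-fit of the per-animal mask
sums is partially absorbed by the more flexible density surfaces, which
inflates their apparent AICc support well beyond the chi-square rate.
Model-selection analyses should therefore keep the default 3.5 km spacing
(or finer) for movement scales around 4 km, and that is what the
model-recovery experiments in the test suite do.

## Phase-1 / phase-2 analysis

Following standard practice for these surveys, detection and movement
models are selected first under constant density (phase 1, per sex; sexes
are always fit separately — the package does not pool sexes with a sex
covariate). The best detection structure is then retained while the five
density surfaces are compared: constant, `~RSF`, `~Risk`, `~RSF+Risk`,
`~RSF*Risk` (the interaction model always includes both main effects).
Detection parameters are re-estimated in every phase-2 fit rather than
fixed. Density covariates are z-scored over in-grid mask points;
classification thresholds (below) are computed on the raw scores, which
are scale-free because the splits are rank-based.

Mask points outside the covariate coverage polygon ("province") take the
value of the nearest covered mask point and are flagged `filled`.
Predictions at covariate values outside the range seen on the sampled
grid are flagged `extrapolated`, warned about, and excluded from region
summaries by default. Region abundance is the plug-in sum
`(a/1000) * sum D(x)` over flagged points with a delta-method variance
and log-normal interval.

## Home-range centers

For each detected animal the posterior weight of mask point `x` is
proportional to `D(x) * Pr(history | x)` under the fitted model. Both
the mode (a mask point, used for region tallies because region membership
is well-defined there) and the weighted mean are reported; region
percentages are rounded to one decimal, matching the tabulation style of
published survey reports.

## Closed model + telemetry comparison estimator

The comparison estimator pools detections per session (Huggins
conditional likelihood; M0/Mt/Mb/Mh2) and recovers abundance by
Horvitz–Thompson summation `N = sum_i 1 / pstar_i`. Telemetry residency
— the fraction of a collared animal's locations inside the grid — is
regressed on the animal's mean distance-from-edge (computed from
inside-grid locations only, for equivalence with DNA-based mean detection
locations) with a binomial GLM on the logit link. The density estimator
weights each detected animal by its predicted residency at its mean
DNA-detection location:

```
D = (1/A) * sum_i r_i / pstar_i
```

reducing exactly to `N/A` when residency is 1. Whether the historical
estimator weighted per animal or multiplied `N` by mean residency is not
recoverable from published descriptions; per-animal weighting is this
package's formulation, and a `mean_residency` variant is available behind
a flag. The variance combines the HT binomial component with delta-method
propagation over the (independent) closed-model and residency-model
parameters.

## Source–sink classification

In-grid mask points are split at the median of each of RSF and Risk:
above-median RSF with low Risk is "safe harbor" (source-like),
above-median RSF with high Risk is "attractive sink". "High" is strictly
above the median, so ties go low — the published description states
"above the median" only for RSF, and the same strict rule is applied to
Risk for symmetry. Category summaries report mean density, area,
relative abundance (mean density × area) and the abundance expected under
uniform density, whose deviation from the overall mean-density baseline
measures selection for or against a category. An activity-center variant
(`category_center_counts()`) tallies posterior modes per category.

## The synthetic-data generator

`simulate_study()` emulates one survey: ordinal RSF/Risk score rasters
built by quantile-binning smoothed Gaussian fields (autocorrelation range
10 km, 10 levels, latent cross-correlation 0.2 by default — Gaussian-field
smoothing gives the spatial coherence such score maps show); a systematic
grid of 7 km cells with one detector per cell per occasion, re-drawn
uniformly within the cell each of 4 occasions; sex-specific populations
from log-linear density surfaces (defaults: females 12 and males 8 bears
per 1000 km² at average habitat, density rising with RSF (+0.4/SD) and
falling with Risk (−0.3/SD)); Bernoulli half-normal detections with the
female-high-`g0`/small-`sigma`, male-low-`g0`/large-`sigma` pattern
characteristic of this species (defaults F: 0.2, 5 km; M: 0.1, 10 km,
consistent with detectability out to ~15 km for females and ~30 km for
males); and circular bivariate-normal telemetry for a collared subsample.
Animals never detected exist only in the truth record, as in real DNA
sampling.

Deliberately not emulated: genotyping error, open-population dynamics,
transient or elongated home ranges, biased (expert-opinion) site
placement within cells — real crews place snags in high-use
micro-habitats, while the generator draws uniformly; an option for biased
placement was considered and left out because detection-scale analyses
showed movement scales well above the cell size, making within-cell
placement second-order. Passing tests therefore demonstrate correctness
of the estimators under the stated model, not robustness to these
real-data features.

## Problem sizes used in the test suite

The parameter-recovery study uses the full systematic design (20 × 20
cells of 7 km, 4 occasions, D = 30 bears/1000 km², g0 = 0.15, sigma =
4 km) with 100 replicates; model-set recovery uses 8 × 8-cell surveys
with about 100 detected animals per replicate, 100 replicates per arm;
the cross-method comparison uses 12 × 12-cell surveys with 50 replicates.
These sizes give stable pass/fail behaviour for the statistical checks
while keeping the full suite runnable on a laptop in well under half an
hour.

## Known limitations

* Half-normal is the only detection kernel; hazard-rate and exponential
  forms are out of scope.
* Single-session (closed) surveys only; no open-population models.
* Euclidean distance only; no least-cost movement.
* The Mh jackknife closed-model estimator is not implemented (Mh2 is).
* Region variance ignores mask-discretization error, which the spacing
  sensitivity checks show is well below sampling error here.
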