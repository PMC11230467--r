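---
title: "Area-weighted redlining exposure and firearm-injury rate models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Area-weighted redlining exposure and firearm-injury rate models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redscore)
```

## The analysis in one paragraph

In the 1930s the Home Owners' Loan Corporation (HOLC) graded urban
neighbourhoods A ("Best") through D ("Hazardous" — outlined in red, hence
*redlining*). This package quantifies a modern zone's historical redlining
exposure as the **area-weighted mean grade** of the historical polygons that
overlap it, on the scale A = 1 ... D = 4, and relates that exposure to
present-day firearm-injury counts with a **negative-binomial rate model**:
for zone $z$ with population $N_z$,

$$y_z \sim \mathrm{NB2}(\mu_z, \alpha), \qquad
\log \mu_z = \beta_0 + \beta_1 S_z + \log N_z ,$$

so $e^{\beta_1}$ is the incidence rate ratio (IRR) per unit of redlining
score $S_z \in [1, 4]$. The pipeline runs from raw GeoJSON polygon layers
and record-level ICD-10 data to IRRs, on either real inputs, a packaged
36-zone Baltimore dataset, or fully synthetic cities.

## The crosswalk and the score

HOLC polygons and zip/ZCTA polygons are different partitions of the plane,
so grade information is reallocated by **polygon overlay**: the coverage
matrix entry $a_{z,g}$ is the intersection area of zone $z$ with all
grade-$g$ regions. Per-zone grade shares and the score are

$$p_{z,g} = 100\,\frac{a_{z,g}}{\sum_{g'} a_{z,g'}}, \qquad
S_z = \frac{\sum_g w_g\, a_{z,g}}{\sum_g a_{z,g}}, \quad
w = (1, 2, 3, 4).$$

Two normalisation choices were genuinely open and are fixed as follows:

* **Denominator = graded-only area.** The historical maps cover only part
  of a modern city; shares are shares *of what was graded*. This is also
  the only convention under which the published per-zone share rows sum to
  100%.
* **Ungraded zones are excluded, not imputed.** A zone with no graded
  overlap has an undefined score; assigning it 0 would be off the 1–4
  scale and bias $\beta_1$. Such zones are flagged and dropped from the
  regression with a logged reason.

All area mathematics happens in planar coordinates. Geographic (lon/lat)
input must be reprojected — areas on the sphere are otherwise meaningless —
and the reader exposes a cylindrical equal-area projection
(`projection_cea()`, central meridian and latitude of true scale
configurable) for that purpose. Synthetic data uses abstract planar units
and skips reprojection.

### Geometry engine

Intersection areas are computed exactly (to floating point) by a
signed-fan decomposition: every simple ring is fanned into triangles from
its first vertex with orientation signs, and the intersection area of two
rings is the signed sum of pairwise triangle–triangle clip areas
(Sutherland–Hodgman against a convex triangle is exact). The identity
holds for arbitrary simple rings, so non-convex zones and holes need no
special casing; holes carry ring sign $-1$. Bounding-box prefilters keep
the double loop cheap.

Numerical choices:

* **Invalid rings are repaired, not rejected** — digitised 1930s maps
  routinely contain bow-ties and slivers. A self-intersecting ring is
  split at its proper crossings into simple loops (the planar analogue of
  a zero-width buffer), with a warning.
* **Sliver policy**: intersection pieces below `sliver_epsilon`
  (default $10^{-10}$ of the zone area) are discarded to stabilise the
  percentage columns.
* **Overlapping graded regions** (digitisation artifacts) are counted
  independently — double counting is allowed — and the doubly-claimed area
  is reported as a diagnostic.
* An independent **Monte-Carlo oracle** (`mc_area_oracle()`: rejection
  sampling over the first polygon's bounding box, binomial standard
  errors) validates the exact engine in the test suite; the two routes
  never share code.

## Injury tabulation

Records are filtered to the study population by four ordered criteria —
firearm code, zip present, zip in the study area, state residency — and
each exclusion carries exactly the first failing reason, so counts
reconcile at every stage. ICD-10 matching is on the 3-character stem
(`"X93.0XXA"` counts as X93). The default codebook maps W32–W34 to
accidental, X72–X74 to self-harm, X93–X95 to assault, Y22–Y24 to
undetermined and Y35 to legal intervention. The source study's methods
text prints a slightly different list (W72 for X72, Y23 twice, no Y24)
than its code-summary table; the table's list is the default because its
counts reconcile exactly with the printed totals, and the methods list
remains available as `codebook("methods")`. Ages below the youngest
summary bin (2–14) go to a logged `unbinned` category rather than being
forced into it.

Zone ids are opaque strings; treating ZCTAs and zip codes as
interchangeable is a stated modelling assumption of the analysis (logged
at read time), not something the code attempts to verify.

## The count model

NB2 is parameterised by the dispersion $\alpha$ (variance
$\mu + \alpha\mu^2$; $\alpha = 1/\theta$ of the shape parameterisation,
and `theta` is also reported for cross-checks against shape-parameterised
software). Fitting is by maximum likelihood from first principles:

1. **IRLS for $\beta$ at fixed $\alpha$** — Fisher scoring with weights
   $\mu/(1+\alpha\mu)$;
2. **profile maximisation for $\alpha$ at fixed $\beta$** — golden-section
   search on $\log\alpha$;

alternated until the joint change is below `tol` ($10^{-8}$ relative on
the coefficients; the profile location is only identifiable to about
$\sqrt{\varepsilon}$, so the dispersion criterion is held at
$\sqrt{\mathrm{tol}}$ on the $\log\alpha$ scale). The dispersion is
floored at $10^{-8}$ (the Poisson boundary) instead of being allowed
negative, and the log-likelihood switches to its exact Poisson limit below
that threshold to avoid $\ln\Gamma$ cancellation. Standard errors come
from the observed information in $\beta$ at the optimum,
$\sum_z x_z x_z^\top \mu_z (1+\alpha y_z)/(1+\alpha\mu_z)^2$; confidence
intervals are Wald on the coefficient scale and exponentiated for the IRR
scale, and both scales are emitted (the published adjusted-model table
mixes the two conventions, so either can be compared). AIC is
$2k - 2\log L$ with the dispersion counted in $k$; ranking ties break
toward fewer parameters. Non-convergence is reported as a flag, never as
a silent answer; an all-zero response or separable design raises an
explicit error.

The supporting statistics go through the standard library routines a
practitioner would use: Pearson chi-square via `chisq.test` (no continuity
correction), the score–rate correlation via `cor.test` (Pearson $r$ with
the two-sided $t$ test). `MASS::glm.nb` appears **only** as an independent
cross-check oracle in the tests.

## The packaged Baltimore dataset

`baltimore_table3()` returns the published per-zip dataset: 36 zip codes,
1055 encounters, populations, grade-coverage percentages and redlining
scores. Analysis uses full-precision scores recomputed from the percentage
columns (the published score range 1.64–4 shows the original analysis did
the same); the printed 1-decimal score column is kept alongside.

One printed row (zip 21214) is internally contradictory: its grade shares
read 100% C (score 3.0) against a printed score of 2.0. The accessor keeps
the printed score for that row, flags it (`score_consistent = FALSE`), and
the inconsistency is deliberately surfaced — not silently corrected — by
the test suite. Recomputing the published headline quantities from this
table gives an unadjusted IRR of 2.043 per score unit (published: 2.054,
CI 1.309–3.236) and a score–rate correlation of $r = 0.46$; the published
$r = 0.49$ with $p = 0.0003$ is not recoverable from the printed table
(at $n = 36$, $r = 0.49$ implies $p \approx 0.002$), and the package
reports the $t$-based $p$ it actually computes. The published adjusted
model (median-age covariate) cannot be reproduced because the per-zip
median ages were never printed; the adjusted-model *form* is exercised on
synthetic covariates instead.

## What the synthetic generator emulates

`city_config()` fixes the study conditions for validation:

| parameter | default | rationale |
|---|---|---|
| zone grid | 6 × 6 = 36 zones | the size of the real analysis |
| zone edge | 1000 planar units | arbitrary scale; areas are relative |
| populations | uniform 2,000–60,000 | the real per-zip range (1,652–68,678) |
| graded coverage | 65% of the city | historical core inside a larger modern city |
| patches | 48 guillotine splits | a few graded patches per zone |
| grade mix | Dirichlet(1) city mix | varied, sometimes polarised cities |
| $\beta_0$ | −8.8 | city-wide rate of order $10^{-3}$ at mean score ≈ 2.6 |
| $\beta_1$ | 0.72 | the coefficient estimated from the real data |
| $\alpha$ | 0.3 | moderate overdispersion |
| median age | uniform 25–45 years | plausible zip-level spread |

A single seed expands into per-stage substreams (geometry, counts,
records) so stages re-run independently with stable randomness, and
generation is byte-identical given the config. The generator writes real
GeoJSON/CSV and is only ever consumed through the public readers, so every
file contract is exercised.

Geometry is deliberately **axis-aligned rectangles only**: rectangle
intersections have closed forms, giving the crosswalk an exact independent
oracle; irregular-polygon stress lives in the geometry property tests
(random convex polygons against the Monte-Carlo oracle). Consequences for
interpretation: passing tests demonstrate correctness of the overlay
arithmetic and the estimation machinery, *not* fidelity to real map
pathologies (projection distortion, coastline slivers, topology errors
beyond simple self-intersections) or to real spatial confounding —
synthetic counts are conditionally independent given the score, with no
spatial autocorrelation, which real cities do not guarantee.

## Validation scale

The test suite validates parameter recovery on 200 generated cities of 36
zones at the default conditions ($\beta_1 = 0.72$, $\alpha = 0.3$),
checking mean bias below 0.05 and 95% Wald coverage between 0.90 and 0.98;
the fitter is also checked against a brute-force $(\beta_0, \beta_1,
\alpha)$ lattice search refined to $10^{-3}$ on three 20-zone datasets,
and against `MASS::glm.nb` on three more. These sizes keep the full suite
around a minute while leaving the Monte-Carlo checks with standard errors
small enough to be discriminating.

## Known limitations

* The analysis is ecological and cross-sectional: an association between
  zone-level exposure and zone-level rates, nothing individual or causal.
* Pure area weighting: no dasymetric (population-weighted) interpolation,
  although historical population surfaces would arguably be better.
* No spatially-correlated error models (CAR/SAR), zero-inflation, or
  Bayesian fitting — the target analysis uses plain NB regression.
* The ring-repair heuristic handles crossings and slivers typical of
  digitised maps; it is not a full polygon-arrangement engine.
* Percentage-derived scores inherit the 1-decimal rounding of printed
  sources; full-precision inputs avoid this.

## A worked example

```{r}
tbl <- baltimore_table3()
fit <- fit_nb(tbl, terms = "score")
effect_table(fit)
rate_correlation(tbl)[c("r", "p")]
```

```{r}
cfg <- city_config(seed = 7, contamination = 0.1)
manifest <- run_pipeline(synthetic = cfg,
                         terms = c("score", "median_age"),
                         out_dir = file.path(tempdir(), "demo"), seed = 7)
manifest$stages$fit$best_model
```
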