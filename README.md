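# redscore

Quantifies a modern city zone's exposure to 1930s **redlining** — the
Home Owners' Loan Corporation (HOLC) practice of grading neighbourhoods
A ("Best") to D ("Hazardous") for mortgage risk — and estimates how that
exposure relates to present-day **firearm-injury rates**. It is written
for spatial epidemiologists and health-services researchers who have a
graded historical polygon layer, a zip/ZCTA polygon layer with
populations, and record-level injury data with ICD-10 external-cause
codes.

## What it computes

1. **Areal crosswalk.** Zone-by-grade intersection areas
   `a[z, g]` from polygon overlay of the two layers (exact planar
   geometry with repair of invalid rings; a Monte-Carlo oracle validates
   the engine).
2. **Redlining score.** The area-weighted mean grade over each zone's
   graded coverage, with weights A = 1, B = 2, C = 3, D = 4:

   `S_z = sum_g w_g a[z,g] / sum_g a[z,g]`, so `S_z` runs 1–4.
3. **Injury tabulation.** Filters records to the study population
   (firearm ICD-10 stem, valid in-area zip, state resident; one logged
   reason per exclusion), classifies intent (accidental / self-harm /
   assault / undetermined / legal intervention), and builds per-zone
   counts plus demographic and intent summaries.
4. **Rate models.** Negative-binomial (NB2) regression of counts on the
   score with a log-population offset,

   `y_z ~ NB2(mu_z, alpha)`, `log mu_z = b0 + b1 S_z + log N_z`,

   fitted by first-principles IRLS + profile-dispersion maximum
   likelihood; reports incidence rate ratios `exp(b1)` with Wald 95%
   intervals on both scales, AIC model ranking, and the Pearson
   score–rate correlation.
5. **Synthetic cities.** A seeded generator of GeoJSON/CSV inputs with
   known truth (`b0`, `b1`, `alpha`) so the whole pipeline is testable
   end to end without any external download.

The published 36-zip Baltimore dataset ships as a fixture
(`baltimore_table3()`, `baltimore_table2()`).

## Worked example

```r
library(redscore)

tbl <- baltimore_table3()          # 36 zips, 1055 encounters
fit <- fit_nb(tbl, terms = "score")
fit
#> Negative-binomial rate model (log link, log-population offset)
#>   n = 36  alpha = 0.8726  logLik = -147.018  AIC = 300.037
#>         term         irr       irr_lo       irr_hi       coef ...
#>  (Intercept) 0.000129525 3.630026e-05 0.0004621655 -8.9516365
#>        score 2.042757047 1.282544e+00 3.2535771128  0.7143004

rate_correlation(tbl)[c("r", "p")]
#> $r
#> [1] 0.4606901
#> $p
#> [1] 0.004690979
```

Reading: each one-unit increase in redlining score (one full HOLC grade)
multiplies the expected firearm-injury rate by about **2.04** (95% CI
1.28–3.25), and the crude per-capita rate correlates with the score at
r ≈ 0.46 across the 36 zips. The dispersion `alpha = 0.87` confirms the
counts are strongly overdispersed relative to Poisson.

A fully synthetic run, from geometry to model ranking:

```r
cfg <- city_config(seed = 7, contamination = 0.1)
run_pipeline(synthetic = cfg, terms = c("score", "median_age"),
             out_dir = "demo-run", seed = 7)
# writes scores.csv, counts.csv, demographics.csv, intents.csv,
# models.json, manifest.json
```

There is also a thin command-line front end:

```sh
Rscript inst/cli/redscore.R fixture --out out/
Rscript inst/cli/redscore.R run --holc holc.geojson --zones zcta.geojson \
    --population pop.csv --records encounters.csv --out out/
```

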