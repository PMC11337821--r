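# spinachshelf

Statistical toolkit for longitudinal microbiological quality studies of
packaged leafy greens — the setting where lots of baby spinach from two
growing regions are sampled at harvest and through refrigerated shelf life,
plate counts (aerobic, psychrotolerant and gram-negative) are taken in
triplicate, a week of preharvest weather is on file for every lot, and
hundreds of colony isolates are identified from 16S BLAST hits. The package
is aimed at food microbiologists and biostatisticians who want the full
analysis chain — kinetics, regression, covariate selection, power, community
composition — as composable, pipe-friendly R functions, exercisable end to
end on synthetic data with known ground truth.

## What it computes

**Growth kinetics.** Per-sample log10 counts over shelf days are fit by
nonlinear least squares to the two standard no-lag primary growth models,

- Baranyi (no lag):
  `log10 N(t) = Nmax − log10(1 + (10^(Nmax−N0) − 1) · e^(−µmax t))`
- Buchanan (no lag, three-phase linear without lag):
  `log10 N(t) = min(N0 + µmax t / ln 10, Nmax)`

with `N0` the initial concentration (log10 CFU/g), `µmax` the maximum
specific growth rate (ln CFU/g per day) and `Nmax` the stationary-phase
concentration. The better model per sample is chosen by AIC, and the fitted
curve is inverted analytically for the time to a quality threshold
(7 log10 CFU/g by default), including the counterfactual where every lot is
assumed to start at a common `N0`.

**Concentration models.** Replicates are aggregated to geometric means
(means of log10 values) and modelled against growing region: a fixed-effects
model for harvest samples and a random-intercept-per-lot mixed model for
packaged samples with an orthogonal quadratic in shelf day, preceded by a
test-by-region interaction screen and followed by protected backward
elimination (region is never dropped; terms leave at p > 0.10).

**Weather covariates.** Hourly preharvest weather is summarized over the
0–24, 25–48, 49–72 and 73–168 h windows before harvest (temperature
mean/min/max, mean dew point, windspeed, solar radiation; precipitation
totals over 0–72 and 73–168 h), clustered by rank correlation, preselected
two-per-cluster by single-addition AIC with a |Spearman rho| > 0.70
replacement rule, and forward-selected at p < 0.10.

**Power.** A resampling-based post hoc power analysis: for every design on a
grid of per-region sample counts (4–8 × 4–12 by default, 45 designs),
samples are drawn without replacement, the packaged-sample model is refit,
and power is the fraction of draws rejecting the no-region-difference null.

**Isolate taxonomy.** BLAST tabular hits are length-filtered (alignment ≥
99% of the query), assigned the top hit's genus with escalation to
family/order when a different-genus hit sits within 0.50 percentage points
of the top identity, pooled into a "rare" class below 1% prevalence, and
summarized per sample visit into composition matrices feeding Bray-Curtis
dissimilarities, principal coordinates analysis, two-factor PERMANOVA with
sequential sums of squares (999 permutations), and Monte-Carlo Fisher exact
tests.

**Synthetic studies.** `sim_config()` / `simulate_study()` generate complete
seeded datasets — counts, metadata, weather, isolates — with recorded truth,
so every stage above is testable without any external download.

## Worked example

Invert the growth curve of a single fitted sample for its time to
7 log10 CFU/g:

```r
library(spinachshelf)
fit <- list(model = "baranyi_nolag", N0 = 5.31, mumax = 0.37, Nmax = 9.03)
round(time_to_threshold(fit, threshold = 7), 1)
#> [1] 10.5
```

Simulate a small two-region study, fit per-sample growth models and compare
regions on their median kinetics (type-7 quantiles):

```r
library(dplyr)
ds <- simulate_study(sim_config(n_samples_per_region = 6, seed = 1))
apc <- aggregate_replicates(ds$counts) |>
  filter(sample_type == "packaged", test == "APC") |>
  rename(day = shelf_day, log10_conc = geo_mean_log10)
fits <- fit_growth_curves(apc, threshold = 7, N0_override = 5)
fits |>
  left_join(distinct(ds$truth, sample_id, region), by = "sample_id") |>
  group_by(region) |>
  summarise(median_N0 = round(unname(quantile_type7(N0, .5)), 2),
            median_mumax = round(unname(quantile_type7(mumax, .5)), 2),
            median_Nmax = round(unname(quantile_type7(Nmax, .5)), 2),
            median_days_to_7 = round(unname(quantile_type7(days_to_threshold, .5)), 1))
#> # A tibble: 2 × 5
#>   region          median_N0 median_mumax median_Nmax median_days_to_7
#>   <chr>               <dbl>        <dbl>       <dbl>            <dbl>
#> 1 salinas_ca_area      5.99         0.63        8.71              4.7
#> 2 yuma_az_area         4.77         0.52        7.87             10.3
```

The synthetic region-B lots start roughly 0.75–1 log10 higher and plateau
higher, so they cross the 7 log10 threshold days earlier — the qualitative
pattern the kinetics module is built to quantify. The full chain (growth,
mixed models, weather harness, power grid, taxonomy ordination and tests)
runs in one call:

```r
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
render_report("run1")   # writes run1/report.md
```

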