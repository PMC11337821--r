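---
title: "Models and methods for regional shelf-life studies of packaged leafy greens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for regional shelf-life studies of packaged leafy greens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinachshelf)
library(dplyr)
```

This vignette is the package's own account of the statistical machinery it
implements: the growth models and their inversion, the concentration
regressions and selection procedures, the weather-covariate harness, the
resampling power analysis, the isolate-taxonomy chain, and — because every
stage is validated on simulated data — what the synthetic-data generator
does and does not emulate.

## Primary growth models and time to threshold

Bacterial concentrations on refrigerated produce are analysed on the log10
scale. Two no-lag primary models cover the shapes seen in packaged leafy
greens, where growth is typically already underway at packaging:

* **Baranyi without lag** (smooth saturating), implemented in the
  numerically stable form
  \[
  \log_{10} N(t) = N_{max} - \frac{\log\!\big(1 + (10^{N_{max}-N_0}-1)e^{-\mu_{max}t}\big)}{\log 10},
  \]
  which avoids overflow of $e^{\mu_{max} t}$ at large $t$ and passes through
  $N_0$ at $t=0$ exactly.
* **Buchanan without lag** (log-linear then plateau), linear with slope
  $\mu_{max}/\ln 10$ until $t^* = \ln(10)(N_{max}-N_0)/\mu_{max}$, constant
  $N_{max}$ after.

Parameters and units: $N_0$ and $N_{max}$ in log10 CFU/g, $\mu_{max}$ in
ln(CFU/g) per day. The time to a threshold $X$ has closed forms
($t = \ln(10)(X-N_0)/\mu_{max}$ for Buchanan;
$t = \mu_{max}^{-1}\log\{D(E-1)/(1-D)\}$ with $D = 10^{X-N_{max}}$,
$E = 10^{N_{max}-N_0}$ for Baranyi), and both inversions round-trip through
the forward curves to $10^{-9}$, which the test suite asserts over random
parameter draws. A threshold at or above $N_{max}$, or below $N_0$, is a
domain error rather than an extrapolation — real studies encounter exactly
this when a sample's plateau sits below the quality threshold, and such
samples are reported as not reaching it. The `N0_override` argument supports
the counterfactual "all lots start at 5 log10 CFU/g", which isolates the
contribution of initial contamination from that of growth rate.

### Fitting

`fit_growth()` uses Levenberg–Marquardt least squares on the log10 scale
with data-driven starts ($N_0 \leftarrow$ first observation,
$N_{max} \leftarrow$ maximum observation, $\mu_{max} \leftarrow \ln(10)$
times the steepest adjacent slope, floored at 0.1), box constraints
($N_0, N_{max} \in [0, 12]$ log10 CFU/g, $\mu_{max} \in (0, 10]$), and up to
five jittered restarts before a fit is flagged non-converged; non-converged
fits are excluded downstream rather than patched. Model choice per sample is
by AIC, using the Gaussian least-squares convention
$\mathrm{AIC} = n\log(\mathrm{RSS}/n) + 2k$ with $k = 4$ (three kinetic
parameters plus a residual variance); only AIC *differences* matter, so the
additive constant is immaterial. Exact ties go to the Baranyi form, the
smoother and more mechanistic of the two. Fits with $N_{max} - N_0 < 0.1$
are flagged degenerate: with so little dynamic range the three parameters
are not separately identifiable.

## Concentration models

Replicates are first aggregated to geometric means — arithmetic means of the
log10 values — one row per sample, test and day. The harvest-sample model is
an ordinary linear model; the packaged-sample model adds a random intercept
per lot to absorb repeated measures over shelf life, with day entered as an
orthogonal second-degree polynomial (`stats::poly`), so the linear and
quadratic trends are estimated on uncorrelated axes.

Whether region effects can be summarized by a single test type is decided by
an interaction screen: a combined model with test, region and their
interaction (random intercept per sample-by-test series) either routes to
separate per-test models (interaction significant at 0.05) or to a single
model of the aerobic count.

**Backward elimination.** From the full fixed-effect list, the least
significant eligible term with p > 0.10 is dropped, iteratively, under two
constraints: protected terms (region, the factor the study is about) are
never dropped regardless of significance, and marginality is respected — an
interaction must leave before its main effects become eligible.

**Objectives and p-values.** Likelihood-based comparisons (AIC ordering of
candidate covariates, the selection traces) use maximum likelihood fits,
since REML likelihoods of models with different fixed effects are not
comparable. The term-level F-tests that drive drops and retention, however,
are computed on REML refits with Satterthwaite denominator degrees of
freedom. This split exists because the Satterthwaite approximation is
calibrated for REML estimates of the variance components: in our null
simulations a truly irrelevant sample-level covariate was rejected at the
0.10 level 13.5% of the time when tested on the ML fit but 11% on the REML
fit. The same reasoning applies to the power simulation below.

A small utility, `normalize_harvest_apc()`, adjusts harvest counts to a
common harvest-to-testing time (reference 36.75 h, slope
0.01 log10 CFU/g per hour by default), the standard way to remove a
logistics covariate before correlating harvest with shelf-life
concentrations. Nonparametric comparisons (Spearman, Mann–Whitney) and the
Holm step-down correction wrap the corresponding `stats` functions; medians
and interquartile ranges throughout are type-7 (linear-interpolation)
quantiles, R's default.

## Weather features and the covariate harness

Hourly weather for the week before harvest is summarized per sample over
four windows anchored at the harvest timestamp — 0–24, 25–48, 49–72 and
73–168 hours before — as mean/min/max temperature, mean dew point, mean
windspeed and mean solar radiation, plus precipitation totals over 0–72 and
73–168 h. A window "k1–k2" contains the stamps with
$k_1 < (\text{harvest} - t) \le k_2$ hours: half-open toward the past, so
the four windows partition the 168 preharvest hourly stamps exactly and the
harvest hour itself belongs to no window. The inclusivity convention is a
documented choice — any consistent half-open rule yields a partition, and
window summaries over 24+ hourly values are insensitive to which single
boundary stamp they receive. Samples with unknown harvest clock time fall
back to 03:00, the median harvest hour in overnight-harvest production
systems, and are flagged.

The 26 features are strongly collinear by construction (neighbouring
windows, temperature vs. dew point), so candidate selection is staged:

1. **Cluster** the features by agglomerative clustering on
   $1 - |\rho_{Spearman}|$ with average linkage, choosing 1–7 clusters by
   mean silhouette width. This is a deliberate substitution of a simple,
   deterministic correlation-clustering backend for stochastic subspace
   methods used in some analyses; the harness contract — clusters feed a
   per-cluster shortlist — is unchanged, and the backend is pluggable.
   Because the backend is deterministic, the `runs` argument is accepted
   for interface stability but has no effect. Constant columns cannot be
   ranked and are isolated as flagged singletons.
2. **Preselect** two variables per cluster by lowest single-addition (ML)
   AIC; unclustered variables ride along. Any selected pair correlated
   beyond |rho| = 0.70 has its lesser-improving member replaced by the next
   best alternative from its cluster, iterating until clean.
3. **Forward-select** the candidates in ascending AIC order, retaining each
   at p < 0.10 (REML F-test); the final model is refit with REML.

Forward selection can only add terms, so the final model's ML log-likelihood
never falls below the base model's — asserted as a property test.

## Post hoc power by resampling

`estimate_power()` draws, without replacement, a design's per-region sample
counts from the pool of packaged lots, refits the packaged-sample model
(region + day polynomial + harvest-to-arrival time, random intercept per
lot) and records whether the region coefficient is significant at
$\alpha = 0.05$; power is the rejection fraction over `n_sims` draws
(default 100), deterministic given the seed. Rejection uses the REML fit's
Satterthwaite p-value for the calibration reasons above. Singular fits are
counted as non-rejections and tallied separately rather than discarded —
silently dropping them would bias power upward at small designs, where
singular fits are most common. The default grid (4–8 region-A by 4–12
region-B lots, 45 designs) is scanned by `power_grid()`, and
`minimum_design()` extracts the Pareto-minimal designs reaching a target
power (default 80%).

Two calibration notes from our simulations, both reproduced by the test
suite. First, the type-I error of this machinery sits in the 3–5% range
when every lot shares one shelf-day schedule. Second, when lots mix
different day grids (for example five test days ending at day 22 for some
lots and day 28 for others), the common quadratic day trend cannot fit both
exactly; the sample-specific lack of fit behaves like extra between-lot
variation that the region contrast can latch onto, and the realized test
size creeps up toward 8–13%. Mixed schedules are a realistic feature of
shelf-life studies, so the generator produces them by default — but the
calibration experiments in the tests use a homogeneous schedule to measure
the property actually under test.

## Isolate taxonomy

The chain from raw 12-column BLAST tabular output to community analysis:

1. **Parse and join** hits with per-query sequence lengths and per-subject
   taxonomy (genus, family, order); unknown subjects are an error, not a
   silent drop.
2. **Length filter**: hits aligning over less than 99% of the query are
   removed; a hit at exactly 99% stays (the rule excludes only strictly
   shorter alignments).
3. **Assign**: the top hit by percent identity nominates its genus. If any
   different-genus hit lies within 0.50 percentage points of the top
   identity — inclusive, and exact ties at the top count as 0-pp
   contenders — the call escalates to the lowest rank shared by the top hit
   and all contenders: family, else order, else the isolate is
   unclassified and excluded from genus-level analysis. Inclusive reading
   of "within 0.50" is a documented choice; percent identities are reported
   to two decimals, so the boundary case is rare but must be deterministic.
4. **Pool rare**: genera below 1% prevalence among the genus-rank calls
   (the analysis set, i.e. after exclusions) are relabelled "rare"; a genus
   at exactly 1% is kept.
5. **Compose**: integer counts per sample-visit unit over the post-pooling
   genus labels. Counts, not proportions, feed the dissimilarities: the
   row sums (isolates analyzed per unit) are nearly constant by design, and
   Bray–Curtis on counts then differs negligibly from proportions while
   keeping the matrix integer-valued and auditable. Unbalanced visits
   (e.g. an end-of-shelf-life day reached by few lots) can be excluded
   before ordination and testing.

Bray–Curtis, PCoA and PERMANOVA are implemented in-package (and
cross-checked against vegan and classical scaling in the tests): PCoA is
Gower double-centering of $-d^2/2$ with eigendecomposition, coordinates from
positive eigenvalues, variance explained reported against the
positive-eigenvalue total, negative eigenvalues reported but not embedded;
PERMANOVA uses sequential (Type-I) sums of squares via cumulative hat
matrices on the centered matrix, pseudo-F per term, and p-values
$(1 + \#\{F_{perm} \ge F_{obs}\})/(n_{perm}+1)$ under row-label permutation
with a fixed seed, so p-values are bounded below by $1/(n_{perm}+1)$ —
0.001 at the default 999 permutations. The Monte-Carlo Fisher test fixes
both margins (`stats::r2dtable`), orders tables by their null
probability — the standard two-sided ordering for exact tests, stated here
because r-by-c generalizations differ — and reports
$(1 + \#\{P_{sim} \le P_{obs}\})/(B+1)$ with $B = 2000$ by default.

## The synthetic-data generator

`simulate_study()` draws, per lot: true kinetic parameters from
region-shifted Gaussians (defaults: region-A means $N_0 = 4.8$,
$\mu_{max} = 0.53$, $N_{max} = 7.9$; region-B shifts +0.75 and +0.9 log10
for $N_0$ and $N_{max}$ — the 0.5–1 log10 regional gap reported for
culturable bacteria on leafy greens, with growth rates similar across
regions); a lot-level intercept (sd 0.15 log10) shared by every measurement
of the lot; per-test offsets (APC 0, PC +0.3, GN −0.5 log10, free
parameters reproducing the usual ordering of the three counts on packaged
produce); and replicate noise (sd 0.2 log10). Counts follow the chosen
no-lag model over a five-day schedule whose first day is the
packaging-to-arrival lag (2–4 days — "day initial" is a study artifact with
no canonical value, so it is configurable); harvest-sample counts sit just
below the lot's packaged $N_0$ with a 0.01 log10/h harvest-to-testing
slope. Weather is hourly at clock stamps covering the harvest day and the
nine days before: a diurnal temperature cycle plus AR(1) noise around a
region-dependent mean (12 °C vs 14 °C), dew point offset from temperature,
windspeed, daytime solar and sparse precipitation. Part of the regional
$N_0$ gap is mediated by the mean temperature in the 24 h before harvest
(`temp_to_N0_slope`, default 0.12 log10 per °C), which is what gives the
weather harness a true signal to find. Isolates are drawn multinomially
(2 colonies × 2 films × 3 tests × 3 replicates = 36 per sample visit) from
region- and visit-dependent genus mixtures, and emitted as BLAST-style hit
sets whose top hit carries the true genus; the identity margin to
different-genus decoys is configurable so the 0.50-pp escalation rule can
be exercised both ways.

The truth table records both the drawn parameters and the realized
trajectory levels (`N0_curve`, `Nmax_curve`, i.e. including the lot
intercept): recovery is judged against the realized curve, since the lot
intercept shifts the whole trajectory and is part of what a per-sample fit
should estimate.

What the generator does **not** emulate: censoring at detection limits,
missing visits and dropped lots, non-Gaussian replicate error, seasonal
weather trends within a region, chlorine-wash effects, or sequencing
failure modes (chimeras, short reads) beyond a fraction of short BLAST
alignments. Passing tests therefore demonstrate that the estimators and
procedures are correct and calibrated under the stated generative
structure, not that real data meet that structure.

## Numerical choices and problem sizes

Tolerances: NLS convergence at $10^{-10}$ on the objective; inversion
round-trips asserted at $10^{-9}$; orthonormality of the day basis at
$10^{-10}$; PERMANOVA residual sums of squares clamped at zero (a saturated
design can produce a floating-point-negative residual, which would flip the
pseudo-F sign). Ties: model selection to Baranyi; top-identity ties treated
as joint top hits. Degenerate inputs error early and loudly: fewer than
four observations or two distinct days for a growth fit, single-level
factors in the screen, all-zero composition rows, zero contingency margins.

The validation experiments shipped in the test suite use sizes chosen to
make their Monte-Carlo error small relative to the property being checked:
200 curves for parameter recovery (mean absolute errors about 0.14 for
$N_0$, 0.07 for $N_{max}$, 0.05 for $\mu_{max}$ at replicate noise 0.2);
1000 resampling simulations for the power type-I check and 400 per design
for monotonicity; 1000 null replicates at 199 permutations for PERMANOVA
size; 100 seeded datasets for the selection-procedure check, where the
expected success rate of dropping a truly null covariate is the nominal
90% at the 0.10 retention threshold — a perfectly calibrated procedure
hovers at that rate by construction, which is worth remembering when
reading selection traces on real data.

## Known limitations

* Satterthwaite degrees of freedom are an approximation; small designs with
  singular variance components fall back to boundary fits that the power
  machinery counts conservatively.
* The correlation-clustering backend groups features by marginal
  association only; subspace structure (features jointly informative but
  marginally weak) is outside its reach.
* PERMANOVA permutes raw observation labels; restricted permutation schemes
  for nested designs are not implemented.
* The backward/forward selection paths inherit the usual caveats of
  stepwise procedures: post-selection inference on the retained
  coefficients is optimistic, and the traces should be read as descriptive.
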