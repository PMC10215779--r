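---
title: "Modelling global jellyfish niches from presence-only reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling global jellyfish niches from presence-only reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rhizostome jellyfishes (order Rhizostomeae) are conspicuous, economically
relevant, and chronically under-sampled. Citizen-science platforms produce
large presence-only occurrence datasets for them, but those data are biased:
identifications are reliable only to genus rank, reporting effort is
concentrated in a few wealthy regions, and records cluster at popular coastal
access points. `rhizoniche` implements a complete workflow that turns such
reports, paired with gridded monthly ocean climatology (7 variables —
temperature, salinity, dissolved oxygen, percent oxygen saturation, silicate,
phosphate, nitrate — at 0, 5, 10, and 20 m depth; 28 predictors in all), into

1. a screen for genera whose report data are *saturated* (sample coverage
   > 0.95),
2. a multivariate GLM test of environmental niche structure across genera,
3. per-genus random-forest occurrence models with data-driven predictor
   selection, and
4. global suitable-habitat predictions evaluated against an independent
   set of literature ("legacy") occurrence records.

The package also ships a synthetic-data module that generates climatology,
niche-driven reports, and legacy records with the statistical structure the
analysis assumes, so every stage is testable without any download.

## Pipeline stages and their assumptions

### Coverage screening

Reports are truncated to genus rank (the first whitespace-delimited token of
the taxon string), coordinates are rounded to tenths of a degree with a
half-away-from-zero rule (pinned explicitly to avoid platform-dependent
banker's rounding in coordinate binning), and each genus' reports are
collapsed to counts per distinct coordinate. Coverage uses the Chao–Jost
abundance-based estimator

$$\hat C \;=\; 1-\frac{f_1}{n}\cdot\frac{(n-1)f_1}{(n-1)f_1+2f_2},$$

with the standard bias-corrected form (replacing $f_1$ by $f_1-1$ in the
correction factor) when $f_2=0$, where $n$ is the total report count and
$f_1, f_2$ count coordinates seen once and twice. Conventions pinned here:
$\hat C = 1$ when $f_1 = 0$, and $\hat C = 0$ when $n = 1$ (the raw formula's
$(n-1)$ factor would return 1 for a single report, which is not a useful
screening value). Retention is strict: a genus passes only if
$\hat C > 0.95$ at the observed sample size; we use the point estimate at
observed $n$, not an extrapolated value. One estimator property worth
knowing: $\hat C$ is *not* monotone under arbitrary duplicate reports —
adding a report at a twice-seen coordinate removes an $f_2$ and can lower
the estimate by up to ~0.02 — though duplicating a singleton coordinate
never lowers it. The tests assert the form that holds.

### Environmental pairing

Each report is paired with every grid cell whose center lies within ±2° of
the report in both axes (a latitude/longitude box, not a great-circle
radius — the generous box accommodates beached-jellyfish reports on land),
in the report's calendar month, and matches are averaged per (variable,
depth). Longitude wraps across the antimeridian; latitude clamps at the
poles. Reports are then snapped to 2° cells (1° for the robustness check)
and accumulated into the *curated frame*: one row per cell × month carrying
per-genus counts and the mean profile of its member reports. Months are kept
separate because pairing is month-specific (seasonal populations); a
collapse option exists. Entries that found no ocean cell are median-imputed
per column **only** for model fitting, with an `.imputed` audit column and a
per-predictor imputation count attribute, because forests and GLMs need
complete rows.

### Multivariate GLM niche test

Counts per genus are modelled with a log-link negative-binomial GLM against
the 28 standardized predictors (overdispersed, low-mean abundance counts;
the NB fit falls back to Poisson, flagged, when dispersion degenerates). The
multivariate statistic is the sum over genera of null-vs-full
likelihood-ratio statistics, each computed with the genus' dispersion held
at its observed estimate; significance comes from unrestricted
row-permutation of the predictor matrix,
$p = (1+\#\{\text{perm} \ge \text{obs}\})/(1+R)$. This is simpler than
residual-resampling schemes and asymptotically valid for the global test.
Numerical note: the depth replicates of each variable are strongly
collinear, so the likelihood-ratio fits use an orthonormal basis of the
design's column space (identical statistics, far better conditioning).

The biplot is a principal-component projection of the standardized genus ×
coefficient matrix with a deterministic sign convention (largest-magnitude
loading positive). Because unregularized coefficients under strong
collinearity are individually unstable, the biplot configuration is itself
noisy — across generator seeds the 1° vs 2° Procrustes correlation on the
default synthetic study ranges from near 0.1 to near 1, and the same caveat
applies to any coefficient-based ordination of such data: interpret the
geometry qualitatively, never metrically. Latitudinal and longitudinal
distribution grouping uses the tie-corrected Kruskal–Wallis χ² with pairwise
Dunn z-tests (unadjusted at α = 0.05 by default; any `p.adjust` method can
be configured) and a compact letter display computed as the maximal cliques
of the non-significance graph, which makes "shares a letter ⇔ not
significantly different" exact by construction.

### Random forests and the Gini-gap rule

Presence/absence labels follow the co-report pseudo-absence rule: any row of
the curated frame with a positive count for some genus supplies absence
labels for all genera not reported there. One uniform random 80/20 split is
shared by all genera (comparable test folds); each genus gets a 500-tree
classification forest. Importance is mean decrease in Gini impurity.
Predictors are selected by sorting importances and cutting at the largest
consecutive gap; if that keeps exactly one predictor the rule extends to the
second-largest gap; gap ties break toward the higher-importance position,
importance ties break by the canonical predictor order; when no usable
second gap exists (two predictors, or all gaps tied) the single top
predictor is kept. Accuracy and specificity are reported on the held-out
fold; specificity is undefined (reported missing) when the fold has no
actual negatives.

### Envelopes, maps, and legacy evaluation

"Suitable habitat" is a hard box in environmental space: for each selected
predictor, the central 90% interval (5th–95th percentile,
linear-interpolation quantiles — the quantile convention is pinned because
definitions differ across software) of the positive rows' values. A cell is
suitable when every selected predictor lies within bounds in at least one
month (static global maps; per-month masks are an option — which months the
original analysis intersected is not stated, so the any-month reading is the
default). Land is never suitable. The 2D report density surface is a
Gaussian KDE (Scott's-rule bandwidth per axis) renormalized to integrate to
1 on the grid.

Evaluation against legacy records uses cell membership: a record is inside
the predicted distribution when its containing grid cell (or any cell within
a configurable Chebyshev radius, default 0) is suitable, and per-genus
accuracy is the percentage of such records. Because a near-global envelope
trivially inflates that percentage, the suitable-ocean-area fraction is
always reported alongside, with a flag above a configurable threshold
(default 0.5). Under uniformly distributed records the expected accuracy
equals the suitable-area fraction — the calibration property the acceptance
tests verify.

## What the synthetic generator emulates — and what it does not

The generator is first-class, tested code defining the study conditions:

* **Climatology** — per variable/depth, a latitudinal base profile plus
  depth and seasonal terms plus spatially smoothed noise (Gaussian blur,
  wrap in longitude), sharing one synthetic land mask (~30% of cells,
  threshold of a smoothed random field). Values sit in realistic ranges
  (e.g. SST −5…30 °C, salinity ~33–36 PSU).
* **Niches** — each genus occurs with intensity proportional to a product
  of Gaussian kernels over 1–2 informative predictors; the defaults place
  tropical, temperate, and nutrient-associated genera apart (Lychnorhiza is
  keyed to silicate/phosphate so that nutrient-driven selection is
  recoverable).
* **Reporting process** — Poisson counts per cell-month with intensity
  kernel × participation weight. The participation surface is both biased
  (high effort over boxes approximating North America, Europe, Australia)
  and *patchy*: a sparse set of active reporting cells with heavy-tailed
  popularity, and report coordinates snap to a small number of fixed access
  sites per cell. The patchiness is essential realism: without coordinate
  reuse, every rounded coordinate is unique and sample coverage can never
  saturate at realistic sample sizes. Defaults (600 expected reports per
  genus on a 2° grid) put all ten genera above the 0.95 coverage threshold,
  the regime the analysis assumes.
* **Legacy data** — the same niches sampled under uniform dense effort
  (literature records are assumed far less geographically biased), tagged
  `legacy`, with no observation month (they are evaluated spatially only).

Not emulated: real coastlines and bathymetry, actual ocean climatology
values, species-level taxonomy, observer-level duplication, and temporal
trends. Passing tests therefore demonstrate that the *pipeline* recovers
known structure under its own assumptions — not that the models are accurate
for real oceans.

## Tunables

| Parameter | Default | Units | Why |
|---|---|---|---|
| `lat_step` | 2 | degrees | grid resolution; must divide 180 |
| `window` | 2 | degrees | pairing half-width (±2°, a 4° box) |
| `map_step` | 2 | degrees | frame cell size; 1 used for robustness |
| `sc_threshold` | 0.95 | – | strict coverage retention cut |
| `central_fraction` | 0.90 | – | envelope mass (5th–95th percentile) |
| `n_trees` | 500 | trees | forest size (library default) |
| `train_fraction` | 0.80 | – | shared train split |
| `n_resamples` | 199–999 | – | permutation count for the global test |
| `tolerance` | 0 | cells | legacy inclusion radius |
| `area_flag_threshold` | 0.5 | – | inflation-prone flag |
| `n_target` / `n_legacy` | 600 / 60 | reports per genus | synthetic sample sizes |

Every stochastic stage has a named seed in the run configuration
(`synth`, `legacy`, `split`, `rf`, `perm`); a configuration (YAML
round-trippable) plus the package version is enough to re-execute a
byte-identical run, and the manifest written by `run_all()` records both
along with row counts at every filter.

## Numerical choices and degenerate inputs

* Half-away-from-zero coordinate rounding; type-7 (linear interpolation)
  quantiles; strict `>` threshold comparisons.
* Coverage conventions at the degenerate ends ($f_1=0$, $n=1$) as above.
* GLM: orthonormalized design for LR statistics; dispersion fixed across
  permutations; divergent fixed-family fits retry from a null start and,
  failing that, contribute a zero LR statistic; all-zero counts are flagged
  degenerate rather than fitted; aliased coefficients enter the biplot as 0.
* Gini-gap selection tie-breaks and fallbacks as above, verified against
  brute-force cut-point enumeration.
* Single-class training labels are an error for a single forest and a
  recorded skip in the all-genus driver.
* KDE bandwidth floors at 0.5° so single points and zero-variance point
  sets remain well-defined.

## Problem sizes used by the tests

The unit suite runs on an 18 × 36 (10°) grid with 3–6 months; the
statistical acceptance checks use 1000-vector oracle sweeps, 40 replicates
of 500 × 28 forest recovery, 200 null replicates (n = 50, 99 permutations)
for the size of the permutation test, and a 5-genus pipeline determinism
run. The acceptance script runs the full ten-genus study on a 4° grid with
12 months and 600 expected reports per genus. These sizes were chosen so the
whole suite completes in a few minutes while every statistical property is
estimated with usable Monte-Carlo error.

## Known limitations

* Envelopes are hard boxes; suitability is binary, not probabilistic, and
  mid-ocean over-prediction is expected for neritic taxa because bathymetry
  and coastline distance are deliberately not predictors.
* The legacy-accuracy metric rewards wide envelopes; always read it next to
  the reported area fraction.
* The permutation test is global; it does not identify which predictors
  drive the signal (that is the forests' job).
* Coefficient-based ordinations are unstable under depth-collinearity;
  interpret biplot geometry qualitatively.
* With `map_step` ≫ report density, frames shrink and single-class labels
  or sub-5-row splits can make stages error out by design rather than
  silently degrade.
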