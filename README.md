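# rhizoniche

Global ecological niche and distribution modelling for rhizostome
jellyfishes (order Rhizostomeae) from presence-only occurrence reports and
gridded monthly ocean climatology.

Citizen-science platforms hold thousands of genus-level jellyfish reports,
but the data are presence-only, genus-rank, and heavily biased toward a few
well-reported coastlines. `rhizoniche` implements a complete, reproducible
workflow for such data, aimed at marine macroecologists and coastal
managers:

1. **Ingest & curation** — validating report tables, genus-rank taxonomy,
   tenth-degree coordinate rounding.
2. **Coverage screening** — coordinate-level abundance and the Chao–Jost
   sample-coverage estimator
   `Ĉ = 1 − (f₁/n)·(n−1)f₁ / ((n−1)f₁ + 2f₂)`;
   only genera with Ĉ > 0.95 (saturated report data) are modelled.
3. **Environmental pairing** — each report is paired with all climatology
   cells within ±2° in its calendar month (7 variables × 4 depths = 28
   predictors), averaged into a profile, and accumulated into a curated
   cell × month abundance/environment frame.
4. **Niche testing** — per-genus negative-binomial GLMs whose
   likelihood-ratio statistics sum to a multivariate niche statistic with a
   row-permutation p-value; a coefficient biplot; Kruskal–Wallis + Dunn
   compact-letter grouping of latitudinal/longitudinal distributions.
5. **Random-forest occurrence models** — co-report pseudo-absences, a
   shared 80/20 split, 500-tree forests, and predictor selection at the
   largest mean-decrease-Gini gap (extended to the second-largest gap when
   one predictor would remain).
6. **Envelope habitat prediction** — suitable habitat is the region where
   every selected predictor lies within the central 90% interval
   (5th–95th percentile) of the genus' positive profiles.
7. **Evaluation** — percentage of independent legacy (literature) records
   falling in predicted habitat, reported next to the suitable-area
   fraction so inflated accuracies are visible.

A first-class synthetic-data module generates climatology, niche-driven
reports, and legacy records with the statistical structure the analysis
assumes (smooth autocorrelated fields, land mask, effort bias, coordinate
reuse at reporting sites), so the entire pipeline runs and is tested fully
offline.

## Worked example

The `analysis/` directory is the workflow as numbered drivers
(`01_simulate.R` … `08_robustness.R`), run from the repository root. The
same thing in one call:

```r
library(rhizoniche)
cfg <- run_config()                  # 2° grid, 12 months, 600 reports/genus
res <- run_all(cfg, "results/run")   # writes every artifact + manifest
```

With the default configuration the run prints, among other things:

```
10 of 10 genera have saturated report data (SC > 0.95).
Curated frame: 922 cell-month rows from 6056 reports (0 unpairable).
<mv_glm_result> statistic = 8205.43, p = 0.005 (199 permutations, 10 genera)
Latitudinal distributions: KW chi-squared = 1364.1 (p = 4.42e-288),
  groups: Cassiopea=ab Catostylus=c Cotylorhiza=b Eupilema=d Lobonema=a
          Lychnorhiza=e Pseudorhiza=e Rhizostoma=d Rhopilema=f Stomolophus=b
Test accuracies span 69.7% - 92.4%.
  Lychnorhiza  -> nitrate_5m, silicate_0m, phosphate_10m
  Stomolophus  -> dissolved_oxygen_5m, temperature_0m, phosphate_10m, ...
Legacy accuracies span 69.0% - 98.5% across 10 genera (1 flagged inflation-prone).
```

Reading this: all ten genera pass the saturation screen; the multivariate
GLM rejects environmental exchangeability of genera (p = 0.005, the
smallest value 199 permutations allow is 0.005); latitudinal distributions
are strongly genus-specific (genera sharing a letter do not differ in the
Dunn tests); the forests recover each genus' generating niche — the
nutrient-associated genus is selected by nitrate/silicate/phosphate while
temperate genera are selected by temperature/salinity; and predicted
distributions contain 69–98.5% of the independent legacy records, with the
one near-global envelope flagged as inflation-prone rather than celebrated
as accurate.

Per-genus maps (suitability mask, report squares, legacy circles) land in
`results/figures/` via `plot_suitability_map()`.

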