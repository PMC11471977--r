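# amazodex

Curation and diversity analysis of Amazonian amphibian occurrence records.

Continental biodiversity syntheses start from hundreds of thousands of
occurrence records pulled from aggregator platforms (GBIF, SpeciesLink,
VertNet, SiBBr, SISBIO), literature and fieldwork — most of which cannot
support spatial analysis. amazodex implements, as one tested pipeline, the
standard three-filter curation sequence and the diversity analysis built on
its survivors, for anyone assembling or auditing a large occurrence
database for the Amazon (or any biome with a boundary polygon and a
reference taxonomy):

1. **Taxonomic refinement** — open-nomenclature detection (*cf.*, *gr.*,
   *aff.*, *sp.*), synonym resolution to accepted names;
2. **Geographic validation** — DMS→decimal conversion, range checks, the
   (0,0) artifact, administrative-level precision, and exclusion of records
   with uncertainty radius > 20 km (strictly);
3. **Biogeographic validation** — closed-boundary point-in-polygon test
   against the biome limit, plus dropping species whose documented
   distribution codes lack `AM`;

then sub-basin selection from a nested drainage hierarchy (area > 30,000
km² rule, auto or zonal mode), an equal-area 50 × 50 km grid, and the
diversity statistics: per-unit richness and endemism (endemic ⇔ biome code
set is exactly `{AM}`), Jaccard similarity *J(A,B) = |A∩B|/|A∪B|* with
UPGMA clustering on 1 − J, species accumulation with years as samples
(exact expectation *E[S(t)] = Σᵢ (1 − C(m−mᵢ, t)/C(m, t))* or seeded
permutation), first- and second-order jackknife richness estimators

&nbsp;&nbsp;&nbsp;&nbsp;*jack2 = S_obs + Q₁(2m−3)/m − Q₂(m−2)²/(m(m−1))*,

a Poisson GLM of richness on log basin area, and summary reports (filter
accounting with the conservation identity, IUCN tallies per family,
decade-level temporal increments, per-source complementarity).

A synthetic-data generator produces multi-source records with controlled
defect rates over a nested-basin landscape, together with a truth ledger
labelling the first filter stage that should exclude each record — so every
stage of the pipeline is verifiable exactly, offline.

## Worked example

```r
library(amazodex)

cfg <- pipeline_config(seed = 1, synth = synth_config(
  1, source_counts = c(gbif = 1500, sibbr = 1000, vertnet = 500)))
res <- run_pipeline(cfg)

res$accounting
#> # A tibble: 4 × 3
#>   stage                      n pct_of_initial
#>   <chr>                  <int>          <dbl>
#> 1 excluded_taxonomic       710           23.7
#> 2 excluded_geographic     1222           40.7
#> 3 excluded_biogeographic   521           17.4
#> 4 retained                 547           18.2

glance(res$richness_estimate)
#> # A tibble: 1 × 7
#>   S_obs jack1 jack2     m    Q1    Q2 completeness_pct
#>   <int> <dbl> <dbl> <int> <int> <int>            <dbl>
#> 1    97 100.0  94.1   192     3     9             103.

head(res$basin_diversity, 4)
#> # A tibble: 4 × 4
#>   unit   richness endemic_count area_km2
#>   <chr>     <int>         <int>    <dbl>
#> 1 B1_1_1       25            19  437212.
#> 2 B1_1_2       29            25  437212.
#> 3 B1_2_1       25            20  444505.
#> 4 B1_2_2       25            18  444505.
```

Of 3,000 generated records, the three filters removed 23.7%, 40.7% and
17.4%, leaving 547 curated records (18.2%) — the per-stage counts agree
exactly with the generator's truth ledger (`res$ledger`). The 97 observed
species across 192 sampling years carry few uniques (Q₁ = 3) relative to
duplicates (Q₂ = 9), so the second-order jackknife (94.1) sits slightly
below the observed richness: this pool is effectively censused. Per-basin
tables give richness, the endemic subset and clipped spherical areas;
`res$similarity`, `res$dendrogram` and `res$groups` hold the compositional
clustering, and `tidy(res$area_fit)` the richness–area Poisson
coefficients.

Plots: `autoplot(res$filter_report)`, `plot_accumulation(res$accumulation)`,
`plot_temporal(res$temporal)`, `autoplot(res$area_fit)`.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/amazodex.R synth --seed 1 --out data/
Rscript inst/cli/amazodex.R run  --config cfg.yaml --out out/
```

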