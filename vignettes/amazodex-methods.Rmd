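---
title: "Curating and analysing Amazonian amphibian occurrence data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and analysing Amazonian amphibian occurrence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amazodex)
```

## The problem

Large-scale biodiversity syntheses for the Amazon aggregate occurrence
records from aggregator platforms (GBIF, SpeciesLink, VertNet, SiBBr,
SISBIO), literature and fieldwork. Raw pulls are dominated by records that
cannot support spatial analysis: names with open-nomenclature qualifiers,
outdated synonyms, missing or vague coordinates, and points (or whole
species) that do not belong to the biome at all. amazodex implements the
standard three-filter curation sequence and the downstream diversity
analysis as one tested, reproducible pipeline, and ships a synthetic-data
generator with exact ground truth so every stage can be verified without
network access.

## The three validation filters

Filters run in a fixed order — taxonomic, geographic, biogeographic —
because exclusion counts are sequential: each stage only sees the previous
stage's survivors, and the conservation identity
`n_initial = n_retained + sum(per-stage exclusions)` is enforced by
`filter_accounting()`, never assumed.

**Filter 1 (taxonomic refinement).** `parse_scientific_name()` detects the
open-nomenclature markers *cf* (confer), *gr* (group), *aff* (affine) and
*sp*, case-insensitively, with or without a trailing period, anywhere after
the genus; the marker list is config-extensible because sources vary in
their uncertainty conventions. "sp. nov."/"n. sp." are treated as *sp* (a
name not yet usable as a binomial), subgenus parentheses and author–year
remnants are stripped, and trinomials collapse to the binomial since the
analysis is species-level. Surviving names are resolved against the
reference table by exact lookup (accepted names first, then the synonym
map); fuzzy matching is deliberately out of scope. Clean binomials absent
from the reference are excluded under the default `strict` policy; the
`lenient` policy keeps them flagged, standing in for voucher
re-confirmation, which cannot be done computationally.

**Filter 2 (geographic).** Coordinates may arrive as decimal or DMS text;
`dms_to_decimal()` converts with the hemisphere letter or leading minus
carrying the sign, and rejects minutes/seconds ≥ 60 or contradictory signs.
Each record then gets exactly one outcome: `missing`, `out_of_range`,
`zero_zero`, `admin_level` (precision described as municipality, state or
country), `too_imprecise` (uncertainty radius strictly greater than 20 km —
exactly 20 km passes), or `ok`. Records with coordinates but no uncertainty
metadata are judged by their stated precision level; absent metadata is not
itself grounds for exclusion. (0, 0) is excluded by default as a well-known
data-entry artifact, with a config switch, since conventions differ. No
datum transformation is attempted: inputs are taken to be WGS84.

**Filter 3 (biogeographic).** Points are tested against the biome boundary
with a *closed* boundary convention — a record exactly on the limit is kept,
because peripheral noise is already handled by the 20 km precision rule and
boundary populations are the object of interest. The expert-judgment review
of dubiously-occurring species is modelled as a data table: a species whose
documented biome codes lack `AM` is dropped entirely (all its records), and
the dropped list is exported. The boundary polygon is used unbuffered.

## Regionalization

Sub-basins come from a nested hierarchy. In `auto` mode the selector
descends each branch only while *every* child clears the 30,000 km² area
threshold (strict `>`), which yields the deepest uniform coverage per
branch with no overlaps; in `zonal` mode explicit zone polygons each name
the hierarchy level to use, reproducing the practice of taking finer levels
in the west where basins are smaller. Clipping to the biome and area
recomputation follow selection.

Areas are spherical (R = 6371 km) and treat polygon edges as straight in
lon/lat space, integrating `sin(lat) d lon` in closed form along each edge.
This makes areas exactly additive under lon/lat tiling — children of a
subdivided basin sum to their parent to machine precision — which the
partition invariants rely on; great-circle edge conventions do not have
this property. The difference is far below the 30,000 km² threshold
granularity. The 50 × 50 km grid lives in a cylindrical equal-area
projection centred on the biome centroid, with the origin at the projected
bounding-box minimum; every point maps to exactly one cell by construction.
Points on shared basin borders (inside several closed polygons) go to the
lexicographically lowest region id, a deterministic tie-break independent
of row order.

## Diversity statistics

All statistics run off a sampling-unit × species incidence matrix
(`build_incidence()`), whose derived counts are the number of units `m`,
per-species incidences `m_i`, and the uniques/duplicates counts `Q1`, `Q2`.

- **Richness and endemism** per unit; endemic means the documented
  distribution code set is exactly `{AM}`.
- **Jaccard similarity** `|A ∩ B| / |A ∪ B|`, with `J(∅, ∅) = 1` by
  decision (a warning is raised; two empty units are vacuously identical).
- **UPGMA clustering** on `1 − J` (via average-linkage `hclust`). The
  linkage is a package decision — UPGMA is the standard for compositional
  dendrograms — and is the only linkage exposed. Groups are read off by
  cutting at a similarity threshold, default 0.40, the background level
  below which basin compositions are treated as unrelated.
- **Accumulation curves** with years as samples: the exact hypergeometric
  expectation `E[S(t)] = Σ_i (1 − C(m − m_i, t)/C(m, t))` (computed on the
  log scale for stability) or a seeded permutation average with 2.5/97.5%
  envelopes. Records without a year are excluded from accumulation only.
- **Jackknife estimators**:
  `jack1 = S_obs + Q1 (m−1)/m` and
  `jack2 = S_obs + Q1 (2m−3)/m − Q2 (m−2)²/(m(m−1))`, undefined for
  `m < 2`. The second-order estimator can fall below `S_obs` when
  duplicates outnumber uniques; it is reported as computed.
- **Richness–area model**: Poisson GLM with log link, fitted by IRLS
  (`glm`, convergence 1e-12, max 100 iterations). The covariate defaults to
  `log(area)` — the conventional species–area form — with raw area
  available, since the choice is not determined by the analysis the
  pipeline reproduces.

## The synthetic generator and what it does (not) emulate

`synth_config()` defaults define the emulated study conditions: 10,000
records split across eight sources in proportion to the real platforms'
shares; defect rates set so the three filters remove about 24%, 39% and
18% of the initial records and about 18% survive, matching the published
accounting shape; an 81.8% endemic fraction; a 15% dubious-species
fraction; years 1818–2021. A 120-species pool over a 24° × 18° biome with
a 3/2/2-way nested basin split keeps a full run around a second while
leaving every per-region composition non-trivial; the acceptance checks
use these sizes, and the heaviest single check (truth-ledger recovery) runs
the full 10,000-record pipeline.

Defects are applied independently per record in a fixed order (name, then
coordinates, then placement), so a record can carry several; the ledger
records the *first* stage that should exclude it, mirroring sequential
filtering, which is what makes per-stage exclusion counts exactly
predictable from labels rather than only in expectation. Points are drawn
by rejection sampling into the target basin polygon.

The generator does *not* emulate spatial sampling bias (rivers, roads,
research stations), spatially autocorrelated ranges, detection differences
among sources, or cross-platform duplicate records. Passing tests therefore
demonstrate that the machinery is correct under known truth — not that real
aggregator data meet these assumptions; on real data the optional
exact-duplicate collapse and the lenient taxonomy policy become relevant.

## Numerical and edge-case decisions

- Printed shares use half-away-from-zero rounding (`percent()`), the
  convention under which 39.459 prints as 39.5; base `round()`'s
  half-to-even would disagree on exact halves.
- A "site" is a unique coordinate pair rounded to 4 decimals (~11 m); the
  precision is a config key because site definitions vary among studies.
- IUCN "NA / not assessed" is stored as NE; DD and NE are never pooled
  into the threatened share (CR + EN + VU), and a family is flagged only
  strictly above 30% threatened.
- Decades are `floor(year/10)·10`; yearless records are counted separately.
- Polygon clipping (Sutherland–Hodgman) requires a convex clip region;
  biome rectangles satisfy this. Self-intersecting input rings are rejected
  (or skipped on request), not repaired.
- Empty-intersection regions are dropped and reported, never silently lost;
  the same no-silent-loss rule applies to the occurrence readers
  (`rows in = records out + rejected with reasons`).

## Known limitations

General concave-biome clipping, gazetteer geocoding, fuzzy name matching,
datum transformations, Chao/ICE estimators and significance tests on
cluster structure are out of scope. The dendrogram cut is a hard threshold,
not a bootstrap-supported grouping. Spherical (not ellipsoidal) areas are
used throughout; the relative error (~0.3%) is negligible against the
area-selection threshold.
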