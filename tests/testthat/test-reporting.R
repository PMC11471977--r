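# Percent convention, filter accounting, IUCN, temporal and source summaries.

test_that("percent rounds half away from zero to the requested precision", {
  expect_equal(percent(775, 947, 1), 81.8)
  expect_equal(percent(947, 1262, 0), 75)
  expect_equal(percent(0, 10, 1), 0)
  expect_equal(percent(39459, 100000, 1), 39.5)   # x.x5 rounds up, not to even
  expect_equal(percent(125, 1000, 1), 12.5)
  expect_equal(percent(1245, 10000, 1), 12.5)     # 12.45 -> 12.5
  expect_error(percent(1, 0), "denominator")
})

test_that("filter accounting verifies the conservation identity", {
  stages <- tibble::tibble(
    stage = c("taxonomic", "geographic", "biogeographic"),
    n_in = c(902986L, 682660L, 326351L),
    n_excluded = c(220326L, 356309L, 165708L),
    n_retained = c(682660L, 326351L, 160643L),
    species_retained = NA_integer_)
  rep <- filter_report(902986L, stages)
  acc <- filter_accounting(rep)
  expect_equal(acc$n[acc$stage == "retained"], 160643)
  expect_equal(acc$pct_of_initial,
               c(24.4, 39.5, 18.4, 17.8))
  expect_equal(percent(sum(stages$n_excluded), 902986, 0), 82)

  broken <- filter_report(902986L,
                          dplyr::mutate(stages, n_excluded = c(1L, 1L, 1L)))
  expect_error(filter_accounting(broken), "identity")
  unchained <- stages
  unchained$n_in[2] <- 999L
  expect_error(filter_accounting(filter_report(902986L, unchained)), "chain")
})

test_that("all-zero exclusions give retained = initial", {
  stages <- tibble::tibble(
    stage = c("taxonomic", "geographic", "biogeographic"),
    n_in = c(10L, 10L, 10L), n_excluded = 0L, n_retained = 10L,
    species_retained = 3L)
  acc <- filter_accounting(filter_report(10L, stages))
  expect_equal(acc$n[acc$stage == "retained"], 10)
})

test_that("IUCN summary pools CR/EN/VU as threatened and flags strictly above 30%", {
  tax <- as_taxon_table(tibble::tibble(
    accepted_name = paste("Genus", letters[1:20]),
    order = "Anura",
    family = rep(c("Fam40", "Fam30"), each = 10),
    genus = "Genus",
    synonyms = rep(list(character(0)), 20),
    biome_codes = rep(list("AM"), 20),
    iucn_category = c(c("CR", "EN", "VU", "VU", rep("LC", 6)),   # 40%
                      c("CR", "EN", "VU", rep("LC", 6), "DD"))   # 30%
  ))
  s <- iucn_summary(tax)
  fam <- s$families
  expect_true(fam$flagged[fam$family == "Fam40"])
  expect_false(fam$flagged[fam$family == "Fam30"])   # exactly 30% is NOT flagged
  expect_equal(s$n_threatened, 7)
  expect_equal(s$categories$n[s$categories$category == "DD"], 1)
  expect_equal(sum(s$categories$n), 20)
})

test_that("per-category threatened counts add up to the pooled total", {
  # from printed per-category species counts: 48 CR + 104 EN + 56 VU = 208
  expect_equal(48 + 104 + 56, 208)
  expect_equal(percent(208, 947, 0), 22)
  expect_equal(percent(48, 947, 1), 5.1)
  expect_equal(percent(104, 947, 0), 11)
  expect_equal(percent(56, 947, 1), 5.9)
})

test_that("temporal summary bins by decade with non-decreasing cumulative species", {
  recs <- make_records(rep(NA_character_, 6),
                       accepted = c("a", "b", "a", "c", "c", "d"),
                       year = c(1818, 1819, 1955, 1957, 2003, NA))
  ts <- temporal_summary(recs)
  expect_equal(ts$decade, c(1810, 1950, 2000))
  expect_equal(ts$n_records, c(2, 2, 1))
  expect_equal(ts$cum_species, c(2, 3, 3))
  expect_true(all(diff(ts$cum_species) >= 0))
  expect_equal(attr(ts, "n_yearless"), 1)
  shuffled <- temporal_summary(recs[c(5, 3, 6, 1, 4, 2), ])
  expect_equal(as.data.frame(shuffled), as.data.frame(ts))
})

test_that("single-decade data collapses to one bin equal to richness", {
  recs <- make_records(rep(NA_character_, 3), accepted = c("a", "b", "b"),
                       year = c(1991, 1995, 1999))
  ts <- temporal_summary(recs)
  expect_equal(nrow(ts), 1)
  expect_equal(ts$cum_species, 2)
})

test_that("source summaries tally records, species, sites and marginal gains", {
  recs <- make_records(rep(NA_character_, 6),
                       accepted = c("a", "b", "c", "c", "d", "d"),
                       lat = c(1, 1, 2, 2, 2.00001, 3),
                       lon = -60,
                       source = c("gbif", "gbif", "gbif", "vertnet", "vertnet",
                                  "sibbr"))
  s <- source_complementarity(recs)
  gb <- s$sources[s$sources$source_id == "gbif", ]
  expect_equal(gb$n_records, 3)
  expect_equal(gb$n_species, 3)
  expect_equal(gb$n_sites, 2)      # (1,-60) and (2,-60); 4-decimal rounding
  expect_equal(sum(s$sources$n_records), 6)
  comp <- s$complementarity
  expect_equal(comp$source_id[1], "gbif")   # biggest pool first
  expect_equal(sum(comp$marginal_species_gain), 4)  # union over all sources
  expect_equal(comp$cum_species[nrow(comp)], 4)
})

test_that("one source owns all totals; disjoint sources sum to total richness", {
  one <- source_complementarity(make_records(rep(NA_character_, 3),
                                             accepted = c("a", "b", "b")))
  expect_equal(nrow(one$sources), 1)
  expect_equal(one$complementarity$marginal_species_gain, 2)
  two <- source_complementarity(make_records(
    rep(NA_character_, 4), accepted = c("a", "b", "c", "d"),
    source = c("x", "x", "y", "y")))
  expect_equal(sum(two$complementarity$marginal_species_gain), 4)
})
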