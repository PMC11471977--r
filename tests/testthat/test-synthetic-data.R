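# The generator: landscape partitioning, defect rates, and the truth ledger.

test_that("landscape levels partition the biome with matching area sums", {
  land <- generate_landscape(splits = c(3, 2, 2))
  biome_area <- land$area_km2[land$region_id == "BIOME"]
  for (lvl in 1:3) {
    expect_equal(sum(land$area_km2[land$level == lvl]), biome_area,
                 tolerance = 1e-3)
  }
  # children partition their parent
  for (pid in land$region_id[land$level == 2]) {
    kids <- land[!is.na(land$parent_id) & land$parent_id == pid, ]
    expect_equal(sum(kids$area_km2),
                 land$area_km2[land$region_id == pid], tolerance = 1e-3)
  }
})

test_that("degenerate splits give coincident rectangles; 2x2 gives quarters", {
  one <- generate_landscape(splits = c(1, 1, 1))
  expect_equal(nrow(one), 4)  # biome + one basin per level
  areas <- one$area_km2
  expect_true(all(abs(areas - areas[1]) < 1e-6))
  # symmetric about the equator so the two latitude bands have equal area
  quad <- generate_landscape(bounds = c(-60, -48, -6, 6), splits = c(1, 2, 2))
  leaf <- quad[quad$level == 3, ]
  expect_equal(nrow(leaf), 4)
  expect_equal(leaf$area_km2 / quad$area_km2[quad$region_id == "BIOME"],
               rep(0.25, 4), tolerance = 1e-3)
  expect_error(generate_landscape(splits = c(0, 1, 1)), "basin")
})

test_that("generation is deterministic under seed and requires one", {
  cfg <- synth_config(seed = 5, source_counts = c(gbif = 300, vertnet = 200))
  land <- generate_landscape()
  a <- generate_occurrences(cfg, land)
  b <- generate_occurrences(cfg, land)
  expect_identical(a$records, b$records)
  expect_identical(a$ledger$labels, b$ledger$labels)
  expect_error(synth_config(), "seed")
  c <- generate_occurrences(synth_config(seed = 6,
                                         source_counts = c(gbif = 300, vertnet = 200)),
                            land)
  expect_false(identical(a$records$raw_name, c$records$raw_name))
})

test_that("taxonomy truth sets honour the configured fractions exactly", {
  cfg <- synth_config(seed = 12, n_species = 100,
                      dubious_species_fraction = 0.1, endemic_fraction = 0.8)
  tax <- generate_taxonomy(cfg)
  dub <- attr(tax, "dubious_species")
  expect_equal(length(dub), 10)
  no_am <- vapply(tax$biome_codes, function(z) !("AM" %in% z), logical(1))
  expect_equal(sum(no_am), 10)       # exactly the dubious set lacks AM
  expect_setequal(tax$accepted_name[no_am], dub)
  end <- attr(tax, "endemic_species")
  expect_equal(length(end), round(0.8 * 90))
  exactly_am <- vapply(tax$biome_codes, function(z) identical(z, "AM"), logical(1))
  expect_setequal(tax$accepted_name[exactly_am], end)
})

test_that("empirical defect frequencies sit within binomial 3-sigma of the rates", {
  n <- 10000
  cfg <- synth_config(seed = 31, source_counts = c(gbif = n),
                      open_nomenclature_rate = 0.25,
                      missing_coord_rate = 0.3, imprecise_coord_rate = 0.1,
                      outside_biome_rate = 0.2)
  land <- generate_landscape()
  g <- generate_occurrences(cfg, land)
  lab <- g$ledger$labels
  tol3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  open_rate <- mean(startsWith(lab$name_defect, "open_nomenclature"))
  expect_lt(abs(open_rate - 0.25), tol3(0.25))
  expect_lt(abs(mean(lab$coord_defect == "missing") - 0.3), tol3(0.3))
  expect_lt(abs(mean(lab$coord_defect %in% c("too_imprecise", "admin_level")) - 0.1),
            tol3(0.1))
  # stage-1 exclusions: binomial around n * open rate (the spec's 2500 +- 130)
  expect_lt(abs(g$ledger$expected_exclusions$n_excluded[1] - 2500), 130)
})

test_that("zero defect rates let every record survive all three filters", {
  cfg <- synth_config(seed = 8, source_counts = c(gbif = 400),
                      open_nomenclature_rate = 0, missing_coord_rate = 0,
                      imprecise_coord_rate = 0, outside_biome_rate = 0,
                      dubious_species_fraction = 0)
  land <- generate_landscape()
  tax <- generate_taxonomy(cfg)
  g <- generate_occurrences(cfg, land, tax)
  expect_equal(g$ledger$n_retained, 400)
  f1 <- apply_taxonomic_filter(g$records, tax)
  f2 <- apply_geographic_filter(f1$retained)
  f3 <- apply_biogeographic_filter(f2$retained,
                                   land[land$region_id == "BIOME", ], tax)
  expect_equal(nrow(f3$retained), 400)
})

test_that("zero-defect per-region richness equals the ledger composition", {
  cfg <- synth_config(seed = 13, source_counts = c(gbif = 600),
                      open_nomenclature_rate = 0, missing_coord_rate = 0,
                      imprecise_coord_rate = 0, outside_biome_rate = 0,
                      dubious_species_fraction = 0, synonym_use_rate = 0)
  land <- generate_landscape()
  tax <- generate_taxonomy(cfg)
  g <- generate_occurrences(cfg, land, tax)
  f1 <- apply_taxonomic_filter(g$records, tax)
  leaves <- land[land$level == 3, ]
  asg <- assign_records(f1$retained, leaves)
  mat <- build_incidence(f1$retained, asg)
  got <- tidy(mat)
  want <- g$ledger$region_composition
  expect_equal(got$unit, want$region_id)
  expect_equal(got$species, want$species)
})

test_that("synthetic outputs survive a CSV round trip into the readers", {
  cfg <- synth_config(seed = 3, source_counts = c(gbif = 50))
  g <- generate_occurrences(cfg, generate_landscape())
  tax <- generate_taxonomy(cfg)
  rec_path <- withr::local_tempfile(fileext = ".csv")
  tax_path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(g$records, rec_path)
  write_taxon_table(tax, tax_path)
  back <- read_occurrences(rec_path)
  expect_equal(nrow(back), 50)
  expect_equal(back$raw_name, g$records$raw_name)
  expect_equal(back$latitude, g$records$latitude, tolerance = 1e-9)
  tax2 <- read_taxon_table(tax_path)
  expect_setequal(tax2$accepted_name, tax$accepted_name)
  expect_identical(attr(tax2, "synonym_map")[sort(names(attr(tax2, "synonym_map")))],
                   attr(tax, "synonym_map")[sort(names(attr(tax, "synonym_map")))])
})
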