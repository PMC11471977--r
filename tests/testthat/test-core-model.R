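# Readers/writers for occurrence tables, taxon references and GeoJSON regions.

write_occurrence_csv <- function(lines, path = withr::local_tempfile(fileext = ".csv",
                                                                     .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

test_that("occurrence reader parses clean rows, flags defects, converts DMS", {
  path <- write_occurrence_csv(c(
    "occurrenceID,source,scientificName,decimalLatitude,decimalLongitude,coordinateUncertaintyInMeters,year",
    "a1,gbif,Boana boans,-3.1,-60.0,100,1999",
    "a2,gbif,Rhinella marina,,-60.0,100,2000",
    "a3,vertnet,Scinax ruber,\"3°51'36\"\"S\",-58.25,50,2001",
    "a4,vertnet,Boana boans,not-a-coord,-58,50,2002"
  ))
  recs <- read_occurrences(path)
  expect_equal(nrow(recs), 4)
  expect_equal(recs$latitude[1], -3.1)
  expect_equal(recs$flags[1], "")
  # empty latitude -> absent coordinates plus MISSING_COORD
  expect_true(is.na(recs$latitude[2]))
  expect_true(has_flag(recs$flags, "MISSING_COORD")[2])
  # DMS converted: 3 + 51/60 + 36/3600 = 3.86, south negative
  expect_equal(recs$latitude[3], -3.86, tolerance = 1e-12)
  # unparseable cell -> NA + parse flag, never a crash
  expect_true(is.na(recs$latitude[4]))
  expect_true(has_flag(recs$flags, "COORD_PARSE_FAIL")[4])
})

test_that("occurrence reader errors on missing mandatory columns and detects delimiters", {
  bad <- write_occurrence_csv(c("source,decimalLatitude", "gbif,1"))
  expect_error(read_occurrences(bad), "scientificName")
  tsv <- write_occurrence_csv(c(
    "occurrenceID\tsource\tscientificName\tdecimalLatitude\tdecimalLongitude",
    "t1\tgbif\tBoana boans\t-1\t-60"))
  expect_equal(read_occurrences(tsv)$longitude, -60)
  semi <- write_occurrence_csv(c(
    "occurrenceID;source;scientificName;decimalLatitude;decimalLongitude",
    "s1;gbif;Boana boans;-1;-60"))
  expect_equal(read_occurrences(semi)$raw_name, "Boana boans")
})

test_that("occurrence write/read round-trips every field for clean inputs", {
  recs <- make_records(c("Boana boans", "Scinax ruber"),
                       lat = c(-3.25, 1.5), lon = c(-60.125, -55),
                       unc = c(120, 40), year = c(1999, 2021))
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(recs, path)
  back <- read_occurrences(path)
  expect_equal(as.data.frame(back), as.data.frame(recs))
})

test_that("taxon reader merges duplicates, maps NA to NE, rejects conflicts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "accepted_name,order,family,genus,synonyms,biome_codes,iucn",
    "Boana boans,Anura,Hylidae,Boana,Hypsiboas boans,AM,LC",
    "Boana boans,Anura,Hylidae,Boana,Hyla boans,AM|AF,LC",
    "Scinax ruber,Anura,Hylidae,Scinax,,AM,NA"
  ), path)
  tax <- read_taxon_table(path)
  expect_equal(nrow(tax), 2)
  i <- match("Boana boans", tax$accepted_name)
  expect_setequal(tax$synonyms[[i]], c("Hypsiboas boans", "Hyla boans"))
  expect_setequal(tax$biome_codes[[i]], c("AM", "AF"))
  # paper-style "not assessed (NA)" stored as NE
  expect_equal(tax$iucn_category[match("Scinax ruber", tax$accepted_name)], "NE")
  map <- attr(tax, "synonym_map")
  expect_equal(unname(map["Hypsiboas boans"]), "Boana boans")

  conflict <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "accepted_name,order,family,genus,synonyms,biome_codes,iucn",
    "Boana boans,Anura,Hylidae,Boana,Hyla vieja,AM,LC",
    "Scinax ruber,Anura,Hylidae,Scinax,Hyla vieja,AM,LC"
  ), conflict)
  expect_error(read_taxon_table(conflict), "Hyla vieja")
})

test_that("GeoJSON regions round-trip; missing level defaults with warning", {
  rs <- region_set(c("A", "B"),
                   list(rect_geometry(0, 1, 0, 1), rect_geometry(1, 2, 0, 1)),
                   level = c(1L, 1L))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_regions(rs, path)
  back <- read_regions(path)
  expect_equal(back$region_id, rs$region_id)
  expect_equal(back$area_km2, rs$area_km2, tolerance = 1e-9)
  expect_equal(back$geometry[[1]], rs$geometry[[1]], ignore_attr = TRUE)

  bare <- withr::local_tempfile(fileext = ".geojson")
  writeLines(paste0(
    '{"type":"FeatureCollection","features":[{"type":"Feature",',
    '"properties":{"name":"sq"},"geometry":{"type":"Polygon",',
    '"coordinates":[[[0,0],[1,0],[1,1],[0,1],[0,0]]]}}]}'), bare)
  expect_warning(b <- read_regions(bare), "level")
  expect_equal(b$level, 0L)
  expect_equal(nrow(b$geometry[[1]][[1]]), 4)
})

test_that("read_regions rejects self-intersecting rings naming the feature", {
  bow <- withr::local_tempfile(fileext = ".geojson")
  writeLines(paste0(
    '{"type":"FeatureCollection","features":[{"type":"Feature",',
    '"properties":{"region_id":"bowtie","level":1},"geometry":{"type":"Polygon",',
    '"coordinates":[[[0,0],[1,1],[1,0],[0,1],[0,0]]]}}]}'), bow)
  expect_error(read_regions(bow), "bowtie")
  expect_warning(skipped <- try(read_regions(bow, on_invalid = "skip"), silent = TRUE),
                 "bowtie")
})

test_that("spherical area matches the closed-form spherical zone formula", {
  # R^2 * dlambda * (sin(lat2) - sin(lat1)), R = 6371 km
  sq <- rect_geometry(0, 1, 0, 1)
  expected <- 6371^2 * (pi / 180) * (sin(pi / 180) - 0)
  expect_equal(polygon_area_km2(sq), expected, tolerance = 0.005)
  # holes subtract
  holed <- c(rect_geometry(0, 4, 0, 4), rect_geometry(1, 2, 1, 2))
  expect_equal(polygon_area_km2(holed),
               polygon_area_km2(rect_geometry(0, 4, 0, 4)) -
                 polygon_area_km2(rect_geometry(1, 2, 1, 2)),
               tolerance = 1e-9)
  # invariant to starting vertex of the ring
  ring <- rect_geometry(-70, -60, -10, 0)[[1]]
  rotated <- list(ring[c(3, 4, 1, 2), ])
  expect_equal(polygon_area_km2(list(ring)), polygon_area_km2(rotated))
  # agrees with an independent geodesic implementation once the ring is
  # densified so both follow (near-)identical paths
  dense <- cbind(lon = c(seq(-70, -60, 0.02), seq(-60, -70, -0.02)),
                 lat = c(rep(-10, 501), rep(0, 501)))
  expect_equal(polygon_area_km2(list(ring)),
               abs(geosphere::areaPolygon(dense, a = 6371000, f = 0)) / 1e6,
               tolerance = 1e-4)
})
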