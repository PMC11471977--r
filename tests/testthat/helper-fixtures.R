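# Shared fixtures, built in code.

# minimal taxon reference: 4 species; one synonym pair; one non-Amazon species
tiny_taxonomy <- function() {
  as_taxon_table(tibble::tibble(
    accepted_name = c("Boana boans", "Rhinella marina",
                      "Pristimantis fenestratus", "Scinax ruber"),
    order = "Anura",
    family = c("Hylidae", "Bufonidae", "Strabomantidae", "Hylidae"),
    genus = c("Boana", "Rhinella", "Pristimantis", "Scinax"),
    synonyms = list("Hypsiboas boans", character(0), character(0),
                    "Hyla rubra"),
    biome_codes = list("AM", c("AM", "CE"), "AM", c("AF", "CE")),
    iucn_category = c("LC", "LC", "EN", "LC")
  ))
}

# occurrence tibble builder with clean defaults
make_records <- function(raw_name, lat = 0.5, lon = -60, unc = 100,
                         precision = "point", year = 2000, source = "gbif",
                         accepted = NA_character_) {
  n <- length(raw_name)
  tibble::tibble(
    record_id = sprintf("r%03d", seq_len(n)),
    source_id = rep_len(source, n),
    raw_name = raw_name,
    accepted_name = rep_len(accepted, n),
    latitude = rep_len(lat, n),
    longitude = rep_len(lon, n),
    coordinate_uncertainty_m = rep_len(unc, n),
    locality_precision = rep_len(precision, n),
    year = as.integer(rep_len(year, n)),
    flags = ""
  )
}

# winding-number containment oracle, independent of the ray-casting path
winding_number_inside <- function(px, py, ring) {
  ring <- as.matrix(ring)
  n <- nrow(ring)
  wn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[j, 1]; y2 <- ring[j, 2]
    if (y1 <= py) {
      if (y2 > py && (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) > 0) wn <- wn + 1
    } else {
      if (y2 <= py && (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# random star-shaped (hence simple) polygon around a centre
random_simple_polygon <- function(n_vertices = 8) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- stats::runif(n_vertices, 0.3, 1)
  list(cbind(lon = cos(ang) * rad, lat = sin(ang) * rad))
}

random_incidence <- function(n_units, n_species, p = 0.3) {
  m <- matrix(stats::runif(n_units * n_species) < p, n_units, n_species,
              dimnames = list(paste0("u", seq_len(n_units)),
                              paste0("s", seq_len(n_species))))
  new_incidence_matrix(m)
}
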