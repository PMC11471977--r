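# Synthetic occurrence datasets with known ground truth. The generator
# emulates multi-platform occurrence pulls (GBIF-, SpeciesLink-, VertNet-,
# SiBBr-, SISBIO-like sources plus literature and fieldwork) over a nested
# drainage-basin landscape: controlled rates of open-nomenclature markers,
# synonym usage, missing/imprecise coordinates, out-of-biome points and
# dubious-distribution species, each record carrying the defect labels used
# to produce it, so every downstream filter can be checked exactly.

#' Synthetic-generator configuration
#'
#' Defaults emulate the study conditions of a continental multi-platform
#' occurrence compilation: per-source record counts proportional to the
#' eight real source shares, per-stage defect rates chosen so the three
#' filters remove roughly 24%, 39% and 18% of the initial records, an 82%
#' endemic fraction, and a 1818–2021 year range.
#'
#' @param seed Integer seed; mandatory (reproducibility is part of the
#'   contract).
#' @param n_species Size of the species pool.
#' @param source_counts Named integer vector of per-source record counts.
#' @param open_nomenclature_rate Probability a record's name carries an
#'   uncertainty marker (cf/gr/aff/sp) — excluded at stage 1.
#' @param synonym_use_rate Probability a clean name is written as a synonym
#'   (resolved, not excluded).
#' @param missing_coord_rate Probability coordinates are absent — stage 2.
#' @param imprecise_coord_rate Probability the record is too imprecise
#'   (uncertainty drawn above 20 km, or administrative-level precision) —
#'   stage 2.
#' @param outside_biome_rate Probability the point is displaced outside the
#'   biome — stage 3.
#' @param dubious_species_fraction Fraction of the species pool lacking the
#'   biome code (all their records die at stage 3).
#' @param endemic_fraction Fraction of the in-biome species whose
#'   distribution code set is exactly the biome (the endemism definition).
#' @param year_range Inclusive sampling-year range.
#' @param n_regions_per_species Mean number of leaf basins a species
#'   occupies (controls per-region composition).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_species = 120,
                         source_counts = c(gbif = 3594, sibbr = 2594,
                                           specieslink = 2000, vertnet = 759,
                                           sisbio = 543, grey_literature = 432,
                                           articles = 39, fieldwork = 39),
                         open_nomenclature_rate = 0.244,
                         synonym_use_rate = 0.20,
                         missing_coord_rate = 0.45,
                         imprecise_coord_rate = 0.072,
                         outside_biome_rate = 0.40,
                         dubious_species_fraction = 0.15,
                         endemic_fraction = 0.818,
                         year_range = c(1818, 2021),
                         n_regions_per_species = 4) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for synthetic generation", call. = FALSE)
  }
  rates <- c(open_nomenclature_rate, synonym_use_rate, missing_coord_rate,
             imprecise_coord_rate, outside_biome_rate,
             dubious_species_fraction, endemic_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (missing_coord_rate + imprecise_coord_rate > 1) {
    stop("missing + imprecise coordinate rates exceed 1", call. = FALSE)
  }
  if (any(source_counts < 0)) stop("record counts must be >= 0", call. = FALSE)
  structure(list(
    seed = as.integer(seed), n_species = n_species,
    source_counts = source_counts,
    open_nomenclature_rate = open_nomenclature_rate,
    synonym_use_rate = synonym_use_rate,
    missing_coord_rate = missing_coord_rate,
    imprecise_coord_rate = imprecise_coord_rate,
    outside_biome_rate = outside_biome_rate,
    dubious_species_fraction = dubious_species_fraction,
    endemic_fraction = endemic_fraction,
    year_range = year_range,
    n_regions_per_species = n_regions_per_species
  ), class = "synth_config")
}

#' Generate a nested-basin landscape
#'
#' Builds a rectangular biome with a 3-level nested basin hierarchy:
#' level 1 splits the biome into longitudinal strips, level 2 splits each
#' strip latitudinally, level 3 splits again longitudinally. Children
#' exactly partition their parent, so areas sum across levels.
#'
#' @param bounds Biome rectangle `c(xmin, xmax, ymin, ymax)` in degrees;
#'   the default spans a western-Amazon-sized window.
#' @param splits Integer vector `c(n1, n2, n3)`: children per parent at
#'   each level.
#' @return A `region_set` holding the biome (level 0, id `BIOME`) and all
#'   basins (levels 1–3, ids like `B2`, `B2_1`, `B2_1_3`).
#' @export
generate_landscape <- function(bounds = c(-75, -51, -15, 3),
                               splits = c(3, 2, 2)) {
  if (length(splits) != 3 || any(splits < 1)) {
    stop("splits must give >= 1 basin per level", call. = FALSE)
  }
  xmin <- bounds[1]; xmax <- bounds[2]; ymin <- bounds[3]; ymax <- bounds[4]
  ids <- "BIOME"; geoms <- list(rect_geometry(xmin, xmax, ymin, ymax))
  levels <- 0L; parents <- NA_character_
  push <- function(id, geom, lvl, parent) {
    ids <<- c(ids, id); geoms[[length(geoms) + 1]] <<- geom
    levels <<- c(levels, lvl); parents <<- c(parents, parent)
  }
  xcuts1 <- seq(xmin, xmax, length.out = splits[1] + 1)
  for (i in seq_len(splits[1])) {
    id1 <- paste0("B", i)
    push(id1, rect_geometry(xcuts1[i], xcuts1[i + 1], ymin, ymax), 1L, "BIOME")
    ycuts2 <- seq(ymin, ymax, length.out = splits[2] + 1)
    for (j in seq_len(splits[2])) {
      id2 <- paste0(id1, "_", j)
      push(id2, rect_geometry(xcuts1[i], xcuts1[i + 1],
                              ycuts2[j], ycuts2[j + 1]), 2L, id1)
      xcuts3 <- seq(xcuts1[i], xcuts1[i + 1], length.out = splits[3] + 1)
      for (k in seq_len(splits[3])) {
        id3 <- paste0(id2, "_", k)
        push(id3, rect_geometry(xcuts3[k], xcuts3[k + 1],
                                ycuts2[j], ycuts2[j + 1]), 3L, id2)
      }
    }
  }
  region_set(ids, geoms, level = levels, parent_id = parents, validate = FALSE)
}

# deterministic latinate epithets: first n unique 3-syllable combinations
synth_epithets <- function(n) {
  syl <- c("ama", "zon", "flu", "via", "sil", "ves", "ter", "ric",
           "ola", "pal", "ust", "ris", "mon", "tan", "ell", "ula")
  out <- character(0)
  for (a in syl) for (b in syl) {
    out <- c(out, paste0(a, b, "a"))
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("epithet pool exhausted", call. = FALSE)
}

synth_genera <- function() {
  tibble::tibble(
    genus = c("Rhinella", "Boana", "Pristimantis", "Allobates", "Osteocephalus",
              "Scinax", "Leptodactylus", "Adenomera", "Ameerega",
              "Dendropsophus", "Caecilia", "Bolitoglossa"),
    family = c("Bufonidae", "Hylidae", "Strabomantidae", "Aromobatidae",
               "Hylidae", "Hylidae", "Leptodactylidae", "Leptodactylidae",
               "Dendrobatidae", "Hylidae", "Caeciliidae", "Plethodontidae"),
    order = c(rep("Anura", 10), "Gymnophiona", "Caudata"),
    old_genus = c("Bufo", "Hypsiboas", "Eleutherodactylus", "Colostethus",
                  "Hyla", "Hyla", "Leptodactylus", "Leptodactylus",
                  "Epipedobates", "Hyla", "Caecilia", "Bolitoglossa")
  )
}

#' Generate a synthetic taxon reference
#'
#' Builds `n_species` accepted binomials over a fixed genus pool, assigns a
#' synonym (under a historical genus name) to roughly half the species,
#' marks a `dubious_species_fraction` of the pool as lacking the biome code
#' (their distribution is other biomes only), sets an `endemic_fraction` of
#' the remaining species to the exact-biome code set `{AM}`, and draws IUCN
#' categories with probabilities close to continental amphibian shares.
#'
#' @param config A [synth_config()].
#' @return A `taxon_table`; attributes `dubious_species` and
#'   `endemic_species` carry the truth sets.
#' @export
generate_taxonomy <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed + 1L, {
    n <- config$n_species
    gen <- synth_genera()
    gi <- sort(rep_len(seq_len(nrow(gen)), n))
    epi <- synth_epithets(n)
    accepted <- paste(gen$genus[gi], epi)
    has_syn <- stats::runif(n) < 0.5
    synonyms <- ifelse(has_syn, paste(gen$old_genus[gi], epi), NA_character_)
    # a synonym equal to its accepted name (same genus kept) is dropped
    synonyms[!is.na(synonyms) & synonyms == accepted] <- NA_character_
    n_dubious <- round(config$dubious_species_fraction * n)
    dubious_idx <- if (n_dubious > 0) sample.int(n, n_dubious) else integer(0)
    other_codes <- c("AF", "AN", "CA", "CE", "CH", "CB", "PA", "PM", "PN", "SPA")
    in_biome_idx <- setdiff(seq_len(n), dubious_idx)
    n_endemic <- round(config$endemic_fraction * length(in_biome_idx))
    endemic_idx <- sample(in_biome_idx, n_endemic)
    biome_codes <- vector("list", n)
    for (i in seq_len(n)) {
      if (i %in% dubious_idx) {
        biome_codes[[i]] <- sort(sample(other_codes, sample(1:3, 1)))
      } else if (i %in% endemic_idx) {
        biome_codes[[i]] <- "AM"
      } else {
        biome_codes[[i]] <- sort(c("AM", sample(other_codes, sample(1:2, 1))))
      }
    }
    iucn_levels <- c("LC", "EN", "DD", "VU", "CR", "NT", "NE")
    iucn_probs <- c(0.62, 0.11, 0.072, 0.059, 0.051, 0.046, 0.041)
    iucn <- sample(iucn_levels, n, replace = TRUE,
                   prob = iucn_probs / sum(iucn_probs))
    tab <- as_taxon_table(tibble::tibble(
      accepted_name = accepted,
      order = gen$order[gi], family = gen$family[gi], genus = gen$genus[gi],
      synonyms = lapply(synonyms, function(s) if (is.na(s)) character(0) else s),
      biome_codes = biome_codes,
      iucn_category = iucn
    ))
    attr(tab, "dubious_species") <- accepted[dubious_idx]
    attr(tab, "endemic_species") <- accepted[sort(endemic_idx)]
    tab
  })
}

sample_point_in_geometry <- function(geometry, n) {
  bb <- geometry_bbox(geometry)
  lon <- numeric(0); lat <- numeric(0)
  while (length(lon) < n) {
    k <- max(16, 2 * (n - length(lon)))
    cx <- stats::runif(k, bb["xmin"], bb["xmax"])
    cy <- stats::runif(k, bb["ymin"], bb["ymax"])
    ok <- point_in_polygon(cx, cy, geometry)
    lon <- c(lon, cx[ok]); lat <- c(lat, cy[ok])
  }
  list(lon = lon[seq_len(n)], lat = lat[seq_len(n)])
}

#' Generate synthetic occurrence records with a truth ledger
#'
#' Draws records per source over the landscape's leaf basins: each species
#' occupies a fixed random set of leaf basins; records pick a basin, a
#' species from its pool, a uniform point inside the basin, and a sampling
#' year. Defects are then applied independently per record in a fixed order
#' (name, coordinates, placement), and the ledger records the *first*
#' pipeline stage that should exclude each record, mirroring sequential
#' filtering.
#'
#' @param config A [synth_config()].
#' @param landscape A landscape from [generate_landscape()].
#' @param taxonomy A taxon table from [generate_taxonomy()] (regenerated
#'   from `config` when omitted).
#' @return List with `records` (occurrence tibble) and `ledger` (class
#'   `truth_ledger`): per-record labels, the expected per-stage exclusion
#'   counts, survivor count, and the zero-defect per-region composition.
#' @export
generate_occurrences <- function(config, landscape = generate_landscape(),
                                 taxonomy = generate_taxonomy(config)) {
  stopifnot(inherits(config, "synth_config"))
  leaf <- landscape[landscape$level == max(landscape$level), ]
  biome_geom <- landscape$geometry[[match("BIOME", landscape$region_id)]]
  n <- sum(config$source_counts)
  withr::with_seed(config$seed + 2L, {
    n_leaf <- nrow(leaf)
    # fixed species->basin affinity defines the true composition potential
    pool_of <- lapply(seq_len(config$n_species), function(i) {
      k <- min(n_leaf, max(1, stats::rpois(1, config$n_regions_per_species - 1) + 1))
      sort(sample.int(n_leaf, k))
    })
    species_by_leaf <- lapply(seq_len(n_leaf), function(r) {
      which(vapply(pool_of, function(p) r %in% p, logical(1)))
    })
    # every leaf basin must host at least one species
    for (r in which(lengths(species_by_leaf) == 0)) {
      sp <- sample.int(config$n_species, 1)
      pool_of[[sp]] <- sort(union(pool_of[[sp]], r))
      species_by_leaf[[r]] <- which(vapply(pool_of, function(p) r %in% p, logical(1)))
    }
    source_id <- rep(names(config$source_counts), config$source_counts)
    region_idx <- sample.int(n_leaf, n, replace = TRUE)
    sp_idx <- vapply(region_idx, function(r) {
      pool <- species_by_leaf[[r]]
      pool[sample.int(length(pool), 1)]
    }, integer(1))
    accepted <- taxonomy$accepted_name[sp_idx]
    year <- sample(seq(config$year_range[1], config$year_range[2]), n,
                   replace = TRUE)
    lon <- numeric(n); lat <- numeric(n)
    for (r in unique(region_idx)) {
      sel <- which(region_idx == r)
      pt <- sample_point_in_geometry(leaf$geometry[[r]], length(sel))
      lon[sel] <- pt$lon; lat[sel] <- pt$lat
    }
    unc <- stats::runif(n, 0, 5000)
    precision <- rep("point", n)
    flags <- rep("", n)

    markers <- c("cf", "gr", "aff", "sp")
    dubious <- attr(taxonomy, "dubious_species")
    syn_of <- vapply(taxonomy$synonyms, function(s) {
      if (length(s) > 0) s[[1]] else NA_character_
    }, character(1))

    # --- name defect ---
    u <- stats::runif(n)
    name_defect <- rep("none", n)
    raw_name <- accepted
    open_nom <- u < config$open_nomenclature_rate
    mk <- sample(markers, n, replace = TRUE)
    gen_part <- vapply(strsplit(accepted, " "), `[[`, character(1), 1)
    epi_part <- vapply(strsplit(accepted, " "), `[[`, character(1), 2)
    raw_name[open_nom] <- ifelse(
      mk[open_nom] == "sp",
      paste0(gen_part[open_nom], " sp."),
      paste0(gen_part[open_nom], " ", mk[open_nom], ". ", epi_part[open_nom]))
    name_defect[open_nom] <- paste0("open_nomenclature:", mk[open_nom])
    use_syn <- !open_nom &
      (stats::runif(n) < config$synonym_use_rate) &
      !is.na(syn_of[sp_idx])
    raw_name[use_syn] <- syn_of[sp_idx][use_syn]
    name_defect[use_syn] <- "synonym"
    with_author <- !open_nom & stats::runif(n) < 0.3
    raw_name[with_author] <- paste0(raw_name[with_author], " (Spix, 1824)")

    # --- coordinate defect ---
    v <- stats::runif(n)
    coord_defect <- rep("none", n)
    miss <- v < config$missing_coord_rate
    lon[miss] <- NA_real_; lat[miss] <- NA_real_
    unc[miss] <- NA_real_
    coord_defect[miss] <- "missing"
    impr <- !miss & v < config$missing_coord_rate + config$imprecise_coord_rate
    impr_kind <- stats::runif(n) < 0.5
    big_unc <- impr & impr_kind
    unc[big_unc] <- stats::runif(sum(big_unc), 20001, 100000)
    coord_defect[big_unc] <- "too_imprecise"
    adm <- impr & !impr_kind
    precision[adm] <- sample(c("municipality", "state", "country"),
                             sum(adm), replace = TRUE)
    coord_defect[adm] <- "admin_level"

    # --- placement defect ---
    w <- stats::runif(n)
    placement_defect <- rep("none", n)
    outside <- !miss & w < config$outside_biome_rate
    if (any(outside)) {
      bb <- geometry_bbox(biome_geom)
      k <- sum(outside)
      side <- sample.int(4, k, replace = TRUE)
      margin <- stats::runif(k, 0.5, 4)
      ox <- stats::runif(k, bb["xmin"], bb["xmax"])
      oy <- stats::runif(k, bb["ymin"], bb["ymax"])
      ox[side == 1] <- bb["xmin"] - margin[side == 1]
      ox[side == 2] <- bb["xmax"] + margin[side == 2]
      oy[side == 3] <- bb["ymin"] - margin[side == 3]
      oy[side == 4] <- bb["ymax"] + margin[side == 4]
      lon[outside] <- ox; lat[outside] <- oy
      placement_defect[outside] <- "outside_biome"
    }
    is_dubious <- accepted %in% dubious

    stage <- rep(0L, n)
    stage[placement_defect == "outside_biome" | is_dubious] <- 3L
    stage[coord_defect != "none"] <- 2L
    stage[open_nom] <- 1L

    record_id <- sprintf("syn_%06d", seq_len(n))
    records <- tibble::tibble(
      record_id = record_id, source_id = source_id, raw_name = raw_name,
      accepted_name = NA_character_, latitude = lat, longitude = lon,
      coordinate_uncertainty_m = unc, locality_precision = precision,
      year = year, flags = flags
    )
    labels <- tibble::tibble(
      record_id = record_id, species = accepted,
      true_region_id = leaf$region_id[region_idx],
      name_defect = name_defect, coord_defect = coord_defect,
      placement_defect = placement_defect, dubious_species = is_dubious,
      first_excluding_stage = stage
    )
    survivors <- labels[labels$first_excluding_stage == 0L, ]
    composition <- survivors |>
      dplyr::distinct(region_id = .data$true_region_id, .data$species) |>
      dplyr::arrange(.data$region_id, .data$species)
    ledger <- structure(list(
      labels = labels,
      species_pool = taxonomy$accepted_name,
      endemic_species = attr(taxonomy, "endemic_species"),
      dubious_species = dubious,
      region_composition = composition,
      expected_exclusions = tibble::tibble(
        stage = c("taxonomic", "geographic", "biogeographic"),
        n_excluded = c(sum(labels$first_excluding_stage == 1L),
                       sum(labels$first_excluding_stage == 2L),
                       sum(labels$first_excluding_stage == 3L))
      ),
      n_initial = n,
      n_retained = sum(stage == 0L)
    ), class = "truth_ledger")
    list(records = records, ledger = ledger)
  })
}

#' @export
print.truth_ledger <- function(x, ...) {
  cat(sprintf("<truth_ledger> %d records, %d expected survivors\n",
              x$n_initial, x$n_retained))
  print(x$expected_exclusions)
  invisible(x)
}
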