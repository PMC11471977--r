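# Filter 3 — biome containment and distribution-code vetting. A record
# survives if its point falls within the biome boundary (closed boundary:
# edge points count as inside) and its species has the biome among its
# documented distribution codes.

#' Vet species by documented distribution
#'
#' A species is dropped when the target biome code (default `"AM"`, the
#' Amazon) is absent from its documented distribution codes; dropping a
#' species removes all of its records. Species missing from the reference
#' are kept with a flag by default (configurable to drop).
#'
#' @param species Character vector of accepted names.
#' @param taxonomy A `taxon_table` with `biome_codes`.
#' @param target_code Biome code that must be present (default `"AM"`).
#' @param missing_action `"keep"` (default) or `"drop"` for species absent
#'   from the reference.
#' @return Tibble with `species`, `decision` (`"keep"`/`"drop"`),
#'   `in_reference`.
#' @export
vet_species_distribution <- function(species, taxonomy, target_code = "AM",
                                     missing_action = c("keep", "drop")) {
  missing_action <- match.arg(missing_action)
  idx <- match(species, taxonomy$accepted_name)
  in_ref <- !is.na(idx)
  has_code <- rep(NA, length(species))
  has_code[in_ref] <- vapply(taxonomy$biome_codes[idx[in_ref]],
                             function(codes) target_code %in% codes,
                             logical(1))
  decision <- ifelse(in_ref,
                     ifelse(has_code, "keep", "drop"),
                     ifelse(missing_action == "keep", "keep", "drop"))
  tibble::tibble(species = species, decision = decision, in_reference = in_ref)
}

#' Apply the biogeographic filter
#'
#' Stage 3 of the curation pipeline: excludes records falling outside the
#' biome boundary (reason `outside_biome`) and, afterwards, all records of
#' species whose documented distribution does not include the biome
#' (reason `dubious_distribution`). The two reasons are kept distinct in
#' the exclusion table.
#'
#' @param records Occurrence tibble (stage-2 output; coordinates present).
#' @param biome A geometry (see [rect_geometry()]) or a one-row `region_set`.
#' @param taxonomy A `taxon_table`.
#' @param target_code Biome code required in each species' distribution.
#' @param missing_action Passed to [vet_species_distribution()].
#' @return A `filter_result`; its `dropped_species` element lists the vetted-out
#'   species (the "disregarded species" table).
#' @export
apply_biogeographic_filter <- function(records, biome, taxonomy,
                                       target_code = "AM",
                                       missing_action = c("keep", "drop")) {
  missing_action <- match.arg(missing_action)
  geometry <- if (inherits(biome, "region_set")) biome$geometry[[1]] else biome
  inside <- point_in_polygon(records$longitude, records$latitude, geometry)
  inside[is.na(inside)] <- FALSE
  vet <- vet_species_distribution(unique(stats::na.omit(records$accepted_name)),
                                  taxonomy, target_code, missing_action)
  dropped_species <- vet$species[vet$decision == "drop"]
  dubious <- records$accepted_name %in% dropped_species
  reason <- rep(NA_character_, nrow(records))
  reason[dubious] <- "dubious_distribution"
  reason[!inside] <- "outside_biome"   # spatial exclusion takes precedence
  keep <- inside & !dubious
  retained <- records[keep, ]
  not_in_ref <- !(retained$accepted_name %in% taxonomy$accepted_name)
  retained$flags[not_in_ref] <- add_flag(retained$flags[not_in_ref],
                                         "TAXON_NOT_IN_REFERENCE")
  excluded <- records[!keep, ]
  excluded$reason <- reason[!keep]
  out <- new_filter_result(retained, excluded, stage_name = "biogeographic",
                           n_in = nrow(records))
  out$dropped_species <- tibble::tibble(species = sort(dropped_species))
  out
}
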