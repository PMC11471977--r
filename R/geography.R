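# Filter 2 — geographic coordinate validation: presence, range, the (0,0)
# artifact, administrative-level precision, and the > 20 km uncertainty rule.

#' Classify a record's coordinates
#'
#' Assigns each record exactly one coordinate outcome, checked in a fixed
#' order: `missing` (either coordinate absent), `out_of_range` (|lat| > 90 or
#' |lon| > 180), `zero_zero` (both coordinates exactly 0, a common data-entry
#' artifact), `admin_level` (locality precision of municipality, state or
#' country), `too_imprecise` (uncertainty radius strictly greater than
#' `max_radius_km`), else `ok`. A record with coordinates but no uncertainty
#' metadata is judged by its locality precision alone: point, locality and
#' unknown pass.
#'
#' @param records Occurrence tibble.
#' @param max_radius_km Maximum admissible uncertainty radius; the exclusion
#'   is strict (`> max_radius_km * 1000` metres), so exactly 20 km passes.
#' @return Character vector of outcomes, one per record.
#' @export
check_coordinates <- function(records, max_radius_km = 20) {
  n <- nrow(records)
  lat <- records$latitude
  lon <- records$longitude
  unc <- records$coordinate_uncertainty_m
  prec <- records$locality_precision
  out <- rep("ok", n)
  admin <- prec %in% c("municipality", "state", "country")
  imprecise <- !is.na(unc) & unc > max_radius_km * 1000
  out[imprecise] <- "too_imprecise"
  out[admin] <- "admin_level"
  zz <- !is.na(lat) & !is.na(lon) & lat == 0 & lon == 0
  out[zz] <- "zero_zero"
  oor <- !is.na(lat) & !is.na(lon) & (abs(lat) > 90 | abs(lon) > 180)
  out[oor] <- "out_of_range"
  out[is.na(lat) | is.na(lon)] <- "missing"
  out
}

#' Apply the geographic filter
#'
#' Stage 2 of the curation pipeline: retains records whose coordinate
#' outcome is `ok` (and `zero_zero` when `drop_zero_zero = FALSE`); all
#' other outcomes are excluded with the outcome as the reason.
#'
#' @param records Occurrence tibble (stage-1 output).
#' @param max_radius_km Uncertainty threshold in km (default 20, strict).
#' @param drop_zero_zero Exclude (0, 0) records (default `TRUE`).
#' @return A `filter_result` (see [apply_taxonomic_filter()]).
#' @export
apply_geographic_filter <- function(records, max_radius_km = 20,
                                    drop_zero_zero = TRUE) {
  outcome <- check_coordinates(records, max_radius_km)
  keep <- outcome == "ok" | (!drop_zero_zero & outcome == "zero_zero")
  retained <- records[keep, ]
  if (!drop_zero_zero) {
    zz <- outcome[keep] == "zero_zero"
    retained$flags[zz] <- add_flag(retained$flags[zz], "ZERO_ZERO")
  }
  excluded <- records[!keep, ]
  excluded$reason <- outcome[!keep]
  new_filter_result(retained, excluded, stage_name = "geographic",
                    n_in = nrow(records))
}

#' Format decimal degrees as DMS text
#'
#' Inverse of [dms_to_decimal()] for round-trip checks and exports.
#'
#' @param x Numeric decimal degrees.
#' @param axis `"lat"` or `"lon"` (controls the hemisphere letter).
#' @return Character vector like `3°51'36"S`.
#' @export
decimal_to_dms <- function(x, axis = c("lat", "lon")) {
  axis <- match.arg(axis)
  letters_pos <- if (axis == "lat") c("N", "S") else c("E", "W")
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    hemi <- if (v < 0) letters_pos[2] else letters_pos[1]
    v <- abs(v)
    d <- floor(v)
    m <- floor((v - d) * 60)
    s <- (v - d - m / 60) * 3600
    sprintf("%d°%d'%.6f\"%s", d, m, s, hemi)
  }, character(1))
}
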