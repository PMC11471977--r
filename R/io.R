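# Readers and writers for occurrence tables and the taxon reference table.
# Delimited text in, tibbles out; Darwin-Core-style default column names.

# default Darwin-Core-flavoured column map: internal name -> file column
default_column_map <- function() {
  c(
    record_id = "occurrenceID",
    source_id = "source",
    raw_name = "scientificName",
    latitude = "decimalLatitude",
    longitude = "decimalLongitude",
    coordinate_uncertainty_m = "coordinateUncertaintyInMeters",
    locality_precision = "localityPrecision",
    year = "year"
  )
}

locality_precision_levels <- function() {
  c("point", "locality", "municipality", "state", "country", "unknown")
}

validation_flags <- function() {
  c("COORD_PARSE_FAIL", "MISSING_COORD", "OPEN_NOMENCLATURE", "UNRESOLVED_NAME",
    "SYNONYM_RESOLVED", "ZERO_ZERO", "TAXON_NOT_IN_REFERENCE")
}

detect_delim <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  counts <- c(`,` = lengths(regmatches(line, gregexpr(",", line, fixed = TRUE))),
              `\t` = lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE))),
              `;` = lengths(regmatches(line, gregexpr(";", line, fixed = TRUE))))
  names(counts)[which.max(counts)]
}

#' Convert coordinate text to decimal degrees
#'
#' Parses degree-minute-second strings (`3°51'36"S`, `3 51 36 S`,
#' `58°15'W`) and plain decimal strings to signed decimal degrees. Sign comes
#' from a hemisphere letter (S/W negative) or a leading minus; decimal input
#' passes through unchanged.
#'
#' @param x Character vector of coordinate strings.
#' @param strict If `TRUE` (default) invalid input — minutes or seconds >= 60,
#'   or a hemisphere letter contradicting a leading minus — raises an error;
#'   if `FALSE` such entries (and unparseable text) return `NA`.
#' @return Numeric vector of decimal degrees; empty strings give `NA`.
#' @export
#' @examples
#' dms_to_decimal(c("3°51'36\"S", "-58.25", "0°0'0\""))
dms_to_decimal <- function(x, strict = TRUE) {
  fail <- function(msg, value) {
    if (strict) stop("coordinate parse error: ", msg, " in '", value, "'",
                     call. = FALSE)
    NA_real_
  }
  vapply(as.character(x), function(s) {
    s0 <- s
    s <- trimws(s)
    if (is.na(s) || s == "") return(NA_real_)
    # plain decimal (or integer) degrees pass through
    if (grepl("^[+-]?[0-9]+(\\.[0-9]+)?$", s)) return(as.numeric(s))
    hemi <- ""
    hm <- regmatches(s, regexpr("[NSEWnsew]\\s*$", s))
    if (length(hm) == 1 && nchar(hm) > 0) {
      hemi <- toupper(trimws(hm))
      s <- trimws(sub("[NSEWnsew]\\s*$", "", s))
    }
    neg_sign <- grepl("^-", s)
    s <- sub("^[+-]", "", s)
    if (neg_sign && hemi %in% c("N", "E")) {
      return(fail("hemisphere letter contradicts leading minus", s0))
    }
    parts <- regmatches(s, gregexpr("[0-9]+(\\.[0-9]+)?", s))[[1]]
    if (length(parts) < 1 || length(parts) > 3) {
      return(fail("unrecognized coordinate format", s0))
    }
    nums <- as.numeric(parts)
    d <- nums[1]
    m <- if (length(nums) >= 2) nums[2] else 0
    sec <- if (length(nums) >= 3) nums[3] else 0
    if (m >= 60 || sec >= 60) {
      return(fail("minutes/seconds must be < 60", s0))
    }
    val <- d + m / 60 + sec / 3600
    if (neg_sign || hemi %in% c("S", "W")) val <- -val
    val
  }, numeric(1), USE.NAMES = FALSE)
}

add_flag <- function(flags, new) {
  ifelse(flags == "", new, paste(flags, new, sep = ";"))
}

has_flag <- function(flags, flag) {
  vapply(strsplit(flags, ";", fixed = TRUE), function(f) flag %in% f, logical(1))
}

#' Read an occurrence table
#'
#' Reads a delimited text file of species occurrence records into a tibble,
#' mapping Darwin-Core-style column names to the internal schema. Coordinate
#' cells may be decimal or DMS text; unparseable cells become `NA`
#' coordinates with a `COORD_PARSE_FAIL` flag rather than an error. Rows are
#' never silently dropped.
#'
#' @param path Path to a CSV/TSV/semicolon-delimited file (UTF-8).
#' @param col_map Named character vector mapping internal names to file
#'   columns; defaults cover `scientificName`, `decimalLatitude`,
#'   `decimalLongitude`, `coordinateUncertaintyInMeters`, `year`.
#' @param delim Field delimiter; `NULL` (default) auto-detects among
#'   comma, tab and semicolon from the header row.
#' @return A tibble with columns `record_id`, `source_id`, `raw_name`,
#'   `accepted_name`, `latitude`, `longitude`, `coordinate_uncertainty_m`,
#'   `locality_precision`, `year`, `flags` (semicolon-separated, `""` = none).
#' @export
read_occurrences <- function(path, col_map = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- default_column_map()
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  if (is.null(delim)) delim <- detect_delim(path)
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(encoding = "UTF-8"), progress = FALSE,
    show_col_types = FALSE
  )
  for (required in c("raw_name", "source_id")) {
    if (!map[[required]] %in% names(raw)) {
      stop("schema error: missing mandatory column '", map[[required]], "'",
           call. = FALSE)
    }
  }
  n <- nrow(raw)
  pick <- function(key, default = NA_character_) {
    col <- map[[key]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(default, n)
  }
  flags <- rep("", n)
  lat_raw <- pick("latitude"); lon_raw <- pick("longitude")
  lat <- dms_to_decimal(lat_raw, strict = FALSE)
  lon <- dms_to_decimal(lon_raw, strict = FALSE)
  parse_fail <- (!is.na(lat_raw) & lat_raw != "" & is.na(lat)) |
                (!is.na(lon_raw) & lon_raw != "" & is.na(lon))
  flags[parse_fail] <- add_flag(flags[parse_fail], "COORD_PARSE_FAIL")
  missing_coord <- is.na(lat) | is.na(lon)
  lat[missing_coord] <- NA_real_
  lon[missing_coord] <- NA_real_
  flags[missing_coord & !parse_fail] <-
    add_flag(flags[missing_coord & !parse_fail], "MISSING_COORD")
  out_of_range <- !is.na(lat) & !is.na(lon) &
    (abs(lat) > 90 | abs(lon) > 180)
  lat[out_of_range] <- NA_real_
  lon[out_of_range] <- NA_real_
  flags[out_of_range] <- add_flag(flags[out_of_range], "COORD_PARSE_FAIL")
  precision <- tolower(trimws(pick("locality_precision", "unknown")))
  precision[is.na(precision) | !(precision %in% locality_precision_levels())] <- "unknown"
  rid <- pick("record_id")
  if (all(is.na(rid))) rid <- sprintf("rec_%06d", seq_len(n))
  if (anyDuplicated(rid[!is.na(rid)])) {
    stop("schema error: duplicate record_id values", call. = FALSE)
  }
  tibble::tibble(
    record_id = as.character(rid),
    source_id = as.character(raw[[map[["source_id"]]]]),
    raw_name = as.character(raw[[map[["raw_name"]]]]),
    accepted_name = NA_character_,
    latitude = lat,
    longitude = lon,
    coordinate_uncertainty_m = suppressWarnings(
      as.numeric(pick("coordinate_uncertainty_m"))),
    locality_precision = precision,
    year = suppressWarnings(as.integer(pick("year"))),
    flags = flags
  )
}

#' Write an occurrence table
#'
#' Writes the internal occurrence schema back to CSV with Darwin-Core-style
#' headers and a deterministic column order, so that
#' `read_occurrences(write_occurrences(x))` round-trips every field.
#'
#' @param records Occurrence tibble (see [read_occurrences()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(records, path) {
  map <- default_column_map()
  out <- tibble::tibble(
    !!map[["record_id"]] := records$record_id,
    !!map[["source_id"]] := records$source_id,
    !!map[["raw_name"]] := records$raw_name,
    acceptedName = records$accepted_name,
    !!map[["latitude"]] := records$latitude,
    !!map[["longitude"]] := records$longitude,
    !!map[["coordinate_uncertainty_m"]] := records$coordinate_uncertainty_m,
    !!map[["locality_precision"]] := records$locality_precision,
    !!map[["year"]] := records$year,
    flags = records$flags
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a taxon reference table
#'
#' Reads the accepted-name reference: one row per accepted binomial with
#' synonyms, order/family/genus, biome distribution codes and IUCN category.
#' Duplicate accepted rows are merged by set-union of synonyms and codes.
#' An IUCN value of `NA` (the "not assessed" convention) or an empty cell is
#' stored as `NE` (not evaluated).
#'
#' @param path CSV with columns `accepted_name`, `order`, `family`, `genus`,
#'   `synonyms` (pipe-separated), `biome_codes` (pipe-separated, e.g.
#'   `AM|AF`), `iucn` (one of CR, EN, VU, NT, LC, DD, NE).
#' @return A tibble of class `taxon_table` with list-columns `synonyms` and
#'   `biome_codes`, plus a `synonym_map` attribute (named character vector,
#'   synonym -> accepted name).
#' @export
read_taxon_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("accepted_name", "synonyms", "biome_codes", "iucn")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("schema error: missing taxon column(s) ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  split_set <- function(x) {
    if (is.na(x) || trimws(x) == "") return(character(0))
    unique(trimws(strsplit(x, "|", fixed = TRUE)[[1]]))
  }
  df <- tibble::tibble(
    accepted_name = trimws(raw$accepted_name),
    order = if ("order" %in% names(raw)) raw$order else NA_character_,
    family = if ("family" %in% names(raw)) raw$family else NA_character_,
    genus = if ("genus" %in% names(raw)) raw$genus else
      vapply(strsplit(trimws(raw$accepted_name), " "), `[[`, character(1), 1),
    synonyms = lapply(raw$synonyms, split_set),
    biome_codes = lapply(raw$biome_codes, split_set),
    iucn_category = toupper(trimws(ifelse(is.na(raw$iucn) | raw$iucn %in% c("", "NA"),
                                          "NE", raw$iucn)))
  )
  merged <- df |>
    dplyr::group_by(.data$accepted_name) |>
    dplyr::summarise(
      order = dplyr::first(stats::na.omit(.data$order))[1],
      family = dplyr::first(stats::na.omit(.data$family))[1],
      genus = dplyr::first(stats::na.omit(.data$genus))[1],
      synonyms = list(unique(unlist(.data$synonyms))),
      biome_codes = list(unique(unlist(.data$biome_codes))),
      iucn_category = dplyr::first(.data$iucn_category),
      .groups = "drop"
    )
  as_taxon_table(merged)
}

#' Assemble a taxon table from a data frame
#'
#' Validates the taxon reference invariants (no accepted name listed among
#' its own synonyms; every synonym resolving to exactly one accepted name)
#' and attaches the synonym lookup map.
#'
#' @param df Tibble with `accepted_name`, `order`, `family`, `genus`,
#'   list-columns `synonyms`, `biome_codes`, and `iucn_category`.
#' @return A `taxon_table` tibble.
#' @export
as_taxon_table <- function(df) {
  df$synonyms <- purrr::map2(df$synonyms, df$accepted_name,
                             function(s, a) setdiff(s, a))
  syn <- tibble::tibble(
    synonym = unlist(df$synonyms),
    accepted = rep(df$accepted_name, lengths(df$synonyms))
  )
  dup <- syn |>
    dplyr::distinct() |>
    dplyr::count(.data$synonym) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    offenders <- syn |> dplyr::filter(.data$synonym %in% dup$synonym) |>
      dplyr::arrange(.data$synonym)
    stop("synonym conflict: ",
         paste(unique(offenders$synonym), collapse = ", "),
         " mapped to multiple accepted names (",
         paste(unique(offenders$accepted), collapse = ", "), ")",
         call. = FALSE)
  }
  map <- stats::setNames(syn$accepted, syn$synonym)
  attr(df, "synonym_map") <- map
  class(df) <- unique(c("taxon_table", class(df)))
  df
}

#' Write a taxon table to CSV
#'
#' @param taxonomy A `taxon_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_taxon_table <- function(taxonomy, path) {
  out <- tibble::tibble(
    accepted_name = taxonomy$accepted_name,
    order = taxonomy$order,
    family = taxonomy$family,
    genus = taxonomy$genus,
    synonyms = vapply(taxonomy$synonyms, paste, character(1), collapse = "|"),
    biome_codes = vapply(taxonomy$biome_codes, paste, character(1), collapse = "|"),
    iucn = taxonomy$iucn_category
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Collapse exact duplicate records
#'
#' Optional exact-duplicate collapse: records agreeing on accepted (or raw)
#' name, coordinates, year and source are reduced to the first occurrence.
#' Cross-source duplicates are deliberately left alone.
#'
#' @param records Occurrence tibble.
#' @return Tibble with duplicates removed; attribute `n_dropped` gives the count.
#' @export
collapse_exact_duplicates <- function(records) {
  key_name <- ifelse(is.na(records$accepted_name), records$raw_name,
                     records$accepted_name)
  key <- paste(key_name, records$latitude, records$longitude,
               records$year, records$source_id, sep = "\r")
  keep <- !duplicated(key)
  out <- records[keep, ]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
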