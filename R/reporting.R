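# Summary products: filter accounting with the conservation identity,
# IUCN tallies per family, temporal increments by decade, per-source
# complementarity, and the rounding convention used for printed shares.

#' Percentage with half-away-from-zero rounding
#'
#' `100 * numerator / denominator`, rounded half away from zero to
#' `decimals` places — the convention under which 39.459 prints as 39.5.
#' (Base R's `round()` rounds half to even, which would disagree on exact
#' halves.)
#'
#' @param numerator,denominator Numeric; `denominator` must be > 0.
#' @param decimals Number of decimal places (default 1).
#' @return Numeric percentage.
#' @export
#' @examples
#' percent(775, 947, 1)   # 81.8
#' percent(947, 1262, 0)  # 75
percent <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) stop("denominator must be > 0", call. = FALSE)
  x <- 100 * numerator / denominator
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Assemble a filter report
#'
#' @param n_initial Record count entering the pipeline.
#' @param stages Tibble binding the per-stage accounting rows emitted by the
#'   three filters (`stage`, `n_in`, `n_excluded`, `n_retained`,
#'   `species_retained`).
#' @return Object of class `filter_report`.
#' @export
filter_report <- function(n_initial, stages) {
  structure(list(n_initial = n_initial, stages = stages,
                 n_retained = stages$n_retained[nrow(stages)]),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  print(filter_accounting(x))
  invisible(x)
}

#' Filter accounting with the conservation identity
#'
#' Expands a [filter_report()] into a per-stage table (excluded counts and
#' shares of the initial total) and verifies the conservation identity
#' `n_initial = n_retained + sum(stage exclusions)`. A violated identity is
#' a hard failure: it means records were lost or double-counted.
#'
#' @param report A `filter_report`.
#' @param decimals Decimal places for the printed shares.
#' @return Tibble with one row per stage plus a `retained` row; columns
#'   `stage`, `n`, `pct_of_initial`.
#' @export
filter_accounting <- function(report, decimals = 1) {
  st <- report$stages
  total_excluded <- sum(st$n_excluded)
  if (report$n_initial != report$n_retained + total_excluded) {
    stop(sprintf(
      "accounting identity violated: initial %d != retained %d + excluded %d",
      report$n_initial, report$n_retained, total_excluded), call. = FALSE)
  }
  chain_ok <- all(st$n_in == c(report$n_initial, utils::head(st$n_retained, -1)))
  if (!chain_ok) {
    stop("accounting identity violated: stage inputs do not chain", call. = FALSE)
  }
  tibble::tibble(
    stage = c(paste0("excluded_", st$stage), "retained"),
    n = c(st$n_excluded, report$n_retained),
    pct_of_initial = percent(c(st$n_excluded, report$n_retained),
                             report$n_initial, decimals)
  )
}

#' IUCN category and per-family threat summary
#'
#' Tallies IUCN categories over a species list and computes per-family
#' threatened shares, where threatened means CR, EN or VU. A family is
#' flagged when strictly more than `flag_threshold_pct` of its species are
#' threatened. DD and NE are reported as their own rows, never pooled into
#' threatened.
#'
#' @param taxonomy A `taxon_table`.
#' @param species Character vector of accepted names (defaults to all).
#' @param flag_threshold_pct Flagging threshold (default 30, strict `>`).
#' @return List with `categories` (tibble `category`, `n`, `pct`),
#'   `families` (tibble `family`, `n_species`, `n_threatened`,
#'   `pct_threatened`, `flagged`), and `n_threatened` overall.
#' @export
iucn_summary <- function(taxonomy, species = taxonomy$accepted_name,
                         flag_threshold_pct = 30) {
  threatened_cats <- c("CR", "EN", "VU")
  df <- taxonomy[taxonomy$accepted_name %in% species, ]
  cat_levels <- c("CR", "EN", "VU", "NT", "LC", "DD", "NE")
  categories <- tibble::tibble(category = factor(df$iucn_category, cat_levels)) |>
    dplyr::count(.data$category, .drop = FALSE, name = "n") |>
    dplyr::mutate(category = as.character(.data$category),
                  pct = percent(.data$n, max(nrow(df), 1), 1))
  families <- df |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      n_species = dplyr::n(),
      n_threatened = sum(.data$iucn_category %in% threatened_cats),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_threatened = percent(.data$n_threatened, .data$n_species, 1),
      flagged = .data$pct_threatened > flag_threshold_pct
    ) |>
    dplyr::arrange(dplyr::desc(.data$pct_threatened))
  list(categories = categories, families = families,
       n_threatened = sum(df$iucn_category %in% threatened_cats))
}

#' Temporal summary by decade
#'
#' Bins dated records into decades (`floor(year / 10) * 10`) and reports
#' per-decade record counts, per-decade species counts, and the cumulative
#' species count over time (non-decreasing). Records without a year are
#' counted separately in the `n_yearless` attribute.
#'
#' @param records Occurrence tibble with `accepted_name` and `year`.
#' @return Tibble `decade`, `n_records`, `n_species`, `cum_species`.
#' @export
temporal_summary <- function(records) {
  dated <- records[!is.na(records$year), ]
  dated$decade <- (dated$year %/% 10L) * 10L
  decades <- sort(unique(dated$decade))
  seen <- character(0)
  rows <- lapply(decades, function(d) {
    sub <- dated[dated$decade == d, ]
    sp <- unique(stats::na.omit(sub$accepted_name))
    seen <<- union(seen, sp)
    tibble::tibble(decade = d, n_records = nrow(sub),
                   n_species = length(sp), cum_species = length(seen))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_yearless") <- sum(is.na(records$year))
  out
}

#' Per-source contribution and complementarity
#'
#' Tallies each data source's records, species, and sampled sites (a site is
#' a unique coordinate pair rounded to `site_decimals` decimal places,
#' about 11 m at 4), then orders sources by greedy marginal species gain:
#' the first source is the one with most species, each next source is the
#' one adding most species not yet covered.
#'
#' @param records Occurrence tibble.
#' @param site_decimals Coordinate rounding for site identity (default 4).
#' @return List with `sources` (tibble `source_id`, `n_records`,
#'   `n_species`, `n_sites`) and `complementarity` (tibble `rank`,
#'   `source_id`, `marginal_species_gain`, `cum_species`).
#' @export
source_complementarity <- function(records, site_decimals = 4) {
  per_source <- records |>
    dplyr::group_by(.data$source_id) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      n_species = dplyr::n_distinct(stats::na.omit(.data$accepted_name)),
      n_sites = dplyr::n_distinct(paste(round(.data$latitude, site_decimals),
                                        round(.data$longitude, site_decimals))[
        !is.na(.data$latitude) & !is.na(.data$longitude)]),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_records))
  species_by_source <- split(records$accepted_name, records$source_id) |>
    lapply(function(x) unique(stats::na.omit(x)))
  remaining <- names(species_by_source)
  covered <- character(0)
  rows <- list()
  rank <- 1L
  while (length(remaining) > 0) {
    gains <- vapply(remaining, function(s) {
      length(setdiff(species_by_source[[s]], covered))
    }, integer(1))
    best <- remaining[order(-gains, remaining)][1]  # ties: alphabetical
    covered <- union(covered, species_by_source[[best]])
    rows[[rank]] <- tibble::tibble(rank = rank, source_id = best,
                                   marginal_species_gain = max(gains),
                                   cum_species = length(covered))
    remaining <- setdiff(remaining, best)
    rank <- rank + 1L
  }
  list(sources = per_source, complementarity = dplyr::bind_rows(rows))
}
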