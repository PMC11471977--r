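# Filter 1 — taxonomic refinement: open-nomenclature detection and synonym
# resolution against the accepted-name reference.

# markers signalling uncertain identification; "sp. nov."/"n. sp." are new
# species in description, still not a resolvable binomial here
open_nomenclature_markers <- function(extra = character(0)) {
  unique(c("cf", "gr", "aff", "sp", tolower(extra)))
}

#' Parse a verbatim scientific-name string
#'
#' Splits a raw name into genus, specific epithet, infraspecific tokens and
#' any open-nomenclature marker (`cf`, `gr`, `aff`, `sp`, extensible).
#' Markers are detected case-insensitively, with or without a trailing
#' period, at any position after the genus. A parenthesized subgenus after
#' the genus is stripped, as is an author/year remnant (parenthesized or a
#' trailing capitalized token with a year). Subspecies trinomials keep the
#' infraspecific token separately so downstream code can collapse to the
#' binomial.
#'
#' @param raw Character vector of verbatim names.
#' @param extra_markers Additional lower-case marker tokens to treat as open
#'   nomenclature (e.g. `"?"`-like source-specific conventions).
#' @return A tibble with one row per input: `raw`, `genus`, `epithet`,
#'   `infraspecific`, `marker` (`"none"` when absent), `author`. A
#'   single-token input (genus only) yields marker `sp`.
#' @export
#' @examples
#' parse_scientific_name(c("Rhinella cf. marina",
#'                         "Rhinella marina (Linnaeus, 1758)",
#'                         "Boana aff. geographica"))
parse_scientific_name <- function(raw, extra_markers = character(0)) {
  markers <- open_nomenclature_markers(extra_markers)
  one <- function(s) {
    out <- list(raw = s, genus = NA_character_, epithet = NA_character_,
                infraspecific = NA_character_, marker = "none",
                author = NA_character_)
    s <- trimws(s)
    if (is.na(s) || s == "") {
      out$marker <- "sp"
      return(out)
    }
    author <- character(0)
    # parenthesized groups: subgenus if single capitalized word right after
    # the genus, otherwise author/year remnant
    paren <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
    for (p in paren) {
      inner <- sub("^\\(", "", sub("\\)$", "", p))
      is_subgenus <- grepl("^[A-Z][a-z]+$", inner) &&
        regexpr(p, s, fixed = TRUE) < 30 &&  # right after genus in practice
        !grepl("[0-9]", inner)
      if (!is_subgenus) author <- c(author, inner)
      s <- sub(p, " ", s, fixed = TRUE)
    }
    s <- gsub("\\s+", " ", trimws(s))
    tokens <- strsplit(s, " ", fixed = TRUE)[[1]]
    if (length(tokens) == 0) {
      out$marker <- "sp"
      return(out)
    }
    out$genus <- paste0(toupper(substr(tokens[1], 1, 1)),
                        tolower(substr(tokens[1], 2, nchar(tokens[1]))))
    rest <- tokens[-1]
    # author-year tail: from the first capitalized token or token with
    # digits — but an upper-cased marker ("CF") is still a marker
    norm_all <- tolower(sub("\\.$", "", rest))
    tail_idx <- which((grepl("^[A-Z]", rest) & !(norm_all %in% markers)) |
                        grepl("[0-9]", rest))
    if (length(tail_idx) > 0) {
      author <- c(author, paste(rest[min(tail_idx):length(rest)], collapse = " "))
      rest <- rest[seq_len(min(tail_idx) - 1)]
    }
    norm <- tolower(sub("\\.$", "", rest))
    # "sp. nov." / "n. sp." collapse to the sp marker
    is_marker <- norm %in% markers | norm %in% c("nov", "n")
    found <- norm[norm %in% markers]
    if (length(found) > 0) out$marker <- found[1]
    epithets <- rest[!is_marker]
    if (length(epithets) >= 1) out$epithet <- tolower(epithets[1])
    if (length(epithets) >= 2) {
      out$infraspecific <- paste(tolower(epithets[-1]), collapse = " ")
    }
    if (is.na(out$epithet) && out$marker == "none") out$marker <- "sp"
    if (length(author) > 0) out$author <- paste(author, collapse = "; ")
    out
  }
  purrr::map_dfr(as.character(raw), function(s) tibble::as_tibble(one(s)))
}

#' Resolve a binomial against the taxon reference
#'
#' Exact-match lookup, first on accepted names, then on the synonym map.
#' Unresolved names are returned as `NA` with `status = "unresolved"`; they
#' are never an error here (exclusion is the filter's decision).
#'
#' @param binomial Character vector of cleaned binomials.
#' @param taxonomy A `taxon_table`.
#' @return Tibble with `input`, `accepted_name`, `status` in
#'   `{"accepted", "synonym", "unresolved"}`.
#' @export
resolve_synonym <- function(binomial, taxonomy) {
  map <- attr(taxonomy, "synonym_map")
  accepted <- taxonomy$accepted_name
  status <- rep("unresolved", length(binomial))
  out <- rep(NA_character_, length(binomial))
  hit_acc <- binomial %in% accepted
  out[hit_acc] <- binomial[hit_acc]
  status[hit_acc] <- "accepted"
  hit_syn <- !hit_acc & binomial %in% names(map)
  out[hit_syn] <- unname(map[binomial[hit_syn]])
  status[hit_syn] <- "synonym"
  tibble::tibble(input = binomial, accepted_name = out, status = status)
}

#' Apply the taxonomic filter
#'
#' Stage 1 of the curation pipeline. Excludes records whose name carries an
#' open-nomenclature marker; resolves the rest to accepted names through the
#' synonym map. Under the default `"strict"` policy, clean binomials absent
#' from the reference are also excluded; `"lenient"` keeps them flagged
#' (standing in for voucher re-confirmation, which cannot be performed
#' offline). Trinomials are collapsed to the binomial.
#'
#' @param records Occurrence tibble.
#' @param taxonomy A `taxon_table`.
#' @param policy `"strict"` (default) or `"lenient"`.
#' @param extra_markers Additional open-nomenclature tokens.
#' @return List of class `filter_result` with elements `retained`
#'   (records with `accepted_name` filled), `excluded` (records plus a
#'   `reason` column), and `stage` (one-row accounting tibble).
#' @export
apply_taxonomic_filter <- function(records, taxonomy,
                                   policy = c("strict", "lenient"),
                                   extra_markers = character(0)) {
  policy <- match.arg(policy)
  n_in <- nrow(records)
  parsed <- parse_scientific_name(records$raw_name, extra_markers)
  binomial <- ifelse(is.na(parsed$epithet), NA_character_,
                     paste(parsed$genus, parsed$epithet))
  open_nom <- parsed$marker != "none"
  res <- resolve_synonym(ifelse(open_nom, NA_character_, binomial), taxonomy)
  unresolved <- !open_nom & res$status == "unresolved"
  excluded_mask <- open_nom | (unresolved & policy == "strict")
  reason <- rep(NA_character_, n_in)
  reason[open_nom] <- paste0("open_nomenclature:", parsed$marker[open_nom])
  reason[unresolved & policy == "strict"] <- "unresolved_name"

  retained <- records[!excluded_mask, ]
  retained$accepted_name <- res$accepted_name[!excluded_mask]
  ret_flags <- retained$flags
  syn <- res$status[!excluded_mask] == "synonym"
  ret_flags[syn] <- add_flag(ret_flags[syn], "SYNONYM_RESOLVED")
  if (policy == "lenient") {
    unres_kept <- res$status[!excluded_mask] == "unresolved"
    ret_flags[unres_kept] <- add_flag(ret_flags[unres_kept], "UNRESOLVED_NAME")
    retained$accepted_name[unres_kept] <- binomial[!excluded_mask][unres_kept]
  }
  retained$flags <- ret_flags

  excluded <- records[excluded_mask, ]
  excluded$reason <- reason[excluded_mask]
  new_filter_result(retained, excluded, stage_name = "taxonomic", n_in = n_in)
}

new_filter_result <- function(retained, excluded, stage_name, n_in) {
  stopifnot(nrow(retained) + nrow(excluded) == n_in)
  stage <- tibble::tibble(
    stage = stage_name,
    n_in = n_in,
    n_excluded = nrow(excluded),
    n_retained = nrow(retained),
    species_retained = dplyr::n_distinct(
      stats::na.omit(retained$accepted_name))
  )
  structure(list(retained = retained, excluded = excluded, stage = stage),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result: %s> %d in, %d excluded, %d retained (%d species)\n",
              x$stage$stage, x$stage$n_in, x$stage$n_excluded,
              x$stage$n_retained, x$stage$species_retained))
  invisible(x)
}
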