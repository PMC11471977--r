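# Region sets: tibbles of polygons (biome boundary, nested drainage basins,
# grid cells) with id, hierarchy level, parent link and spherical area.

#' Construct a region set
#'
#' A region set is a tibble with one row per polygon and columns
#' `region_id`, `name`, `level`, `parent_id`, `area_km2` and a `geometry`
#' list-column (each element a list of (lon, lat) vertex matrices; first ring
#' outer, later rings holes). All spatial units in the pipeline — the biome
#' boundary, nested sub-basins and grid cells — share this container.
#'
#' @param region_id Character ids, unique within the set.
#' @param geometry List of geometries (see [rect_geometry()]).
#' @param name Display names; defaults to the ids.
#' @param level Integer hierarchy level (0 = biome, increasing downwards).
#' @param parent_id Parent region id or `NA` for roots.
#' @param validate Check rings (closure, self-intersection) and recompute
#'   areas; set `FALSE` only for pre-validated internal construction.
#' @return A tibble of class `region_set`.
#' @export
region_set <- function(region_id, geometry, name = region_id,
                       level = 0L, parent_id = NA_character_,
                       validate = TRUE) {
  stopifnot(length(region_id) == length(geometry))
  if (anyDuplicated(region_id)) {
    stop("duplicate region_id in region set", call. = FALSE)
  }
  geometry <- lapply(geometry, function(g) lapply(g, normalize_ring))
  if (validate) {
    for (i in seq_along(geometry)) {
      for (r in geometry[[i]]) {
        if (nrow(r) < 3) {
          stop("geometry error in region '", region_id[i],
               "': ring has fewer than 3 vertices", call. = FALSE)
        }
        if (ring_self_intersects(r)) {
          stop("geometry error in region '", region_id[i],
               "': self-intersecting ring", call. = FALSE)
        }
      }
    }
  }
  area <- vapply(geometry, polygon_area_km2, numeric(1))
  out <- tibble::tibble(
    region_id = as.character(region_id),
    name = as.character(name),
    level = as.integer(level),
    parent_id = as.character(parent_id),
    area_km2 = area,
    geometry = geometry
  )
  class(out) <- c("region_set", class(out))
  out
}

# dplyr verbs strip custom classes; restore after manipulation
as_region_set <- function(df) {
  class(df) <- unique(c("region_set", class(df)))
  df
}

#' Read regions from GeoJSON
#'
#' Reads an RFC 7946 FeatureCollection (lon-lat order, WGS84) of Polygon or
#' MultiPolygon features into a [region_set()]. Feature properties `region_id`
#' (or `id`), `name`, `level` and `parent_id` are honoured; a missing `level`
#' defaults to 0 with a warning. Areas are recomputed on the sphere.
#'
#' @param path Path to a GeoJSON file.
#' @param on_invalid What to do with a self-intersecting ring: `"error"`
#'   (default) or `"skip"` the feature with a warning.
#' @return A `region_set` tibble.
#' @export
read_regions <- function(path, on_invalid = c("error", "skip")) {
  on_invalid <- match.arg(on_invalid)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  rows <- list()
  for (i in seq_along(gj$features)) {
    ft <- gj$features[[i]]
    props <- ft$properties
    rid <- props$region_id %||% props$id %||% ft$id %||% paste0("feature_", i)
    lvl <- props$level
    if (is.null(lvl)) {
      warning("feature '", rid, "' has no 'level' property; defaulting to 0",
              call. = FALSE)
      lvl <- 0L
    }
    geomtype <- ft$geometry$type
    coords <- ft$geometry$coordinates
    polys <- switch(geomtype,
      Polygon = list(coords),
      MultiPolygon = coords,
      stop("unsupported geometry type '", geomtype, "' in feature '", rid, "'",
           call. = FALSE)
    )
    # flatten MultiPolygon parts into one ring list (outer rings first part
    # only carries holes; parts beyond the first are additional outers and are
    # rare in this pipeline — treated as separate rows suffixed _p<k>)
    for (p in seq_along(polys)) {
      rings <- lapply(polys[[p]], function(ring) {
        m <- do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
        normalize_ring(m)
      })
      bad <- any(vapply(rings, ring_self_intersects, logical(1)))
      if (bad) {
        if (on_invalid == "error") {
          stop("geometry error in feature '", rid,
               "': self-intersecting ring", call. = FALSE)
        }
        warning("skipping feature '", rid, "': self-intersecting ring",
                call. = FALSE)
        next
      }
      rows[[length(rows) + 1]] <- list(
        region_id = if (length(polys) > 1) paste0(rid, "_p", p) else as.character(rid),
        name = as.character(props$name %||% rid),
        level = as.integer(lvl),
        parent_id = as.character(props$parent_id %||% NA_character_),
        geometry = rings
      )
    }
  }
  if (length(rows) == 0) stop("no readable features in ", path, call. = FALSE)
  region_set(
    region_id = vapply(rows, `[[`, character(1), "region_id"),
    geometry = lapply(rows, `[[`, "geometry"),
    name = vapply(rows, `[[`, character(1), "name"),
    level = vapply(rows, `[[`, integer(1), "level"),
    parent_id = vapply(rows, `[[`, character(1), "parent_id"),
    validate = FALSE
  )
}

#' Write regions to GeoJSON
#'
#' Inverse of [read_regions()]: emits a FeatureCollection with `region_id`,
#' `name`, `level`, `parent_id` and `area_km2` properties, rings closed,
#' lon-lat order.
#'
#' @param regions A `region_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  features <- purrr::pmap(
    list(regions$region_id, regions$name, regions$level,
         regions$parent_id, regions$area_km2, regions$geometry),
    function(rid, nm, lvl, pid, area, geom) {
      coords <- lapply(geom, function(ring) {
        ring <- close_ring(normalize_ring(ring))
        lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
      })
      list(
        type = "Feature",
        properties = list(region_id = rid, name = nm, level = lvl,
                          parent_id = pid, area_km2 = area),
        geometry = list(type = "Polygon", coordinates = coords)
      )
    }
  )
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}
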