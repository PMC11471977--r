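# Analysis units: sub-basin selection from the nested drainage hierarchy
# (area rule), clipping to the biome, the equal-area 50 x 50 km grid, and
# record-to-unit assignment.

#' Select analysis sub-basins from a nested hierarchy
#'
#' Two modes mirror how drainage units are chosen from a nested basin
#' hierarchy. `mode = "auto"` walks each branch from the root and descends
#' only while *every* child's biome-clipped area exceeds `min_area_km2`,
#' returning the deepest qualifying level per branch — basins never overlap
#' and jointly cover the hierarchy's root. `mode = "zonal"` takes an explicit
#' per-zone level: `zones` is a `region_set` whose rows carry a `level`
#' column, and a basin of that level is selected when its centroid falls in
#' the zone (western branches can thus use deeper levels than eastern ones).
#'
#' @param hierarchy A `region_set` of nested basins with `parent_id` links
#'   (level 1 = coarsest).
#' @param mode `"auto"` or `"zonal"`.
#' @param min_area_km2 Area threshold for `"auto"` (default 30000; strict
#'   `>`).
#' @param zones For `"zonal"`: a `region_set` with an extra `level` column
#'   naming the hierarchy level to use inside each zone.
#' @param biome Optional biome geometry; when given, areas are evaluated on
#'   the clipped geometry.
#' @return A `region_set` of the selected basins (clipped when `biome` is
#'   given).
#' @export
select_subbasins <- function(hierarchy, mode = c("auto", "zonal"),
                             min_area_km2 = 30000, zones = NULL,
                             biome = NULL) {
  mode <- match.arg(mode)
  h <- hierarchy
  clipped_area <- function(i) {
    if (is.null(biome)) return(h$area_km2[i])
    g <- clip_geometry_convex(h$geometry[[i]], biome[[1]])
    if (length(g) == 0) 0 else polygon_area_km2(g)
  }
  if (mode == "auto") {
    children_of <- split(seq_len(nrow(h)), h$parent_id)
    roots <- which(is.na(h$parent_id) | !(h$parent_id %in% h$region_id))
    selected <- integer(0)
    descend <- function(i) {
      kids <- children_of[[h$region_id[i]]]
      if (is.null(kids) || length(kids) == 0) return(i)
      if (all(vapply(kids, clipped_area, numeric(1)) > min_area_km2)) {
        unlist(lapply(kids, descend))
      } else {
        i
      }
    }
    selected <- unlist(lapply(roots, descend))
    out <- h[sort(selected), ]
  } else {
    if (is.null(zones) || !("level" %in% names(zones))) {
      stop("zonal mode needs a 'zones' region_set with a 'level' column",
           call. = FALSE)
    }
    picked <- integer(0)
    for (z in seq_len(nrow(zones))) {
      lvl <- zones$level[z]
      cands <- which(h$level == lvl)
      cent <- t(vapply(cands, function(i) ring_centroid(h$geometry[[i]][[1]]),
                       numeric(2)))
      inz <- point_in_polygon(cent[, 1], cent[, 2], zones$geometry[[z]])
      if (!any(inz)) {
        stop("no level-", lvl, " basin found in zone '", zones$region_id[z],
             "'", call. = FALSE)
      }
      picked <- c(picked, cands[inz])
    }
    out <- h[sort(unique(picked)), ]
  }
  if (!is.null(biome)) {
    out <- clip_and_area(out, biome)
  }
  as_region_set(out)
}

#' Clip regions to the biome and recompute areas
#'
#' Intersects each region with the biome boundary (which must be convex —
#' rectangles in the synthetic landscapes) and recomputes spherical areas.
#' Regions left empty by the clip are dropped and reported via the
#' `dropped` attribute.
#'
#' @param regions A `region_set`.
#' @param biome Biome geometry (list of rings) or one-row `region_set`.
#' @return The clipped `region_set` with updated `area_km2`.
#' @export
clip_and_area <- function(regions, biome) {
  geometry <- if (inherits(biome, "region_set")) biome$geometry[[1]] else biome
  clip_ring <- geometry[[1]]
  new_geom <- lapply(regions$geometry, clip_geometry_convex, clip_ring = clip_ring)
  empty <- vapply(new_geom, length, integer(1)) == 0
  out <- regions[!empty, ]
  out$geometry <- new_geom[!empty]
  out$area_km2 <- vapply(out$geometry, polygon_area_km2, numeric(1))
  attr(out, "dropped") <- regions$region_id[empty]
  as_region_set(out)
}

#' Build an equal-area grid over the biome
#'
#' Lays a square grid of `cell_size_km` (default 50) over the biome in a
#' cylindrical equal-area projection centred on the biome centroid, with the
#' origin at the projected bounding-box minimum corner. Cells that do not
#' intersect the biome are discarded. Cell ids are `cell_<row>_<col>`.
#'
#' @param biome Biome geometry or one-row `region_set`.
#' @param cell_size_km Cell edge length in km.
#' @return A `region_set` of cells (level 99) whose `grid_spec` attribute
#'   records the projection parameters, origin and dimensions.
#' @export
build_grid <- function(biome, cell_size_km = 50) {
  geometry <- if (inherits(biome, "region_set")) biome$geometry[[1]] else biome
  ring <- normalize_ring(geometry[[1]])
  cent <- ring_centroid(ring)
  proj <- cea_project(ring[, 1], ring[, 2], lon0 = cent[1], lat_ts = cent[2])
  x0 <- min(proj$x); y0 <- min(proj$y)
  n_cols <- max(1L, ceiling((max(proj$x) - x0) / cell_size_km))
  n_rows <- max(1L, ceiling((max(proj$y) - y0) / cell_size_km))
  biome_xy <- cbind(proj$x, proj$y)
  cells <- list(); ids <- character(0)
  for (r in seq_len(n_rows)) {
    for (cl in seq_len(n_cols)) {
      xa <- x0 + (cl - 1) * cell_size_km; xb <- xa + cell_size_km
      ya <- y0 + (r - 1) * cell_size_km; yb <- ya + cell_size_km
      cell_xy <- cbind(c(xa, xb, xb, xa), c(ya, ya, yb, yb))
      inter <- clip_ring_convex(biome_xy, cell_xy)
      if (nrow(inter) >= 3 && abs(ring_signed_area(inter)) > 1e-9) {
        ll <- cea_unproject(cell_xy[, 1], cell_xy[, 2],
                            lon0 = cent[1], lat_ts = cent[2])
        cells[[length(cells) + 1]] <- list(cbind(lon = ll$lon, lat = ll$lat))
        ids <- c(ids, sprintf("cell_%03d_%03d", r, cl))
      }
    }
  }
  out <- region_set(ids, cells, level = 99L, validate = FALSE)
  attr(out, "grid_spec") <- list(
    lon0 = cent[1], lat_ts = cent[2], x0 = x0, y0 = y0,
    cell_size_km = cell_size_km, n_cols = n_cols, n_rows = n_rows
  )
  out
}

#' Assign records to regions or grid cells
#'
#' Point-in-polygon assignment of each record to one analysis unit. A point
#' on a shared border (inside several closed polygons) is assigned to the
#' lexicographically lowest `region_id` — a deterministic tie-break that is
#' independent of row order. For grids built by [build_grid()], assignment
#' goes through the projection arithmetic directly, so every biome point
#' maps to exactly one cell.
#'
#' @param records Occurrence tibble with valid coordinates (post filter 2).
#' @param regions A `region_set` (sub-basins or grid cells).
#' @return Tibble `record_id`, `region_id` (`NA` for unassigned points,
#'   which are also reported via the `n_unassigned` attribute).
#' @export
assign_records <- function(records, regions) {
  spec <- attr(regions, "grid_spec")
  if (!is.null(spec)) {
    p <- cea_project(records$longitude, records$latitude,
                     lon0 = spec$lon0, lat_ts = spec$lat_ts)
    col <- pmin(pmax(floor((p$x - spec$x0) / spec$cell_size_km), 0),
                spec$n_cols - 1) + 1
    row <- pmin(pmax(floor((p$y - spec$y0) / spec$cell_size_km), 0),
                spec$n_rows - 1) + 1
    rid <- sprintf("cell_%03d_%03d", row, col)
    rid[!(rid %in% regions$region_id)] <- NA_character_
  } else {
    order_idx <- order(regions$region_id)
    rid <- rep(NA_character_, nrow(records))
    for (i in order_idx) {
      todo <- is.na(rid)
      if (!any(todo)) break
      inside <- point_in_polygon(records$longitude[todo], records$latitude[todo],
                                 regions$geometry[[i]])
      inside[is.na(inside)] <- FALSE
      rid[which(todo)[inside]] <- regions$region_id[i]
    }
  }
  out <- tibble::tibble(record_id = records$record_id, region_id = rid)
  attr(out, "n_unassigned") <- sum(is.na(rid))
  out
}
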