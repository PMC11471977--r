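# Planar/spherical polygon primitives shared by the filtering, regionalization
# and gridding stages. A geometry is a list of rings; each ring is an n x 2
# matrix of (lon, lat) vertices with no repeated closing vertex. Ring 1 is the
# outer boundary, subsequent rings are holes.

#' Build a rectangular geometry
#'
#' Convenience constructor for axis-aligned rectangles in lon/lat degrees,
#' used throughout the synthetic landscape generator and tests.
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds in decimal degrees.
#' @return A geometry: a list holding one 4 x 2 vertex matrix (lon, lat),
#'   counter-clockwise, unclosed.
#' @export
rect_geometry <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  list(cbind(
    lon = c(xmin, xmax, xmax, xmin),
    lat = c(ymin, ymin, ymax, ymax)
  ))
}

# drop a duplicated closing vertex, keep matrix shape
normalize_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) > 1 && all(abs(ring[1, ] - ring[nrow(ring), ]) < 1e-12)) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  storage.mode(ring) <- "double"
  colnames(ring) <- c("lon", "lat")
  ring
}

close_ring <- function(ring) rbind(ring, ring[1, , drop = FALSE])

# TRUE if point lies on the segment (a, b) within tolerance
point_on_segment <- function(px, py, ax, ay, bx, by, eps = 1e-9) {
  cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  scale <- max(abs(c(ax, ay, bx, by, px, py)), 1)
  if (abs(cross) > eps * scale) return(FALSE)
  dot <- (px - ax) * (bx - ax) + (py - ay) * (by - ay)
  len2 <- (bx - ax)^2 + (by - ay)^2
  dot >= -eps * scale && dot <= len2 + eps * scale
}

point_on_ring_boundary <- function(px, py, ring) {
  n <- nrow(ring)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (point_on_segment(px, py, ring[i, 1], ring[i, 2], ring[j, 1], ring[j, 2])) {
      return(TRUE)
    }
  }
  FALSE
}

# even-odd crossing number; boundary handled separately by the caller
ring_crossing_inside <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- ring[i, 2]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- ring[i, 1] + (py - yi) / (yj - yi) * (ring[j, 1] - ring[i, 1])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Point-in-polygon test with a closed boundary
#'
#' Ray-casting (even-odd) containment with the closed-boundary convention:
#' a point lying exactly on any ring edge or vertex counts as inside,
#' including on a hole's boundary. Vectorized over points.
#'
#' @param lon,lat Numeric vectors of point coordinates (decimal degrees).
#' @param geometry A geometry (list of rings; ring 1 outer, others holes).
#' @return Logical vector, one element per point. `NA` coordinates give `NA`.
#' @export
#' @examples
#' sq <- rect_geometry(0, 1, 0, 1)
#' point_in_polygon(c(0.5, 1.5, 1.0), c(0.5, 0.5, 0.5), sq)
point_in_polygon <- function(lon, lat, geometry) {
  stopifnot(length(lon) == length(lat))
  rings <- lapply(geometry, normalize_ring)
  if (length(rings) == 0 || nrow(rings[[1]]) < 3) {
    stop("invalid polygon: outer ring needs at least 3 vertices", call. = FALSE)
  }
  vapply(seq_along(lon), function(k) {
    px <- lon[k]; py <- lat[k]
    if (is.na(px) || is.na(py)) return(NA)
    if (!is.finite(px) || !is.finite(py)) {
      stop("point_in_polygon: coordinates must be finite", call. = FALSE)
    }
    # boundary of any ring (outer or hole) is inside
    for (r in rings) if (point_on_ring_boundary(px, py, r)) return(TRUE)
    if (!ring_crossing_inside(px, py, rings[[1]])) return(FALSE)
    if (length(rings) > 1) {
      for (r in rings[-1]) if (ring_crossing_inside(px, py, r)) return(FALSE)
    }
    TRUE
  }, logical(1))
}

#' Spherical polygon area in square kilometres
#'
#' Area on a sphere of radius 6371 km for polygons whose edges are straight
#' in lon/lat space (they follow the plate-carrée chart, not great circles).
#' Computed exactly by Green's theorem, \eqn{A = R^2 |\oint \sin\varphi \,
#' d\lambda|}, with the closed-form integral for latitude varying linearly
#' with longitude along each edge. This convention makes areas exactly
#' additive under lon/lat tiling: children of a subdivided basin sum to
#' their parent. For an axis-aligned rectangle it reduces to the spherical
#' zone formula \eqn{R^2 \Delta\lambda (\sin\varphi_2 - \sin\varphi_1)}.
#' Hole areas are subtracted from the outer ring.
#'
#' @param geometry A geometry (list of rings).
#' @return Area in km^2.
#' @export
polygon_area_km2 <- function(geometry) {
  rings <- lapply(geometry, normalize_ring)
  areas <- vapply(rings, ring_area_sphere_km2, numeric(1))
  if (length(areas) == 1) areas else areas[1] - sum(areas[-1])
}

ring_area_sphere_km2 <- function(ring) {
  R <- 6371
  lam <- ring[, 1] * pi / 180
  phi <- ring[, 2] * pi / 180
  n <- length(lam)
  j <- c(2:n, 1L)
  dlam <- lam[j] - lam
  dphi <- phi[j] - phi
  # edge integral of sin(phi) d lambda with phi linear in lambda
  mean_sin <- ifelse(abs(dphi) < 1e-12,
                     sin((phi + phi[j]) / 2),
                     (cos(phi) - cos(phi[j])) / ifelse(dphi == 0, 1, dphi))
  abs(sum(dlam * mean_sin)) * R^2
}

# planar shoelace signed area (degrees^2); >0 means counter-clockwise
ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

is_convex_ring <- function(ring) {
  ring <- normalize_ring(ring)
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  sgn <- 0
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[(i %% n) + 1, ]; c <- ring[((i + 1) %% n) + 1, ]
    cr <- (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
    if (abs(cr) < 1e-12) next
    if (sgn == 0) sgn <- sign(cr) else if (sign(cr) != sgn) return(FALSE)
  }
  TRUE
}

ring_centroid <- function(ring) {
  ring <- normalize_ring(ring)
  a <- ring_signed_area(ring)
  if (abs(a) < 1e-12) return(colMeans(ring))
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Sutherland-Hodgman: clip a (possibly concave) subject ring against a CONVEX
# clip ring. Returns a ring matrix (possibly with 0 rows when disjoint).
clip_ring_convex <- function(subject, clip) {
  subject <- normalize_ring(subject)
  clip <- normalize_ring(clip)
  if (!is_convex_ring(clip)) {
    stop("clip region must be convex for polygon clipping", call. = FALSE)
  }
  if (ring_signed_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]
    b <- clip[(i %% nc) + 1, ]
    input <- out
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(input)
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    for (k in seq_len(n)) {
      cur <- input[k, ]
      prv <- input[if (k == 1) n else k - 1, ]
      cs <- side(cur); ps <- side(prv)
      intersect_pt <- function() {
        t <- ps / (ps - cs)
        prv + t * (cur - prv)
      }
      if (cs >= 0) {
        if (ps < 0) out <- rbind(out, intersect_pt())
        out <- rbind(out, cur)
      } else if (ps >= 0) {
        out <- rbind(out, intersect_pt())
      }
    }
  }
  if (nrow(out) >= 3) {
    # drop numerically duplicated consecutive vertices
    keep <- c(TRUE, rowSums(abs(diff(out))) > 1e-12)
    out <- out[keep, , drop = FALSE]
    if (nrow(out) > 1 && all(abs(out[1, ] - out[nrow(out), ]) < 1e-12)) {
      out <- out[-nrow(out), , drop = FALSE]
    }
  }
  colnames(out) <- c("lon", "lat")
  out
}

# intersect a full geometry (outer + holes) with a convex clip ring
clip_geometry_convex <- function(geometry, clip_ring) {
  rings <- lapply(geometry, function(r) clip_ring_convex(r, clip_ring))
  rings <- rings[vapply(rings, nrow, integer(1)) >= 3]
  rings
}

segments_properly_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

ring_self_intersects <- function(ring) {
  ring <- normalize_ring(ring)
  n <- nrow(ring)
  if (n < 4) return(FALSE)
  edges <- lapply(seq_len(n), function(i) {
    list(a = ring[i, ], b = ring[(i %% n) + 1, ])
  })
  for (i in seq_len(n - 2)) {
    for (j in seq((i + 2), n)) {
      if (i == 1 && j == n) next  # adjacent through the wrap-around
      if (segments_properly_intersect(edges[[i]]$a, edges[[i]]$b,
                                      edges[[j]]$a, edges[[j]]$b)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

geometry_bbox <- function(geometry) {
  ring <- normalize_ring(geometry[[1]])
  c(xmin = min(ring[, 1]), xmax = max(ring[, 1]),
    ymin = min(ring[, 2]), ymax = max(ring[, 2]))
}

# cylindrical equal-area projection, standard parallel lat_ts, central
# meridian lon0; returns/accepts km
cea_project <- function(lon, lat, lon0, lat_ts) {
  R <- 6371
  k <- cos(lat_ts * pi / 180)
  list(x = R * (lon - lon0) * pi / 180 * k,
       y = R * sin(lat * pi / 180) / k)
}

cea_unproject <- function(x, y, lon0, lat_ts) {
  R <- 6371
  k <- cos(lat_ts * pi / 180)
  list(lon = lon0 + x / (R * k) * 180 / pi,
       lat = asin(pmin(1, pmax(-1, y * k / R))) * 180 / pi)
}
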