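# Low-level planar/spherical geometry used across the package.
# Coordinates are WGS84 lon/lat degrees everywhere; planar work happens in a
# local equirectangular projection whose error is negligible at metro scale
# (the study areas span < 1.5 degrees).

#' Mean Earth radius in kilometres used for all spherical distances.
#' @noRd
EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between lon/lat points, in kilometres.
#'
#' Thin wrapper over [geosphere::distHaversine()] pinning the mean Earth
#' radius, so every distance in the package uses the same sphere.
#'
#' @param p,q two-column matrices (lon, lat) or length-2 vectors; recycled
#'   row-wise as in `geosphere`.
#' @return numeric vector of distances in km.
#' @export
haversine_km <- function(p, q) {
  geosphere::distHaversine(p, q, r = EARTH_RADIUS_KM)
}

#' Local equirectangular projection to metres.
#'
#' Projects lon/lat onto a plane tangent near `center`: x = R cos(lat0) dlon,
#' y = R dlat (radians). Adequate for point-to-segment distances and polygon
#' areas at metropolitan extents.
#'
#' @param coords two-column matrix (lon, lat) in degrees.
#' @param center length-2 numeric (lon0, lat0); defaults to the coordinate
#'   column means.
#' @return two-column matrix (x, y) in metres, with the center as attribute
#'   `"center"`.
#' @export
project_local <- function(coords, center = NULL) {
  coords <- coerce_coords(coords)
  if (is.null(center)) center <- colMeans(coords)
  rad <- pi / 180
  r_m <- EARTH_RADIUS_KM * 1000
  x <- (coords[, 1] - center[1]) * rad * r_m * cos(center[2] * rad)
  y <- (coords[, 2] - center[2]) * rad * r_m
  out <- cbind(x = x, y = y)
  attr(out, "center") <- center
  out
}

#' @noRd
coerce_coords <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  storage.mode(p) <- "double"
  p
}

#' Signed shoelace area of a projected ring (m^2); positive if CCW.
#' @noRd
ring_signed_area_m2 <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(n, seq_len(n - 1))  # previous vertex
  sum(x[j] * y - x * y[j]) / 2
}

#' Area of a polygon (exterior ring plus holes) in km^2.
#'
#' @param rings list of two-column lon/lat matrices; first is the exterior
#'   ring, the rest are holes. Rings need not be explicitly closed.
#' @return area in km^2 (holes subtracted).
#' @export
polygon_area_km2 <- function(rings) {
  center <- colMeans(rings[[1]])
  areas <- vapply(rings, function(r) {
    abs(ring_signed_area_m2(project_local(r, center)))
  }, numeric(1))
  (areas[1] - sum(areas[-1])) / 1e6
}

#' Centroid of a polygon's exterior ring, in lon/lat.
#'
#' Standard area-weighted polygon centroid computed in the local projection
#' and mapped back to degrees. Holes are ignored: for the administrative
#' polygons this package handles they are rare and tiny, and the centroid is
#' only used as a representative point for distances.
#'
#' @param rings as in [polygon_area_km2()].
#' @return length-2 numeric (lon, lat).
#' @export
polygon_centroid <- function(rings) {
  ring <- close_ring(rings[[1]])
  center <- colMeans(ring)
  xy <- project_local(ring, center)
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  i <- seq_len(n - 1); j <- i + 1
  cross <- x[i] * y[j] - x[j] * y[i]
  a <- sum(cross) / 2
  if (abs(a) < 1e-9) {  # degenerate: fall back to vertex mean
    cx <- mean(x[i]); cy <- mean(y[i])
  } else {
    cx <- sum((x[i] + x[j]) * cross) / (6 * a)
    cy <- sum((y[i] + y[j]) * cross) / (6 * a)
  }
  rad <- pi / 180
  r_m <- EARTH_RADIUS_KM * 1000
  c(
    lon = center[1] + cx / (r_m * cos(center[2] * rad)) / rad,
    lat = center[2] + cy / r_m / rad
  )
}

#' Ensure a ring's last vertex equals its first.
#' @noRd
close_ring <- function(ring) {
  ring <- coerce_coords(ring)
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

#' Drop a closing vertex if present.
#' @noRd
open_ring <- function(ring) {
  ring <- coerce_coords(ring)
  n <- nrow(ring)
  if (n > 1 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  ring
}

#' Points-in-polygon test with even-odd hole semantics.
#'
#' Fast path is [mgcv::in.out()] applied per ring; a point is inside the
#' polygon iff it falls inside an odd number of rings (exterior + holes).
#' Points exactly on a boundary are resolved by the caller's tie-break rule.
#'
#' @param pts two-column lon/lat matrix of query points.
#' @param rings list of rings (exterior first).
#' @return logical vector, one per query point.
#' @export
points_in_polygon <- function(pts, rings) {
  pts <- coerce_coords(pts)
  inside <- rep(0L, nrow(pts))
  for (r in rings) {
    ring <- close_ring(r)
    inside <- inside + as.integer(mgcv::in.out(ring, pts))
  }
  inside %% 2L == 1L
}

#' Minimum distance from points to one segment, planar coordinates.
#'
#' Vectorised over points. Degenerate (zero-length) segments are treated as
#' points.
#'
#' @param pts two-column xy matrix (metres).
#' @param a,b segment endpoints, length-2 each (metres).
#' @return numeric vector of distances (metres).
#' @noRd
dist_point_segment <- function(pts, a, b) {
  d <- b - a
  len2 <- sum(d * d)
  if (len2 == 0) {
    return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  }
  t <- ((pts[, 1] - a[1]) * d[1] + (pts[, 2] - a[2]) * d[2]) / len2
  t <- pmin(1, pmax(0, t))
  px <- a[1] + t * d[1]
  py <- a[2] + t * d[2]
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

#' Minimum distance between two planar segments (metres).
#'
#' Zero when the segments intersect; otherwise the smallest of the four
#' endpoint-to-segment distances.
#' @noRd
dist_segment_segment <- function(p1, p2, q1, q2) {
  if (segments_intersect(p1, p2, q1, q2)) return(0)
  min(
    dist_point_segment(matrix(p1, ncol = 2), q1, q2),
    dist_point_segment(matrix(p2, ncol = 2), q1, q2),
    dist_point_segment(matrix(q1, ncol = 2), p1, p2),
    dist_point_segment(matrix(q2, ncol = 2), p1, p2)
  )
}

#' Proper/improper segment intersection test (orientation method).
#' @noRd
segments_intersect <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(a, b, c) {  # c collinear with ab: does c lie on ab?
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (o1 == 0 && on_seg(p1, p2, q1)) || (o2 == 0 && on_seg(p1, p2, q2)) ||
    (o3 == 0 && on_seg(q1, q2, p1)) || (o4 == 0 && on_seg(q1, q2, p2))
}

#' Minimum distance between two polygon boundaries in metres.
#'
#' Used by the contiguity test: boundaries sharing at least one point are at
#' distance zero (up to the caller's tolerance).
#'
#' @param ring_a,ring_b projected xy matrices of the two exterior rings.
#' @return minimum over all segment pairs, metres.
#' @noRd
boundary_min_dist_m <- function(ring_a, ring_b) {
  ra <- close_ring(ring_a); rb <- close_ring(ring_b)
  best <- Inf
  for (i in seq_len(nrow(ra) - 1)) {
    p1 <- ra[i, ]; p2 <- ra[i + 1, ]
    for (j in seq_len(nrow(rb) - 1)) {
      d <- dist_segment_segment(p1, p2, rb[j, ], rb[j + 1, ])
      if (d < best) best <- d
      if (best == 0) return(0)
    }
  }
  best
}

#' Length of collinear overlap between the boundaries of two rings (metres).
#'
#' Rook contiguity requires a shared border of positive length, i.e. a pair
#' of collinear segments overlapping in more than a point.
#' @noRd
boundary_shared_length_m <- function(ring_a, ring_b, tol_m = 1e-3) {
  ra <- close_ring(ring_a); rb <- close_ring(ring_b)
  total <- 0
  for (i in seq_len(nrow(ra) - 1)) {
    p1 <- ra[i, ]; p2 <- ra[i + 1, ]
    u <- p2 - p1
    ulen <- sqrt(sum(u * u))
    if (ulen == 0) next
    uhat <- u / ulen
    for (j in seq_len(nrow(rb) - 1)) {
      q1 <- rb[j, ]; q2 <- rb[j + 1, ]
      # both endpoints of q within tol of the line through p, and vice versa
      dq1 <- dist_point_segment(matrix(q1, ncol = 2), p1, p2)
      dq2 <- dist_point_segment(matrix(q2, ncol = 2), p1, p2)
      if (dq1 > tol_m || dq2 > tol_m) next
      t1 <- sum((q1 - p1) * uhat); t2 <- sum((q2 - p1) * uhat)
      lo <- max(0, min(t1, t2)); hi <- min(ulen, max(t1, t2))
      if (hi - lo > tol_m) total <- total + (hi - lo)
    }
  }
  total
}

#' Clip a polyline to a lon/lat bounding box.
#'
#' Liang–Barsky parametric clipping per segment; a polyline leaving and
#' re-entering the box yields multiple output polylines.
#'
#' @param line two-column lon/lat matrix.
#' @param bbox numeric `c(xmin, ymin, xmax, ymax)`.
#' @return list of two-column matrices (possibly empty).
#' @export
clip_polyline_bbox <- function(line, bbox) {
  line <- coerce_coords(line)
  pieces <- list()
  current <- NULL
  for (i in seq_len(nrow(line) - 1)) {
    seg <- clip_segment_bbox(line[i, ], line[i + 1, ], bbox)
    if (is.null(seg)) {
      if (!is.null(current) && nrow(current) >= 2) pieces[[length(pieces) + 1]] <- current
      current <- NULL
      next
    }
    if (is.null(current)) {
      current <- seg
    } else if (all(abs(current[nrow(current), ] - seg[1, ]) < 1e-12)) {
      current <- rbind(current, seg[2, ])
    } else {
      if (nrow(current) >= 2) pieces[[length(pieces) + 1]] <- current
      current <- seg
    }
  }
  if (!is.null(current) && nrow(current) >= 2) pieces[[length(pieces) + 1]] <- current
  pieces
}

#' @noRd
clip_segment_bbox <- function(p, q, bbox) {
  d <- q - p
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    pk <- switch(k, -d[1], d[1], -d[2], d[2])
    qk <- switch(k, p[1] - bbox[1], bbox[3] - p[1], p[2] - bbox[2], bbox[4] - p[2])
    if (pk == 0) {
      if (qk < 0) return(NULL)
    } else {
      r <- qk / pk
      if (pk < 0) {
        if (r > t1) return(NULL)
        if (r > t0) t0 <- r
      } else {
        if (r < t0) return(NULL)
        if (r < t1) t1 <- r
      }
    }
  }
  rbind(p + t0 * d, p + t1 * d)
}
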