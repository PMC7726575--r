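# Event-to-nearest-highway distances and their yearly upper percentiles.

#' Distance from a point to a polyline, in metres
#'
#' Minimum over segments of the point-to-segment distance, computed in the
#' local equirectangular projection centred on the combined point/polyline
#' extent. Degenerate (repeated-vertex) segments are treated as points.
#'
#' @param p length-2 lon/lat vector, or a two-column matrix of points.
#' @param line two-column lon/lat polyline matrix (>= 2 vertices).
#' @param center optional projection center (lon, lat); defaults to the
#'   midpoint of the combined point/polyline bounding box.
#' @return numeric vector of distances in metres, one per point.
#' @export
point_to_polyline_m <- function(p, line, center = NULL) {
  p <- coerce_coords(p)
  line <- coerce_coords(line)
  if (nrow(line) < 2) stop("polyline needs at least 2 vertices")
  if (is.null(center)) center <- bbox_center(rbind(p, line))
  pts <- project_local(p, center)
  seg <- project_local(line, center)
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(seg) - 1)) {
    best <- pmin(best, dist_point_segment(pts, seg[i, ], seg[i + 1, ]))
  }
  best
}

#' Per-event distance to the nearest highway, metres
#'
#' @param events event data.frame with `lon`, `lat`.
#' @param highways a `highway_set` (>= 1 polyline).
#' @return numeric vector, one distance per event row.
#' @export
event_highway_distance_m <- function(events, highways) {
  if (length(highways) == 0) stop("empty highway set")
  pts <- cbind(events$lon, events$lat)
  if (nrow(pts) == 0) return(numeric(0))
  # one projection center for the whole dataset (events + highways)
  center <- bbox_center(rbind(pts, do.call(rbind, lapply(highways, identity))))
  best <- rep(Inf, nrow(pts))
  for (line in highways) {
    best <- pmin(best, point_to_polyline_m(pts, line, center = center))
  }
  best
}

#' Midpoint of a coordinate set's bounding box.
#' @noRd
bbox_center <- function(coords) {
  c((min(coords[, 1]) + max(coords[, 1])) / 2,
    (min(coords[, 2]) + max(coords[, 2])) / 2)
}

#' Yearly 99th percentile of event-to-highway distance
#'
#' For each calendar year, computes the distance below which 99% of that
#' year's events lie. The default percentile convention is linear
#' interpolation between order statistics (R quantile type 7);
#' `method = "nearest"` uses the nearest-rank convention instead (the two
#' differ by well under a metre at a few hundred events).
#'
#' @param events dated, geolocated event data.frame.
#' @param highways a `highway_set`.
#' @param prob percentile level (default 0.99).
#' @param method `"linear"` or `"nearest"`.
#' @return data.frame (`year`, `n_events`, `p99_m`), one row per year with
#'   events; the full per-event distance vector is attached as attribute
#'   `"distances"` (named by year). Years with a single event report that
#'   event's distance.
#' @export
p99_by_year <- function(events, highways, prob = 0.99,
                        method = c("linear", "nearest")) {
  method <- match.arg(method)
  d <- event_highway_distance_m(events, highways)
  yr <- as.integer(format(events$date, "%Y"))
  years <- sort(unique(yr))
  rows <- lapply(years, function(y) {
    dy <- d[yr == y]
    p <- if (method == "linear") {
      unname(stats::quantile(dy, probs = prob, type = 7))
    } else {
      sort(dy)[max(1L, ceiling(prob * length(dy)))]
    }
    data.frame(year = y, n_events = length(dy), p99_m = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "distances") <- stats::setNames(
    lapply(years, function(y) d[yr == y]), years
  )
  out
}
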