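# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Ray-casting point-in-polygon (even-odd rule, single ring, open or closed).
oracle_point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) {
    ring <- ring[-n, , drop = FALSE]
    n <- n - 1
  }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

# Brute-force double-loop spatial correlation for an explicit pair set.
oracle_spatial_G <- function(h, pairs, mu = NULL, sigma2 = NULL) {
  if (is.null(mu)) mu <- sum(h) / length(h)
  if (is.null(sigma2)) sigma2 <- sum((h - mu)^2) / length(h)
  acc <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    acc <- acc + (h[i] - mu) * (h[j] - mu)
  }
  acc / (nrow(pairs) * sigma2)
}

# Brute-force co-occurrence weights: intersection of active-week sets.
oracle_cooc_weights <- function(events, anchor) {
  wk <- as.integer(floor(as.numeric(events$date - anchor) / 7))
  nb <- sort(unique(events$neighborhood_id))
  weeks_of <- lapply(nb, function(k) unique(wk[events$neighborhood_id == k]))
  names(weeks_of) <- nb
  out <- list()
  if (length(nb) >= 2) {
    cmb <- utils::combn(nb, 2)
    for (c_i in seq_len(ncol(cmb))) {
      a <- cmb[1, c_i]; b <- cmb[2, c_i]
      w <- length(intersect(weeks_of[[a]], weeks_of[[b]]))
      if (w > 0) out[[paste(a, b, sep = "|")]] <- w
    }
  }
  out
}

# Union-find connected components over an edge list of string ids.
oracle_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      ra <- find(edges[r, 1]); rb <- find(edges[r, 2])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  vapply(nodes, find, character(1))
}

# Dense-sampling point-to-polyline distance: sample each segment every
# step_m metres in the projected plane and take the closest sample. The
# projection center is shared with the implementation's convention (bounding
# box midpoint) so that only the sampling differs.
oracle_polyline_dist_m <- function(p, line, step_m = 1, center = NULL) {
  if (is.null(center)) {
    all_c <- rbind(matrix(p, ncol = 2), line)
    center <- c((min(all_c[, 1]) + max(all_c[, 1])) / 2,
                (min(all_c[, 2]) + max(all_c[, 2])) / 2)
  }
  prj <- function(m) homnet::project_local(m, center)
  pt <- prj(matrix(p, ncol = 2))
  xy <- prj(line)
  best <- Inf
  for (i in seq_len(nrow(xy) - 1)) {
    a <- xy[i, ]; b <- xy[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    ts <- if (len == 0) 0 else seq(0, 1, length.out = max(2, ceiling(len / step_m) + 1))
    for (t in ts) {
      q <- a + t * (b - a)
      best <- min(best, sqrt(sum((pt - q)^2)))
    }
  }
  best
}

# Small standard fixtures -----------------------------------------------------

grid_city <- function(n_rows, n_cols, n_muni = 1, seed = 1, ...) {
  cfg <- homnet::city_config(
    n_rows = n_rows, n_cols = n_cols, n_municipalities = n_muni,
    seed = seed, ...
  )
  list(cfg = cfg, city = homnet::generate_city(cfg))
}

# Expected queen / rook pair counts on an r x c grid.
grid_queen_pairs <- function(r, c) {
  rook <- r * (c - 1) + c * (r - 1)
  diag <- 2 * (r - 1) * (c - 1)
  rook + diag
}
grid_rook_pairs <- function(r, c) r * (c - 1) + c * (r - 1)

# weekly_counts constructor for hand-built matrices.
as_weekly <- function(m, anchor = as.Date("2011-01-03")) {
  structure(
    m,
    week_start = anchor + 7 * (seq_len(nrow(m)) - 1L),
    anchor = anchor,
    class = c("weekly_counts", "matrix", "array")
  )
}
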