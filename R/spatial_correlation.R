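# Distance-binned spatial correlation of per-capita event counts across
# neighborhood pairs.

#' Per-neighborhood population proxy
#'
#' Neighborhood-level populations are typically unavailable, so the
#' per-capita denominator is the proxy `A_i * P_m`: neighborhood area (km^2)
#' times the population of its municipality (persons). An alternative
#' `"area_fraction"` mode allocates the municipal population by area share,
#' `(A_i / sum of municipal area) * P_m`, which has person units.
#'
#' @param nmap a [neighborhood_map()].
#' @param pops municipality/population data.frame.
#' @param mode `"literal"` (default, `A_i * P_m`) or `"area_fraction"`.
#' @return named numeric vector of proxies, one per neighborhood id.
#' @export
percapita_proxy <- function(nmap, pops, mode = c("literal", "area_fraction")) {
  mode <- match.arg(mode)
  idx <- match(nmap$municipality, pops$municipality)
  if (anyNA(idx)) {
    stop("no population for municipality: ",
         paste(unique(nmap$municipality[is.na(idx)]), collapse = ", "))
  }
  p_m <- pops$population[idx]
  if (any(nmap$area_km2 <= 0)) stop("zero-area neighborhood in map")
  proxy <- switch(mode,
    literal = nmap$area_km2 * p_m,
    area_fraction = {
      muni_area <- tapply(nmap$area_km2, nmap$municipality, sum)
      nmap$area_km2 / as.numeric(muni_area[nmap$municipality]) * p_m
    }
  )
  stats::setNames(proxy, nmap$id)
}

#' Quantile edges for distance bins
#'
#' Edges at the 0, `step`, 2`step`, ..., 1 quantiles of the pairwise-distance
#' distribution; the default step 0.05 yields exactly 20 intervals. Intervals
#' are half-open `[lo, hi)` with the last closed.
#'
#' @param distances numeric vector of pairwise distances.
#' @param step quantile step in (0, 1).
#' @return numeric vector of `1/step + 1` increasing edges.
#' @export
quantile_bins <- function(distances, step = 0.05) {
  if (length(distances) < round(1 / step)) {
    stop("need at least ", round(1 / step), " pairwise distances")
  }
  edges <- unname(stats::quantile(distances, probs = seq(0, 1, by = step), type = 7))
  if (any(diff(edges) <= 0)) {
    stop("degenerate distance distribution: duplicated quantile edges")
  }
  edges
}

#' Bin index of each distance given quantile edges ([lo, hi), last closed).
#' @noRd
bin_of <- function(d, edges) {
  b <- findInterval(d, edges, rightmost.closed = TRUE)
  b[b < 1 | b > length(edges) - 1] <- NA_integer_
  b
}

#' Spatial correlation statistic for one pair set
#'
#' `G = sum over unordered pairs (i, j), i != j, of
#' (h_i - mu)(h_j - mu) / (|N| * sigma^2)`, where `h` holds per-capita
#' values, and `mu`, `sigma^2` are the mean and *population* variance of `h`
#' over all neighborhoods (global moments, not per-bin).
#'
#' @param h named numeric vector of per-capita values for all neighborhoods.
#' @param pairs two-column matrix (or data.frame) of neighborhood ids or
#'   indices forming the pair set `N`.
#' @param mu,sigma2 global moments; computed from `h` when omitted.
#' @return the scalar G value.
#' @export
spatial_G <- function(h, pairs, mu = mean(h), sigma2 = mean((h - mean(h))^2)) {
  if (sigma2 <= 0) stop("sigma^2 is zero: spatial correlation undefined")
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 1) stop("empty pair set")
  i <- pairs[, 1]; j <- pairs[, 2]
  if (is.character(i)) {
    i <- match(i, names(h)); j <- match(j, names(h))
    if (anyNA(i) || anyNA(j)) stop("pair ids not present in h")
  }
  if (any(i == j)) stop("self-pairs are not allowed")
  sum((h[i] - mu) * (h[j] - mu)) / (nrow(pairs) * sigma2)
}

#' Distance-binned spatial correlation curve for one year
#'
#' Aggregates casualties per neighborhood over the calendar year, converts to
#' per-capita values through the [percapita_proxy()], computes global moments
#' over all neighborhoods (zero-event ones included), bins all unordered
#' centroid-distance pairs into quantile bins, and evaluates [spatial_G()]
#' per bin.
#'
#' @param events mapped event data.frame.
#' @param nmap a [neighborhood_map()].
#' @param pops municipality/population data.frame.
#' @param year calendar year (events outside it are ignored).
#' @param step quantile step for [quantile_bins()].
#' @param proxy_mode passed to [percapita_proxy()].
#' @param measure `"casualties"` or `"events"` per neighborhood.
#' @param active_only if `TRUE`, restrict the statistic (moments, pairs) to
#'   neighborhoods with at least one event — a sensitivity variant.
#' @return data.frame (`year`, `r_lo_km`, `r_hi_km`, `n_pairs`, `G`); the
#'   per-neighborhood `h` vector is attached as attribute `"h"`.
#' @export
spatial_curve <- function(events, nmap, pops, year, step = 0.05,
                          proxy_mode = "literal",
                          measure = c("casualties", "events"),
                          active_only = FALSE) {
  measure <- match.arg(measure)
  if (is.null(events$neighborhood_id)) stop("events must be mapped first")
  yr <- as.integer(format(events$date, "%Y"))
  ev <- events[yr == year, , drop = FALSE]

  val <- if (measure == "casualties") ev$casualties else rep(1, nrow(ev))
  counts <- stats::setNames(rep(0, nrow(nmap)), nmap$id)
  if (nrow(ev) > 0) {
    agg <- tapply(val, ev$neighborhood_id, sum)
    counts[names(agg)] <- agg
  }
  proxy <- percapita_proxy(nmap, pops, mode = proxy_mode)
  h <- counts / proxy

  sel <- if (active_only) names(h)[counts > 0] else names(h)
  if (length(sel) < 2) stop("fewer than two neighborhoods in scope for year ", year)
  h <- h[sel]
  mu <- mean(h)
  sigma2 <- mean((h - mu)^2)
  if (sigma2 <= 0) {
    stop("sigma^2 is zero for year ", year, " (no event variation)")
  }

  dmat <- centroid_distance_km(nmap)[sel, sel, drop = FALSE]
  pr <- which(upper.tri(dmat), arr.ind = TRUE)
  d <- dmat[pr]
  edges <- quantile_bins(d, step = step)
  b <- bin_of(d, edges)

  rows <- lapply(seq_len(length(edges) - 1), function(k) {
    in_bin <- which(b == k)
    if (length(in_bin) == 0) return(NULL)
    g <- spatial_G(h, pr[in_bin, , drop = FALSE], mu = mu, sigma2 = sigma2)
    data.frame(
      year = year, r_lo_km = edges[k], r_hi_km = edges[k + 1],
      n_pairs = length(in_bin), G = g
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "h") <- h
  out
}
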