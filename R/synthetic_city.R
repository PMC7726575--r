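# Synthetic study area and event stream. The generator emulates the four
# real input layers (events, neighborhood polygons, municipality populations,
# highways) with known statistical structure, so every downstream stage can
# be tested against ground truth.

#' Configuration for the synthetic city
#'
#' Defines a `n_rows` x `n_cols` grid of rectangular neighborhood cells of
#' side `cell_size_km`, partitioned into `n_municipalities` contiguous blocks
#' of grid columns. Events are drawn per neighborhood and week as
#' inhomogeneous Poisson counts with rate
#' `base_rate * hotspot_multiplier(k) * wave(w)`; planted same-week
#' co-occurring pairs and a highway-proximity bias can be layered on top.
#'
#' The grid is placed near (-100.3, 25.7), i.e. at the latitude of a northern
#' Mexican metropolitan area, so the spherical-distance and projection code
#' paths run under realistic coordinates.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size_km side length of each square cell, km.
#' @param n_municipalities number of contiguous column-block municipalities.
#' @param populations integer vector of municipal populations (persons), one
#'   per municipality.
#' @param base_rate expected events per neighborhood per week.
#' @param hotspot_ids integer cell indices (row-major, 1-based) with elevated
#'   rates.
#' @param hotspot_multiplier rate multiplier (>= 1) applied to hotspots.
#' @param wave numeric vector of weekly rate multipliers; recycled to
#'   `n_weeks`. Encodes e.g. a violence wave that rises and decays.
#' @param planted_pairs list of `c(a, b, n_weeks)` triples (cell indices):
#'   each pair is forced to have >= 1 event in both cells in `n_weeks`
#'   distinct weeks. Week sets are disjoint across all planted pairs so that
#'   exactly the planted edges (and no by-product edges) appear downstream.
#' @param highway_path two-column lon/lat matrix; `NULL` gives a diagonal
#'   across the city.
#' @param highway_bias fraction in `[0, 1]` of events relocated to within
#'   `d_h_km` of the highway.
#' @param d_h_km highway-bias distance threshold, km.
#' @param casualty_p if `NULL`, every event has 1 casualty; otherwise
#'   casualties are zero-truncated geometric with success probability
#'   `casualty_p` (mean `1/casualty_p`).
#' @param n_weeks number of study weeks.
#' @param start_date first day of the study window (a Monday keeps week bins
#'   aligned with calendar weeks).
#' @param seed integer seed driving all generator randomness.
#' @return a `city_config` list.
#' @export
city_config <- function(n_rows = 10, n_cols = 10, cell_size_km = 1,
                        n_municipalities = 4,
                        populations = NULL,
                        base_rate = 0.05,
                        hotspot_ids = integer(0), hotspot_multiplier = 8,
                        wave = 1,
                        planted_pairs = list(),
                        highway_path = NULL, highway_bias = 0, d_h_km = 0.5,
                        casualty_p = NULL,
                        n_weeks = 104,
                        start_date = as.Date("2011-01-03"),
                        seed = 1) {
  if (is.null(populations)) {
    populations <- rep(100000L, n_municipalities)
  }
  cfg <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size_km = cell_size_km,
    n_municipalities = as.integer(n_municipalities),
    populations = as.numeric(populations),
    base_rate = base_rate,
    hotspot_ids = as.integer(hotspot_ids),
    hotspot_multiplier = hotspot_multiplier,
    wave = wave,
    planted_pairs = planted_pairs,
    highway_path = highway_path,
    highway_bias = highway_bias, d_h_km = d_h_km,
    casualty_p = casualty_p,
    n_weeks = as.integer(n_weeks),
    start_date = as.Date(start_date),
    seed = as.integer(seed)
  )
  class(cfg) <- "city_config"
  validate_city_config(cfg)
  cfg
}

#' @noRd
validate_city_config <- function(cfg) {
  n_cells <- cfg$n_rows * cfg$n_cols
  if (cfg$n_rows < 1 || cfg$n_cols < 1) stop("grid dimensions must be positive")
  if (length(cfg$populations) != cfg$n_municipalities) {
    stop("populations must have one entry per municipality (",
         cfg$n_municipalities, "), got ", length(cfg$populations))
  }
  if (any(cfg$populations <= 0)) stop("populations must be positive")
  if (cfg$n_municipalities > cfg$n_cols) {
    stop("cannot form ", cfg$n_municipalities, " contiguous column blocks from ",
         cfg$n_cols, " columns")
  }
  if (cfg$hotspot_multiplier < 1) stop("hotspot_multiplier must be >= 1")
  if (cfg$highway_bias < 0 || cfg$highway_bias > 1) stop("highway_bias must be in [0, 1]")
  if (cfg$n_weeks <= 0) stop("n_weeks must be positive")
  if (cfg$base_rate < 0) stop("base_rate must be non-negative")
  if (length(cfg$hotspot_ids) > 0 &&
      (any(cfg$hotspot_ids < 1) || any(cfg$hotspot_ids > n_cells))) {
    stop("hotspot_ids out of range")
  }
  for (p in cfg$planted_pairs) {
    if (length(p) != 3) stop("each planted pair must be c(a, b, n_weeks)")
    if (p[1] == p[2]) stop("planted pair ids must be distinct")
    if (any(p[1:2] < 1) || any(p[1:2] > n_cells)) stop("planted pair ids out of range")
    if (p[3] < 1 || p[3] > cfg$n_weeks) stop("planted pair week count out of range")
  }
  total_planted <- sum(vapply(cfg$planted_pairs, function(p) p[3], numeric(1)))
  if (length(cfg$planted_pairs) > 0 && total_planted > cfg$n_weeks) {
    stop("planted pairs need ", total_planted,
         " disjoint weeks but only ", cfg$n_weeks, " are available")
  }
  invisible(cfg)
}

#' Anchor longitude/latitude of the synthetic city's south-west corner.
#' @noRd
CITY_ORIGIN <- c(lon = -100.3, lat = 25.7)

#' Degree extents of one grid cell.
#' @noRd
cell_deg <- function(cfg) {
  rad <- pi / 180
  dlat <- cfg$cell_size_km / (EARTH_RADIUS_KM * rad)
  dlon <- cfg$cell_size_km / (EARTH_RADIUS_KM * rad * cos(CITY_ORIGIN["lat"] * rad))
  c(dlon = unname(dlon), dlat = unname(dlat))
}

#' Row-major cell index -> (row, col), 1-based.
#' @noRd
cell_rc <- function(idx, cfg) {
  r <- ((idx - 1) %/% cfg$n_cols) + 1
  c <- ((idx - 1) %% cfg$n_cols) + 1
  cbind(row = r, col = c)
}

#' Generate the synthetic study area
#'
#' Builds the gap-free grid tessellation, assigns contiguous column blocks to
#' municipalities, and lays the highway polyline (clipped to the city
#' bounding box). Deterministic given the config (the tessellation itself
#' involves no randomness).
#'
#' @param cfg a [city_config()].
#' @return list with elements `nmap` (a [neighborhood_map()]), `pops`
#'   (municipality/population data.frame) and `highways` (a `highway_set`).
#' @export
generate_city <- function(cfg) {
  validate_city_config(cfg)
  dd <- cell_deg(cfg)
  n_cells <- cfg$n_rows * cfg$n_cols
  rc <- cell_rc(seq_len(n_cells), cfg)

  # contiguous column blocks, sizes as equal as possible
  block_sizes <- diff(round(seq(0, cfg$n_cols, length.out = cfg$n_municipalities + 1)))
  muni_of_col <- rep(seq_len(cfg$n_municipalities), times = block_sizes)
  muni_names <- sprintf("M%02d", seq_len(cfg$n_municipalities))

  rings <- vector("list", n_cells)
  for (k in seq_len(n_cells)) {
    x0 <- CITY_ORIGIN["lon"] + (rc[k, "col"] - 1) * dd["dlon"]
    y0 <- CITY_ORIGIN["lat"] + (rc[k, "row"] - 1) * dd["dlat"]
    x1 <- x0 + dd["dlon"]; y1 <- y0 + dd["dlat"]
    rings[[k]] <- list(unname(rbind(
      c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)
    )))
  }
  nmap <- neighborhood_map(
    name = sprintf("N%04d", seq_len(n_cells)),
    municipality = muni_names[muni_of_col[rc[, "col"]]],
    rings = rings
  )
  pops <- data.frame(
    municipality = muni_names,
    population = cfg$populations,
    stringsAsFactors = FALSE
  )
  bbox <- c(
    CITY_ORIGIN["lon"], CITY_ORIGIN["lat"],
    CITY_ORIGIN["lon"] + cfg$n_cols * dd["dlon"],
    CITY_ORIGIN["lat"] + cfg$n_rows * dd["dlat"]
  )
  hw_path <- cfg$highway_path
  if (is.null(hw_path)) {
    hw_path <- rbind(bbox[1:2], bbox[3:4])  # SW-NE diagonal
  }
  pieces <- clip_polyline_bbox(hw_path, bbox)
  if (length(pieces) == 0) stop("highway path lies entirely outside the city")
  list(nmap = nmap, pops = pops, highways = highway_set(pieces))
}

#' Stable neighborhood id of a grid cell index.
#' @noRd
cell_id <- function(idx, city) city$nmap$id[idx]

#' Generate the synthetic event stream
#'
#' For each neighborhood `k` and week `w`, draws a Poisson count with rate
#' `base_rate * m_k * wave_w` (`m_k` the hotspot multiplier). Events receive
#' a uniform day within their week and uniform coordinates inside their cell.
#' Then, in order: planted pairs are injected (one event in each member
#' neighborhood on disjoint weeks, unless the background already put one
#' there), and a `highway_bias` fraction of events is relocated to uniform
#' positions within `d_h_km` of the highway (rejection-sampled to stay inside
#' the tessellation). Casualties default to 1 per event.
#'
#' All randomness flows from `cfg$seed`; the tessellation stage and the event
#' stage use deterministically derived sub-seeds, so the same config always
#' yields the same table.
#'
#' @param city output of [generate_city()].
#' @param cfg the same [city_config()].
#' @return event data.frame (`date`, `lon`, `lat`, `casualties`) sorted by
#'   date; the `true_neighborhood` attribute records each event's source cell
#'   id (ground truth for mapping tests; relocated events carry their
#'   post-relocation cell).
#' @export
generate_events <- function(city, cfg) {
  validate_city_config(cfg)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed + 1L)  # events sub-seed

  n_cells <- cfg$n_rows * cfg$n_cols
  wave <- rep_len(cfg$wave, cfg$n_weeks)
  mult <- rep(1, n_cells)
  mult[cfg$hotspot_ids] <- cfg$hotspot_multiplier
  dd <- cell_deg(cfg)
  rc <- cell_rc(seq_len(n_cells), cfg)
  cell_x0 <- CITY_ORIGIN["lon"] + (rc[, "col"] - 1) * dd["dlon"]
  cell_y0 <- CITY_ORIGIN["lat"] + (rc[, "row"] - 1) * dd["dlat"]

  # background counts: matrix cells x weeks
  lambda <- outer(cfg$base_rate * mult, wave)
  counts <- matrix(stats::rpois(length(lambda), lambda), nrow = n_cells)

  cell_of <- rep(rep(seq_len(n_cells), cfg$n_weeks), as.vector(counts))
  week_of <- rep(rep(seq_len(cfg$n_weeks), each = n_cells), as.vector(counts))

  # planted pairs: disjoint week sets drawn from weeks not yet used by any pair
  free_weeks <- seq_len(cfg$n_weeks)
  for (p in cfg$planted_pairs) {
    wk <- sort(sample_int(free_weeks, p[3]))
    free_weeks <- setdiff(free_weeks, wk)
    for (w in wk) {
      for (cell in p[1:2]) {
        if (!any(cell_of == cell & week_of == w)) {
          cell_of <- c(cell_of, cell)
          week_of <- c(week_of, w)
        }
      }
    }
  }

  n_ev <- length(cell_of)
  if (n_ev == 0) {
    out <- data.frame(
      date = as.Date(character(0)), lon = numeric(0), lat = numeric(0),
      casualties = integer(0)
    )
    attr(out, "true_neighborhood") <- character(0)
    return(out)
  }

  lon <- cell_x0[cell_of] + stats::runif(n_ev) * dd["dlon"]
  lat <- cell_y0[cell_of] + stats::runif(n_ev) * dd["dlat"]
  day <- sample_int(0:6, n_ev, replace = TRUE)
  date <- cfg$start_date + (week_of - 1) * 7 + day

  # highway bias: relocate a fixed fraction of events near the highway
  if (cfg$highway_bias > 0 && n_ev > 0) {
    n_move <- round(cfg$highway_bias * n_ev)
    move <- sample_int(seq_len(n_ev), n_move)
    for (i in move) {
      pt <- sample_near_highway(city, cfg)
      if (!is.null(pt)) {
        lon[i] <- pt[1]; lat[i] <- pt[2]; cell_of[i] <- pt[3]
      }
    }
  }

  casualties <- if (is.null(cfg$casualty_p)) {
    rep(1L, n_ev)
  } else {
    1L + stats::rgeom(n_ev, cfg$casualty_p)
  }

  ord <- order(date, cell_of)
  out <- data.frame(
    date = date[ord], lon = unname(lon[ord]), lat = unname(lat[ord]),
    casualties = casualties[ord]
  )
  attr(out, "true_neighborhood") <- cell_id(cell_of[ord], city)
  out
}

#' sample() without its length-1 surprise.
#' @noRd
sample_int <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Draw one point within d_h of the highway and inside some cell.
#'
#' Uniform position along the (projected) highway plus a uniform
#' perpendicular offset in [-d_h, d_h]; rejection keeps the point inside the
#' tessellation. Returns c(lon, lat, cell_index) or NULL after 200 misses.
#' @noRd
sample_near_highway <- function(city, cfg) {
  hw <- city$highways
  verts <- do.call(rbind, hw)
  center <- colMeans(verts)
  segs <- list()
  for (line in hw) {
    xy <- project_local(line, center)
    for (i in seq_len(nrow(xy) - 1)) segs[[length(segs) + 1]] <- xy[c(i, i + 1), ]
  }
  seg_len <- vapply(segs, function(s) sqrt(sum((s[2, ] - s[1, ])^2)), numeric(1))
  keep <- seg_len > 0
  segs <- segs[keep]; seg_len <- seg_len[keep]
  if (length(segs) == 0) return(NULL)
  d_m <- cfg$d_h_km * 1000
  rad <- pi / 180
  r_m <- EARTH_RADIUS_KM * 1000
  for (try in 1:200) {
    si <- sample_int(seq_along(segs), 1)
    if (length(segs) > 1) {
      si <- sample.int(length(segs), 1, prob = seg_len)
    }
    s <- segs[[si]]
    t <- stats::runif(1)
    base <- s[1, ] + t * (s[2, ] - s[1, ])
    u <- (s[2, ] - s[1, ]) / seg_len[si]
    normal <- c(-u[2], u[1])
    off <- stats::runif(1, -d_m, d_m)
    xy <- base + off * normal
    lon <- center[1] + xy[1] / (r_m * cos(center[2] * rad)) / rad
    lat <- center[2] + xy[2] / r_m / rad
    cell <- locate_cell(lon, lat, cfg)
    if (!is.na(cell)) return(c(lon, lat, cell))
  }
  NULL
}

#' Grid cell index containing a lon/lat point, NA if outside.
#' @noRd
locate_cell <- function(lon, lat, cfg) {
  dd <- cell_deg(cfg)
  col <- floor((lon - CITY_ORIGIN["lon"]) / dd["dlon"]) + 1
  row <- floor((lat - CITY_ORIGIN["lat"]) / dd["dlat"]) + 1
  if (col < 1 || col > cfg$n_cols || row < 1 || row > cfg$n_rows) return(NA_integer_)
  as.integer((row - 1) * cfg$n_cols + col)
}

#' Write all synthetic layers to disk
#'
#' Emits the same formats the real-data path reads: events CSV, neighborhoods
#' GeoJSON, municipality CSV, highways GeoJSON.
#'
#' @param city output of [generate_city()].
#' @param events output of [generate_events()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths.
#' @export
write_synthetic_city <- function(city, events, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    events = file.path(dir, "events.csv"),
    neighborhoods = file.path(dir, "neighborhoods.geojson"),
    municipalities = file.path(dir, "municipalities.csv"),
    highways = file.path(dir, "highways.geojson")
  )
  write_events_csv(events, paths["events"])
  write_neighborhoods_geojson(city$nmap, paths["neighborhoods"])
  utils::write.csv(city$pops, paths["municipalities"], row.names = FALSE)
  write_highways_geojson(city$highways, paths["highways"])
  paths
}
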