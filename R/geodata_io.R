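# Containers and I/O for the four input layers: events (CSV), neighborhood
# polygons (GeoJSON), municipality populations (CSV), highways (GeoJSON
# LineStrings or minimal OSM XML).

#' Construct a neighborhood map
#'
#' A `neighborhood_map` is a data.frame with one row per neighborhood polygon
#' and a `rings` list-column holding the polygon geometry (a list of
#' two-column lon/lat matrices, exterior ring first, holes after). Areas and
#' centroids are derived from the geometry at construction.
#'
#' Neighborhood ids are `"municipality::name"`, which disambiguates duplicate
#' neighborhood names across municipalities.
#'
#' @param name character vector of neighborhood names.
#' @param municipality character vector, same length.
#' @param rings list of ring lists, one per neighborhood.
#' @return object of class `neighborhood_map` (also a data.frame) with
#'   columns `id`, `name`, `municipality`, `area_km2`, `centroid_lon`,
#'   `centroid_lat`, `rings`.
#' @export
neighborhood_map <- function(name, municipality, rings) {
  stopifnot(length(name) == length(municipality), length(name) == length(rings))
  id <- paste0(municipality, "::", name)
  if (anyDuplicated(id)) {
    stop("duplicate neighborhood ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  area <- vapply(rings, polygon_area_km2, numeric(1))
  if (any(area <= 0)) stop("non-positive polygon area for: ", paste(id[area <= 0], collapse = ", "))
  cent <- t(vapply(rings, polygon_centroid, numeric(2)))
  out <- data.frame(
    id = id, name = name, municipality = municipality,
    area_km2 = area, centroid_lon = cent[, 1], centroid_lat = cent[, 2],
    stringsAsFactors = FALSE
  )
  out$rings <- rings
  class(out) <- c("neighborhood_map", "data.frame")
  out
}

#' @export
print.neighborhood_map <- function(x, ...) {
  cat(sprintf(
    "<neighborhood_map> %d neighborhoods, %d municipalities, total area %.2f km2\n",
    nrow(x), length(unique(x$municipality)), sum(x$area_km2)
  ))
  invisible(x)
}

#' Read a geolocated event table from CSV
#'
#' Expects columns `date` (ISO-8601), `lat`, `lon`, `casualties`; extra
#' columns (`title`, `url`, ...) are ignored. Malformed rows (unparseable
#' date or coordinate, missing casualty count) are rejected row-by-row, not
#' fatally: the returned table carries a `rejected` attribute listing each
#' rejected row number and the reason.
#'
#' @param path CSV file path.
#' @return data.frame with columns `date` (Date), `lon`, `lat`, `casualties`
#'   (integer, missing values defaulting to 1); attribute `rejected` is a
#'   data.frame (`row`, `reason`).
#' @export
read_events <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("date", "lat", "lon", "casualties")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("event CSV is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  lat <- suppressWarnings(as.numeric(raw$lat))
  lon <- suppressWarnings(as.numeric(raw$lon))
  cas <- suppressWarnings(as.integer(raw$casualties))
  cas[is.na(cas) & (is.na(raw$casualties) | raw$casualties == "")] <- 1L

  reason <- character(nrow(raw))
  reason[is.na(date)] <- "unparseable date"
  reason[is.na(lat) | is.na(lon)] <- "unparseable coordinate"
  reason[!is.na(lat) & (lat < -90 | lat > 90)] <- "latitude out of range"
  reason[!is.na(cas) & cas < 1] <- "casualties < 1"
  reason[is.na(cas)] <- "unparseable casualties"
  bad <- reason != ""

  out <- data.frame(
    date = date[!bad], lon = lon[!bad], lat = lat[!bad],
    casualties = cas[!bad], stringsAsFactors = FALSE
  )
  attr(out, "rejected") <- data.frame(
    row = which(bad), reason = reason[bad], stringsAsFactors = FALSE
  )
  out
}

#' Write an event table to CSV
#'
#' Column order is `date, lat, lon, casualties, title, url`, matching the
#' source-database schema; `title`/`url` are filled with placeholders when
#' absent.
#'
#' @param events event data.frame.
#' @param path output path.
#' @export
write_events_csv <- function(events, path) {
  n <- nrow(events)
  out <- data.frame(
    date = format(events$date, "%Y-%m-%d"),
    lat = events$lat, lon = events$lon,
    casualties = events$casualties,
    title = if (is.null(events$title)) rep("synthetic event", n) else events$title,
    url = if (is.null(events$url)) rep("about:blank", n) else events$url,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read neighborhoods from a GeoJSON FeatureCollection
#'
#' Features must be Polygon (or single-polygon MultiPolygon) geometries with
#' `name` and `municipality` properties.
#'
#' @param path GeoJSON file.
#' @return a [neighborhood_map()].
#' @export
read_neighborhoods_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  feats <- gj$features
  name <- character(length(feats))
  muni <- character(length(feats))
  rings <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    name[i] <- as.character(f$properties$name)
    muni[i] <- as.character(f$properties$municipality)
    geom <- f$geometry
    coords <- switch(geom$type,
      Polygon = geom$coordinates,
      MultiPolygon = {
        if (length(geom$coordinates) != 1) {
          stop("feature ", i, ": multi-part polygons are not supported")
        }
        geom$coordinates[[1]]
      },
      stop("feature ", i, ": unsupported geometry type ", geom$type)
    )
    rings[[i]] <- lapply(coords, function(ring) {
      do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    })
  }
  neighborhood_map(name, muni, rings)
}

#' Write a neighborhood map as GeoJSON
#' @param nmap a [neighborhood_map()].
#' @param path output path.
#' @export
write_neighborhoods_geojson <- function(nmap, path) {
  feats <- lapply(seq_len(nrow(nmap)), function(i) {
    coords <- lapply(nmap$rings[[i]], function(r) {
      r <- close_ring(r)
      lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2]))
    })
    list(
      type = "Feature",
      properties = list(name = nmap$name[i], municipality = nmap$municipality[i]),
      geometry = list(type = "Polygon", coordinates = coords)
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read municipality populations from CSV
#' @param path CSV with columns `municipality`, `population`.
#' @return data.frame with those columns.
#' @export
read_municipalities <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("municipality", "population") %in% names(df))) {
    stop("municipality CSV needs columns 'municipality' and 'population'")
  }
  if (any(df$population <= 0)) stop("populations must be positive")
  df
}

#' Read highway polylines from GeoJSON
#'
#' Accepts LineString and MultiLineString features.
#'
#' @param path GeoJSON file.
#' @return object of class `highway_set`: a list of two-column lon/lat
#'   matrices.
#' @export
read_highways_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  lines <- list()
  for (f in gj$features) {
    geom <- f$geometry
    parts <- switch(geom$type,
      LineString = list(geom$coordinates),
      MultiLineString = geom$coordinates,
      next
    )
    for (part in parts) {
      m <- do.call(rbind, lapply(part, function(p) c(p[[1]], p[[2]])))
      if (nrow(m) >= 2) lines[[length(lines) + 1]] <- m
    }
  }
  highway_set(lines)
}

#' @noRd
highway_set <- function(lines) {
  if (length(lines) > 0) {
    stopifnot(all(vapply(lines, nrow, integer(1)) >= 2))
    lines <- lapply(lines, function(m) {
      dimnames(m) <- NULL
      m
    })
  }
  structure(lines, class = "highway_set")
}

#' @export
print.highway_set <- function(x, ...) {
  cat(sprintf(
    "<highway_set> %d polylines, %d vertices\n",
    length(x), sum(vapply(x, nrow, integer(1)))
  ))
  invisible(x)
}

#' Write highways as GeoJSON LineStrings
#' @param highways a `highway_set`.
#' @param path output path.
#' @export
write_highways_geojson <- function(highways, path) {
  feats <- lapply(seq_along(highways), function(i) {
    m <- highways[[i]]
    list(
      type = "Feature",
      properties = list(way_id = i),
      geometry = list(
        type = "LineString",
        coordinates = lapply(seq_len(nrow(m)), function(k) c(m[k, 1], m[k, 2]))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Default study-area bounding box (lon/lat)
#'
#' The Monterrey metropolitan area box used when filtering OSM extracts:
#' `c(xmin, ymin, xmax, ymax)`.
#' @export
mma_bbox <- function() c(-100.8421, 25.3217, -99.5650, 26.0346)

#' Read highway ways from a minimal OSM XML export
#'
#' Parses `<node>` elements and `<way>` elements carrying a `highway` tag,
#' keeping ways whose highway class is in `types`. Ways are converted to
#' lon/lat polylines via their node references and clipped to `bbox`.
#'
#' @param path OSM XML file (as produced by an Overpass export).
#' @param types character vector of highway classes to keep. The default
#'   covers high-speed roads.
#' @param bbox optional `c(xmin, ymin, xmax, ymax)` clip box; `NULL` keeps
#'   everything.
#' @return a `highway_set`.
#' @export
read_osm_highways <- function(path,
                              types = c("motorway", "trunk", "primary"),
                              bbox = mma_bbox()) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//node")
  node_id <- xml2::xml_attr(nodes, "id")
  node_lon <- as.numeric(xml2::xml_attr(nodes, "lon"))
  node_lat <- as.numeric(xml2::xml_attr(nodes, "lat"))
  names(node_lon) <- node_id
  names(node_lat) <- node_id

  lines <- list()
  for (way in xml2::xml_find_all(doc, ".//way")) {
    tags <- xml2::xml_find_all(way, "./tag")
    keys <- xml2::xml_attr(tags, "k")
    vals <- xml2::xml_attr(tags, "v")
    hw <- vals[keys == "highway"]
    if (length(hw) == 0 || !(hw[1] %in% types)) next
    refs <- xml2::xml_attr(xml2::xml_find_all(way, "./nd"), "ref")
    refs <- refs[refs %in% node_id]
    if (length(refs) < 2) next
    m <- cbind(node_lon[refs], node_lat[refs])
    dimnames(m) <- NULL
    if (is.null(bbox)) {
      lines[[length(lines) + 1]] <- m
    } else {
      for (piece in clip_polyline_bbox(m, bbox)) {
        lines[[length(lines) + 1]] <- piece
      }
    }
  }
  highway_set(lines)
}

#' Assign events to neighborhoods by point-in-polygon
#'
#' Each event is assigned the neighborhood polygon containing its
#' coordinates; events outside every polygon are dropped (the count is
#' reported in the `n_dropped` attribute and the dropped row indices in
#' `dropped_rows`). A point on a shared boundary is assigned to the
#' containing neighborhood whose id sorts first, a deterministic tie-break.
#' Row order of the surviving events is preserved, so the operation is
#' idempotent.
#'
#' @param events event data.frame with `lon`, `lat`.
#' @param nmap a [neighborhood_map()].
#' @return the events that fell inside some polygon, with `neighborhood_id`
#'   and `municipality` columns set; attributes `n_dropped` / `dropped_rows`.
#' @export
map_events <- function(events, nmap) {
  if (nrow(nmap) == 0) stop("neighborhood map is empty")
  pts <- cbind(events$lon, events$lat)
  n <- nrow(events)
  assigned <- rep(NA_character_, n)
  if (n > 0) {
    ord <- order(nmap$id)  # visit polygons in id order so first hit wins ties
    bb <- t(vapply(nmap$rings, function(r) {
      ring <- r[[1]]
      c(min(ring[, 1]), min(ring[, 2]), max(ring[, 1]), max(ring[, 2]))
    }, numeric(4)))
    unresolved <- rep(TRUE, n)
    for (k in ord) {
      if (!any(unresolved)) break
      cand <- which(unresolved &
        pts[, 1] >= bb[k, 1] & pts[, 1] <= bb[k, 3] &
        pts[, 2] >= bb[k, 2] & pts[, 2] <= bb[k, 4])
      if (length(cand) == 0) next
      hit <- points_in_polygon(pts[cand, , drop = FALSE], nmap$rings[[k]])
      assigned[cand[hit]] <- nmap$id[k]
      unresolved[cand[hit]] <- FALSE
    }
  }
  keep <- !is.na(assigned)
  out <- events[keep, , drop = FALSE]
  out$neighborhood_id <- assigned[keep]
  out$municipality <- nmap$municipality[match(out$neighborhood_id, nmap$id)]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "dropped_rows") <- which(!keep)
  out
}

#' Polygon contiguity of a neighborhood map
#'
#' Queen contiguity links two neighborhoods whose polygon boundaries share at
#' least one point (within `tol_m` metres, to absorb coordinate noise in real
#' data); rook contiguity additionally requires a shared border of positive
#' length, so corner-only contacts do not count.
#'
#' @param nmap a [neighborhood_map()].
#' @param mode `"queen"` (default) or `"rook"`.
#' @param tol_m contact tolerance in metres.
#' @return data.frame of unordered adjacent pairs (`id_a` < `id_b`).
#' @export
adjacency <- function(nmap, mode = c("queen", "rook"), tol_m = 1) {
  mode <- match.arg(mode)
  n <- nrow(nmap)
  if (n < 2) {
    return(data.frame(id_a = character(0), id_b = character(0), stringsAsFactors = FALSE))
  }
  all_pts <- do.call(rbind, lapply(nmap$rings, function(r) r[[1]]))
  center <- colMeans(all_pts)
  proj <- lapply(nmap$rings, function(r) project_local(close_ring(r[[1]]), center))
  bb <- t(vapply(proj, function(m) c(min(m[, 1]), min(m[, 2]), max(m[, 1]), max(m[, 2])), numeric(4)))

  a_idx <- integer(0); b_idx <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      # bounding boxes must come within tol of touching
      if (bb[i, 1] > bb[j, 3] + tol_m || bb[j, 1] > bb[i, 3] + tol_m ||
          bb[i, 2] > bb[j, 4] + tol_m || bb[j, 2] > bb[i, 4] + tol_m) next
      touch <- boundary_min_dist_m(proj[[i]], proj[[j]]) <= tol_m
      if (touch && mode == "rook") {
        touch <- boundary_shared_length_m(proj[[i]], proj[[j]], tol_m = tol_m) > tol_m
      }
      if (touch) {
        a_idx <- c(a_idx, i); b_idx <- c(b_idx, j)
      }
    }
  }
  ids <- nmap$id
  a <- ids[a_idx]; b <- ids[b_idx]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(id_a = a, id_b = b, stringsAsFactors = FALSE)
  out[order(out$id_a, out$id_b), , drop = FALSE]
}

#' Pairwise centroid distances in kilometres
#'
#' Great-circle (haversine) distance between neighborhood centroids.
#'
#' @param nmap a [neighborhood_map()].
#' @return symmetric matrix (km) with neighborhood ids as dimnames.
#' @export
centroid_distance_km <- function(nmap) {
  cent <- cbind(nmap$centroid_lon, nmap$centroid_lat)
  n <- nrow(cent)
  d <- matrix(0, n, n, dimnames = list(nmap$id, nmap$id))
  if (n > 1) {
    idx <- which(upper.tri(d), arr.ind = TRUE)
    v <- haversine_km(cent[idx[, 1], , drop = FALSE], cent[idx[, 2], , drop = FALSE])
    d[idx] <- v
    d[idx[, c(2, 1), drop = FALSE]] <- v
  }
  d
}
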