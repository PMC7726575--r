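test_that("event CSV round-trips through write and read", {
  g <- grid_city(5, 5, base_rate = 0.8, n_weeks = 25, seed = 9)
  ev <- generate_events(g$city, g$cfg)
  expect_gt(nrow(ev), 300)
  path <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(ev, path)
  back <- read_events(path)
  expect_equal(nrow(back), nrow(ev))
  expect_equal(back$date, ev$date)
  expect_equal(back$lon, ev$lon, tolerance = 1e-12)
  expect_equal(back$lat, ev$lat, tolerance = 1e-12)
  expect_equal(back$casualties, ev$casualties)
  expect_equal(nrow(attr(back, "rejected")), 0)
})

test_that("malformed event rows are rejected individually with reasons", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "date,lat,lon,casualties,title,url",
    "2011-03-07,25.71,-100.29,2,ok,u",
    "2011-03-08,,-100.29,1,missing lat,u",
    "not-a-date,25.71,-100.29,1,bad date,u",
    "2011-03-09,25.72,-100.28,1,ok,u"
  ), path)
  ev <- read_events(path)
  expect_equal(nrow(ev), 2)
  rej <- attr(ev, "rejected")
  expect_equal(rej$row, c(2, 3))
  expect_match(rej$reason[1], "coordinate")
  expect_match(rej$reason[2], "date")
})

test_that("missing required columns abort the read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,lat,casualties", "2011-01-05,25.7,1"), path)
  expect_error(read_events(path), "lon")
})

test_that("neighborhood GeoJSON round-trips", {
  g <- grid_city(3, 4, n_muni = 2)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_neighborhoods_geojson(g$city$nmap, path)
  back <- read_neighborhoods_geojson(path)
  expect_equal(back$id, g$city$nmap$id)
  expect_equal(back$municipality, g$city$nmap$municipality)
  expect_equal(back$area_km2, g$city$nmap$area_km2, tolerance = 1e-9)
})

test_that("highway GeoJSON round-trips and the OSM reader parses ways", {
  g <- grid_city(3, 3)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_highways_geojson(g$city$highways, path)
  back <- read_highways_geojson(path)
  expect_length(back, length(g$city$highways))
  expect_equal(back[[1]], g$city$highways[[1]], tolerance = 1e-12)

  osm <- withr::local_tempfile(fileext = ".osm")
  writeLines(c(
    '<?xml version="1.0"?>',
    "<osm>",
    ' <node id="1" lat="25.70" lon="-100.30"/>',
    ' <node id="2" lat="25.72" lon="-100.28"/>',
    ' <node id="3" lat="25.74" lon="-100.26"/>',
    ' <node id="4" lat="25.70" lon="-100.20"/>',
    ' <way id="10"><nd ref="1"/><nd ref="2"/><nd ref="3"/>',
    '  <tag k="highway" v="motorway"/></way>',
    ' <way id="11"><nd ref="1"/><nd ref="4"/>',
    '  <tag k="highway" v="residential"/></way>',
    ' <way id="12"><nd ref="2"/><nd ref="4"/></way>',
    "</osm>"
  ), osm)
  hw <- read_osm_highways(osm)
  expect_length(hw, 1)  # only the motorway way survives the type filter
  expect_equal(nrow(hw[[1]]), 3)
  expect_equal(hw[[1]][1, ], c(-100.30, 25.70))
})

test_that("map_events assigns interior points and drops exterior ones", {
  g <- grid_city(3, 3)
  nmap <- g$city$nmap
  ev <- data.frame(
    date = as.Date("2011-06-06") + 0:2,
    lon = c(nmap$centroid_lon[5], nmap$centroid_lon[1], -99.0),
    lat = c(nmap$centroid_lat[5], nmap$centroid_lat[1], 25.7),
    casualties = 1L
  )
  m <- map_events(ev, nmap)
  expect_equal(nrow(m), 2)
  expect_equal(m$neighborhood_id, nmap$id[c(5, 1)])
  expect_equal(attr(m, "n_dropped"), 1)
  expect_equal(attr(m, "dropped_rows"), 3L)
  expect_error(map_events(ev, nmap[0, ]), "empty")

  # idempotence: re-mapping a mapped table changes nothing
  m2 <- map_events(m, nmap)
  expect_equal(m2$neighborhood_id, m$neighborhood_id)
  expect_equal(attr(m2, "n_dropped"), 0)
})

test_that("synthetic events map back to their source neighborhood", {
  g <- grid_city(6, 6, n_muni = 3, base_rate = 0.5, n_weeks = 20, seed = 8)
  ev <- generate_events(g$city, g$cfg)
  m <- map_events(ev, g$city$nmap)
  expect_equal(attr(m, "n_dropped"), 0)
  expect_identical(m$neighborhood_id, attr(ev, "true_neighborhood"))
})

test_that("queen and rook contiguity match grid combinatorics", {
  g2 <- grid_city(2, 2)
  expect_equal(nrow(adjacency(g2$city$nmap)), grid_queen_pairs(2, 2))  # 6
  g3 <- grid_city(3, 3)
  adj <- adjacency(g3$city$nmap)
  expect_equal(nrow(adj), grid_queen_pairs(3, 3))
  center <- g3$city$nmap$id[5]
  expect_equal(sum(adj$id_a == center | adj$id_b == center), 8)
  rook <- adjacency(g3$city$nmap, mode = "rook")
  expect_equal(nrow(rook), grid_rook_pairs(3, 3))
  expect_equal(sum(rook$id_a == center | rook$id_b == center), 4)
})

test_that("disjoint polygons are not adjacent", {
  sq <- function(x0) rbind(c(x0, 25.7), c(x0 + 0.005, 25.7),
                           c(x0 + 0.005, 25.705), c(x0, 25.705), c(x0, 25.7))
  nmap <- neighborhood_map(
    c("a", "b"), c("M", "M"),
    list(list(sq(-100.3)), list(sq(-100.28)))  # ~2 km apart
  )
  expect_equal(nrow(adjacency(nmap)), 0)
})

test_that("centroid distances are haversine and satisfy the triangle inequality", {
  # two 1-degree-of-latitude separated squares at fixed longitude
  sq <- function(lat0) rbind(c(-100.3, lat0), c(-100.29, lat0),
                             c(-100.29, lat0 + 0.01), c(-100.3, lat0 + 0.01),
                             c(-100.3, lat0))
  nmap <- neighborhood_map(c("a", "b"), c("M", "M"),
                           list(list(sq(25.0)), list(sq(26.0))))
  d <- centroid_distance_km(nmap)
  expect_equal(d["M::a", "M::b"], 111.1951, tolerance = 1e-4)
  expect_equal(d["M::a", "M::a"], 0)

  g <- grid_city(5, 5)
  dm <- centroid_distance_km(g$city$nmap)
  expect_equal(dm, t(dm))
  n <- nrow(dm)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-9)
  }
})

test_that("polyline clipping keeps only in-box pieces", {
  bbox <- c(0, 0, 1, 1)
  line <- rbind(c(-1, 0.5), c(2, 0.5))  # crosses the box
  out <- clip_polyline_bbox(line, bbox)
  expect_length(out, 1)
  expect_equal(out[[1]], rbind(c(0, 0.5), c(1, 0.5)))
  expect_length(clip_polyline_bbox(rbind(c(-2, -2), c(-1, -1)), bbox), 0)
})
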