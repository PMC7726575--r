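mk_events <- function(dates, nb, muni = "M") {
  data.frame(
    date = as.Date(dates), lon = -100.3, lat = 25.7, casualties = 1L,
    neighborhood_id = nb, municipality = muni, stringsAsFactors = FALSE
  )
}

test_that("weight classes follow the 1-2 / 3-7 / 8+ scheme", {
  expect_equal(weight_class(c(1, 2)), c("grey", "grey"))
  expect_equal(weight_class(c(3, 5, 7)), c("blue", "blue", "blue"))
  expect_equal(weight_class(c(8, 12, 40)), c("red", "red", "red"))
  expect_error(weight_class(0), ">= 1")
})

test_that("a single violent neighborhood is an isolated node", {
  ev <- mk_events("2011-04-05", "M::a")
  g <- cooccurrence_network(ev, 2011)
  expect_equal(igraph::vcount(g), 1)
  expect_equal(igraph::ecount(g), 0)
})

test_that("shared active weeks set the edge weight", {
  # a and b both active in the weeks of Jan 17 and Feb 14 only
  ev <- mk_events(
    c("2011-01-17", "2011-01-18", "2011-02-14", "2011-02-15", "2011-03-01"),
    c("M::a", "M::b", "M::a", "M::b", "M::a")
  )
  g <- cooccurrence_network(ev, 2011)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 2)
  expect_equal(igraph::E(g)$class, "grey")

  # presence-based: multiple same-week events still count one co-occurrence
  ev2 <- rbind(ev, mk_events(c("2011-01-19", "2011-01-19"), c("M::a", "M::b")))
  g2 <- cooccurrence_network(ev2, 2011)
  expect_equal(igraph::E(g2)$weight, 2)
})

test_that("co-occurrence weights equal the set-intersection oracle", {
  g <- grid_city(5, 5, n_muni = 2, base_rate = 0.5, n_weeks = 40, seed = 23)
  ev <- map_events(generate_events(g$city, g$cfg), g$city$nmap)
  anchor <- week_anchor(min(ev$date))
  net <- cooccurrence_network(ev, 2011, anchor = anchor)
  # restrict the oracle to weeks whose Monday lies in 2011 (as the builder does)
  wk <- week_index(ev$date, anchor)
  in_year <- format(anchor + 7 * wk, "%Y") == "2011"
  want <- oracle_cooc_weights(ev[in_year, ], anchor)
  el <- igraph::as_data_frame(net, what = "edges")
  got <- setNames(as.list(el$weight), paste(pmin(el$from, el$to),
                                            pmax(el$from, el$to), sep = "|"))
  expect_equal(length(got), length(want))
  for (k in names(want)) expect_equal(got[[k]], want[[k]], label = k)
})

test_that("planted pairs are recovered exactly when background rate is zero", {
  g <- grid_city(4, 4, base_rate = 0, n_weeks = 30, seed = 2,
                 planted_pairs = list(c(2, 15, 5), c(2, 9, 2)))
  ev <- map_events(generate_events(g$city, g$cfg), g$city$nmap)
  net <- cooccurrence_network(ev, 2011, anchor = g$cfg$start_date)
  el <- igraph::as_data_frame(net, what = "edges")
  expect_equal(nrow(el), 2)
  id <- g$city$nmap$id
  key <- paste(pmin(el$from, el$to), pmax(el$from, el$to))
  w <- setNames(el$weight, key)
  expect_equal(unname(w[paste(min(id[2], id[15]), max(id[2], id[15]))]), 5)
  expect_equal(unname(w[paste(min(id[2], id[9]), max(id[2], id[9]))]), 2)
})

test_that("the adjacent-only variant drops non-contiguous edges", {
  g <- grid_city(3, 3)
  id <- g$city$nmap$id
  # cells 1 and 9 are opposite corners (not adjacent); 1 and 2 are adjacent
  ev <- mk_events(rep("2011-05-03", 3), id[c(1, 9, 2)])
  adj <- adjacency(g$city$nmap)
  full <- cooccurrence_network(ev, 2011)
  expect_equal(igraph::ecount(full), 3)
  restricted <- cooccurrence_network(ev, 2011, adjacent_only = TRUE, adj = adj)
  el <- igraph::as_data_frame(restricted, what = "edges")
  expect_equal(nrow(el), 1)  # only (1,2) is a contiguous pair
  expect_setequal(c(el$from, el$to), id[c(1, 2)])
})

test_that("crime network equals the contiguity graph when all cells are violent", {
  g <- grid_city(3, 3, base_rate = 5, n_weeks = 4, seed = 12)
  ev <- map_events(generate_events(g$city, g$cfg), g$city$nmap)
  expect_equal(length(unique(ev$neighborhood_id)), 9)
  cn <- crime_network(ev, g$city$nmap)
  expect_equal(igraph::vcount(cn), 9)
  expect_equal(igraph::ecount(cn), grid_queen_pairs(3, 3))
  expect_equal(igraph::components(cn)$no, 1)
})

test_that("crime network edges respect the adjacency predicate and components add up", {
  g <- grid_city(5, 5, n_muni = 2, base_rate = 0.3, n_weeks = 20, seed = 19)
  ev <- map_events(generate_events(g$city, g$cfg), g$city$nmap)
  adj <- adjacency(g$city$nmap)
  cn <- crime_network(ev, g$city$nmap, adj = adj)
  el <- igraph::as_data_frame(cn, what = "edges")
  adj_key <- paste(adj$id_a, adj$id_b)
  expect_true(all(paste(pmin(el$from, el$to), pmax(el$from, el$to)) %in% adj_key))

  tab <- igraph::graph_attr(cn, "components")
  expect_equal(sum(tab$n_neighborhoods), igraph::vcount(cn))
  expect_equal(sum(tab$n_edges), igraph::ecount(cn))

  # components match a union-find oracle
  comp <- oracle_components(igraph::V(cn)$name, as.matrix(el[, 1:2]))
  expect_equal(length(unique(comp)), nrow(tab))
})

test_that("an event-free middle row splits the grid into two equal sectors", {
  g <- grid_city(5, 5, base_rate = 0, n_weeks = 10, seed = 3)
  # place one event in every cell except row 3 (cells 11..15)
  keep <- setdiff(1:25, 11:15)
  ev <- mk_events(rep("2011-02-01", length(keep)), g$city$nmap$id[keep],
                  muni = g$city$nmap$municipality[keep])
  cn <- crime_network(ev, g$city$nmap)
  tab <- igraph::graph_attr(cn, "components")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$n_neighborhoods, c(10, 10))
})

test_that("component composition finds the modal municipality", {
  g <- grid_city(2, 2, n_muni = 2)
  nmap <- g$city$nmap
  cc <- component_composition(nmap$id, nmap)
  expect_equal(cc$count_in_main, 2L)
  expect_equal(cc$proportion, 0.5)
  expect_true(cc$tie)
  expect_equal(cc$main_municipality, "M01")  # lexicographic tie-break

  # 3-of-4 majority
  nmap2 <- grid_city(2, 2)$city$nmap
  nmap2$municipality <- c("X", "X", "X", "Y")
  cc2 <- component_composition(nmap2$id, nmap2)
  expect_equal(cc2$main_municipality, "X")
  expect_equal(cc2$count_in_main, 3L)
  expect_equal(cc2$proportion, 0.75)
  expect_false(cc2$tie)

  # random labels against a brute-force mode count
  set.seed(9)
  nmap3 <- grid_city(5, 10)$city$nmap
  nmap3$municipality <- sample(LETTERS[1:4], 50, replace = TRUE)
  nmap3$id <- paste0(nmap3$municipality, "::", nmap3$name)
  cc3 <- component_composition(nmap3$id, nmap3)
  tab <- sort(table(nmap3$municipality), decreasing = TRUE)
  expect_equal(cc3$count_in_main, as.integer(tab[1]))
})

test_that("the main-component flag is strict at more than 10 edges", {
  # 1 x n row grids: a path of n violent cells has n-1 edges
  for (spec in list(list(n = 11, main = FALSE), list(n = 12, main = TRUE))) {
    g <- grid_city(1, spec$n)
    ev <- mk_events(rep("2011-06-07", spec$n), g$city$nmap$id,
                    muni = g$city$nmap$municipality)
    cn <- crime_network(ev, g$city$nmap)
    tab <- igraph::graph_attr(cn, "components")
    expect_equal(tab$n_edges, spec$n - 1)
    expect_equal(tab$main, spec$main)
  }
})

test_that("networks export to GraphML and edge-list CSV", {
  g <- grid_city(3, 3, base_rate = 2, n_weeks = 6, seed = 4)
  ev <- map_events(generate_events(g$city, g$cfg), g$city$nmap)
  net <- cooccurrence_network(ev, 2011)
  gml <- withr::local_tempfile(fileext = ".graphml")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_network(net, graphml_path = gml, edgelist_path = csv)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(net))
  expect_equal(igraph::ecount(back), igraph::ecount(net))
  el <- read.csv(csv)
  expect_equal(nrow(el), igraph::ecount(net))
  expect_true(all(c("from", "to", "weight", "class") %in% names(el)))
})
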