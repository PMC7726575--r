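# Two network constructions over violent neighborhoods: yearly same-week
# co-occurrence networks, and the whole-period contiguity crime network with
# its connected components.

#' Co-occurrence weight classes
#'
#' Edge weights (number of shared active weeks within a year) are classed as
#' `"grey"` (1-2 co-occurrences), `"blue"` (3-7) or `"red"` (8 or more; the
#' class is open-ended upward).
#'
#' @param weight integer vector of weights (>= 1).
#' @return character vector of class labels.
#' @export
weight_class <- function(weight) {
  if (any(weight < 1)) stop("co-occurrence weights must be >= 1")
  ifelse(weight >= 8, "red", ifelse(weight >= 3, "blue", "grey"))
}

#' Yearly same-week co-occurrence network
#'
#' For each Monday-anchored week whose Monday falls in `year`, every
#' unordered pair of distinct neighborhoods that both record at least one
#' event that week gains +1 edge weight (presence-based: multiple events in a
#' week still contribute one co-occurrence). Nodes are all neighborhoods with
#' at least one event in the year's weeks, including isolated ones.
#'
#' By default pairs are counted regardless of adjacency; `adjacent_only`
#' restricts edges to contiguous polygon pairs (requires `adj`).
#'
#' @param events mapped event data.frame.
#' @param year calendar year.
#' @param anchor optional anchor Monday (defaults to the Monday on-or-before
#'   the first event).
#' @param adjacent_only if `TRUE`, keep only edges between adjacent polygons.
#' @param adj adjacency pair data.frame from [adjacency()] (only used with
#'   `adjacent_only`).
#' @return undirected `igraph` with vertex attributes `name`, `n_events`, and
#'   edge attributes `weight`, `class`; graph attribute `year`.
#' @export
cooccurrence_network <- function(events, year, anchor = NULL,
                                 adjacent_only = FALSE, adj = NULL) {
  if (is.null(events$neighborhood_id)) stop("events must be mapped first")
  if (nrow(events) > 0) {
    yrs <- as.integer(format(events$date, "%Y"))
    if (!(year %in% yrs)) stop("no events in year ", year)
  }
  if (is.null(anchor)) anchor <- week_anchor(min(events$date))
  wk <- week_index(events$date, anchor)
  wk_monday <- anchor + 7 * wk
  in_year <- as.integer(format(wk_monday, "%Y")) == year
  ev <- events[in_year, , drop = FALSE]
  wk <- wk[in_year]

  nodes <- sort(unique(ev$neighborhood_id))
  n_events <- as.integer(table(factor(ev$neighborhood_id, levels = nodes)))

  # per week, the set of active neighborhoods; accumulate pair counts
  pair_count <- new.env(parent = emptyenv())
  for (w in unique(wk)) {
    active <- sort(unique(ev$neighborhood_id[wk == w]))
    if (length(active) < 2) next
    cmb <- utils::combn(active, 2)
    keys <- paste(cmb[1, ], cmb[2, ], sep = "\r")
    for (key in keys) {
      pair_count[[key]] <- (if (is.null(pair_count[[key]])) 0L else pair_count[[key]]) + 1L
    }
  }
  keys <- ls(pair_count)
  if (length(keys) > 0) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    edges <- data.frame(
      from = vapply(parts, `[`, "", 1),
      to = vapply(parts, `[`, "", 2),
      weight = vapply(keys, function(k) pair_count[[k]], integer(1)),
      stringsAsFactors = FALSE
    )
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0), weight = integer(0))
  }

  if (adjacent_only) {
    if (is.null(adj)) stop("adjacent_only requires an adjacency pair table")
    adj_key <- paste(pmin(adj$id_a, adj$id_b), pmax(adj$id_a, adj$id_b))
    edges <- edges[paste(edges$from, edges$to) %in% adj_key, , drop = FALSE]
  }

  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, n_events = n_events, stringsAsFactors = FALSE)
  )
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$class <- weight_class(igraph::E(g)$weight)
  }
  g <- igraph::set_graph_attr(g, "year", year)
  g
}

#' Whole-period contiguity crime network
#'
#' Nodes are neighborhoods with at least one event inside `window`; an edge
#' joins two nodes iff their polygons are adjacent. Connected components are
#' the "crime sectors"; components with strictly more than 10 edges are
#' flagged as main components.
#'
#' @param events mapped event data.frame.
#' @param nmap a [neighborhood_map()].
#' @param window optional length-2 Date vector; default is the full event
#'   range.
#' @param adj optional precomputed [adjacency()] table (queen by default).
#' @return undirected `igraph`; vertex attributes `name`, `municipality`,
#'   `n_events`, `component`; graph attribute `components`, the composition
#'   table from [component_table()].
#' @export
crime_network <- function(events, nmap, window = NULL, adj = NULL) {
  if (is.null(events$neighborhood_id)) stop("events must be mapped first")
  ev <- events
  if (!is.null(window)) {
    window <- as.Date(window)
    ev <- ev[ev$date >= window[1] & ev$date <= window[2], , drop = FALSE]
  }
  violent <- sort(unique(ev$neighborhood_id))
  if (is.null(adj)) adj <- adjacency(nmap)
  keep <- adj$id_a %in% violent & adj$id_b %in% violent
  edges <- adj[keep, , drop = FALSE]

  n_events <- as.integer(table(factor(ev$neighborhood_id, levels = violent)))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(
      name = violent,
      municipality = nmap$municipality[match(violent, nmap$id)],
      n_events = n_events,
      stringsAsFactors = FALSE
    )
  )
  comp <- igraph::components(g)
  igraph::V(g)$component <- comp$membership
  g <- igraph::set_graph_attr(g, "components", component_table(g, nmap))
  g
}

#' Majority municipality of one component
#'
#' @param ids character vector of neighborhood ids in the component.
#' @param nmap a [neighborhood_map()].
#' @return list with `main_municipality` (modal municipality, lexicographic
#'   tie-break), `count_in_main`, `proportion` (count / component size) and
#'   `tie` (logical).
#' @export
component_composition <- function(ids, nmap) {
  if (length(ids) == 0) stop("empty component")
  muni <- nmap$municipality[match(ids, nmap$id)]
  tab <- table(muni)
  best <- max(tab)
  winners <- sort(names(tab)[tab == best])
  list(
    main_municipality = winners[1],
    count_in_main = as.integer(best),
    proportion = as.numeric(best) / length(ids),
    tie = length(winners) > 1
  )
}

#' Component composition table of a crime network
#'
#' One row per connected component, largest first: size, edge count, modal
#' municipality with its count and proportion, and the main-component flag
#' (`n_edges > 10`, strict).
#'
#' @param g a [crime_network()] graph.
#' @param nmap a [neighborhood_map()].
#' @return data.frame (`component`, `n_neighborhoods`, `n_edges`,
#'   `main_municipality`, `count_in_main`, `proportion`, `main`).
#' @export
component_table <- function(g, nmap) {
  comp <- igraph::components(g)
  if (comp$no == 0) {
    return(data.frame(
      component = integer(0), n_neighborhoods = integer(0), n_edges = integer(0),
      main_municipality = character(0), count_in_main = integer(0),
      proportion = numeric(0), main = logical(0), stringsAsFactors = FALSE
    ))
  }
  rows <- lapply(seq_len(comp$no), function(k) {
    ids <- igraph::V(g)$name[comp$membership == k]
    sub <- igraph::induced_subgraph(g, ids)
    cc <- component_composition(ids, nmap)
    data.frame(
      component = k,
      n_neighborhoods = length(ids),
      n_edges = igraph::ecount(sub),
      main_municipality = cc$main_municipality,
      count_in_main = cc$count_in_main,
      proportion = cc$proportion,
      main = igraph::ecount(sub) > 10,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_neighborhoods, out$component), , drop = FALSE]
  out$component <- seq_len(nrow(out))  # rank components by size
  rownames(out) <- NULL
  out
}

#' Export a network as GraphML and edge-list CSV
#'
#' @param g an `igraph` from [cooccurrence_network()] or [crime_network()].
#' @param graphml_path path for GraphML output (`NULL` to skip).
#' @param edgelist_path path for edge-list CSV (`NULL` to skip); columns
#'   `from`, `to` plus any edge attributes.
#' @export
write_network <- function(g, graphml_path = NULL, edgelist_path = NULL) {
  if (!is.null(graphml_path)) {
    g2 <- g  # GraphML cannot carry table-valued graph attributes
    for (a in igraph::graph_attr_names(g2)) {
      if (!is.atomic(igraph::graph_attr(g2, a)) ||
          length(igraph::graph_attr(g2, a)) != 1) {
        g2 <- igraph::delete_graph_attr(g2, a)
      }
    }
    igraph::write_graph(g2, graphml_path, format = "graphml")
  }
  if (!is.null(edgelist_path)) {
    el <- igraph::as_data_frame(g, what = "edges")
    utils::write.csv(el, edgelist_path, row.names = FALSE)
  }
  invisible(g)
}
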