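# homnet

Spatio-temporal network analysis of geolocated violent-event records in a
metropolitan area.

## The problem

City-scale homicide data — one dated, geolocated record per event — invites
questions that sit between time-series analysis and spatial statistics: do
municipalities rise and fall together? Is violence spatially correlated at
the neighborhood scale, and over what distances? Do pairs of neighborhoods
flare up in the *same week*, suggesting coordinated or retaliatory dynamics,
even when they are far apart? Do contiguous blocks of violent neighborhoods
("crime sectors") align with administrative borders? And does the road
network structure where events happen?

`homnet` implements an end-to-end pipeline for these questions, for analysts
working with an event table (date, latitude, longitude, casualties), a
neighborhood polygon layer, municipal populations, and highway polylines:

1. **Event mapping** — point-in-polygon assignment of events to
   neighborhoods (`map_events()`), polygon contiguity under queen or rook
   rules (`adjacency()`), spherical centroid distances.
2. **Municipal correlation** — weekly casualty series per municipality
   (`weekly_aggregate()`, Monday-anchored bins), all pairwise Pearson
   correlation coefficients, and a permutation null: each municipality's
   weekly vector is independently reshuffled (1000 iterations by default)
   and each observed PCC is scored as
   `Z = (PCC − null mean) / null sd`, with `Z > 3` flagged significant
   (`null_zscores()`).
3. **Spatial correlation** — for year *t* and distance bin *r*,

   `G(t, r) = Σ_{(i,j)∈N, i≠j} (h_i − μ)(h_j − μ) / (|N| σ²)`

   where `h_k` is the per-capita count of neighborhood *k*, `μ` and `σ²`
   are the mean and (population) variance of `h` over **all** neighborhoods,
   and `N` is the set of unordered neighborhood pairs whose centroid
   distance falls in bin *r*. Because neighborhood populations are typically
   unavailable, the per-capita denominator is the proxy `A_i · P_m`
   (neighborhood area × municipal population). Bins are the 0.05-quantile
   steps of the pairwise-distance distribution — 20 intervals
   (`spatial_curve()`, `spatial_G()`, `quantile_bins()`).
4. **Co-occurrence networks** — per year, neighborhoods are linked with
   weight equal to the number of distinct weeks in which **both** had at
   least one event (presence-based, any distance); weights are classed
   grey (1–2), blue (3–7), red (8+) (`cooccurrence_network()`,
   `weight_class()`).
5. **Crime network** — over the whole period, violent neighborhoods are
   linked iff their polygons are adjacent; connected components are the
   crime sectors, a component with more than 10 edges is a *main* component,
   and each component is summarised by its modal municipality and the
   proportion of member neighborhoods in it (`crime_network()`,
   `component_table()`).
6. **Highway proximity** — per-event distance to the nearest highway
   polyline and the yearly 99th percentile (linear interpolation between
   order statistics; `p99_by_year()`).

A first-class **synthetic city generator** (`city_config()`,
`generate_city()`, `generate_events()`) produces all four input layers with
known structure — gridded neighborhoods in contiguous municipalities,
per-neighborhood Poisson rates with planted hotspots and temporal waves,
planted same-week co-occurring pairs, and a highway-biased event fraction —
so the entire pipeline is testable without any external data.

## Worked example

```r
library(homnet)

cfg <- city_config(n_rows = 8, n_cols = 8, n_municipalities = 3,
                   populations = c(900000, 400000, 150000),
                   base_rate = 0.04, hotspot_ids = c(28, 36), hotspot_multiplier = 8,
                   planted_pairs = list(c(1, 64, 6)),
                   highway_bias = 0.4, n_weeks = 104, seed = 42)
city   <- generate_city(cfg)
events <- generate_events(city, cfg)
mapped <- map_events(events, city$nmap)

wc <- weekly_aggregate(mapped)
head(null_zscores(wc, n_iter = 1000, seed = 42), 3)
#>   municipality_1 municipality_2      pcc null_mean null_sd        z significant
#> 1            M01            M02  0.05937 -0.000998  0.0955  0.63179       FALSE
#> 2            M01            M03  0.05913 -0.000852  0.0985  0.60915       FALSE
#> 3            M02            M03 -0.00404 -0.003359  0.0986 -0.00693       FALSE
```

Three weakly coupled municipalities: the Z-scores place each observed PCC
well inside its reshuffling null, so no pair is flagged.

```r
head(spatial_curve(mapped, city$nmap, city$pops, 2011), 3)
#>   year r_lo_km r_hi_km n_pairs      G
#> 1 2011   0.999    1.00      64 0.2543
#> 2 2011   1.000    1.41     138 0.3968
#> 3 2011   1.414    2.00      72 0.0492
```

Positive `G` in the shortest-distance bins: the planted hotspots and the
highway-biased corridor make nearby neighborhoods covary; beyond ~2 km the
correlation decays toward noise.

```r
net <- cooccurrence_network(mapped, 2011)
el  <- igraph::as_data_frame(net, "edges")
head(el[order(-el$weight), ], 3)
#>          from         to weight class
#>    M01::N0019 M02::N0028      6  blue
#>    M01::N0001 M02::N0028      4  blue
#>    M01::N0001 M02::N0036      4  blue
```

The heaviest same-week pairs join the highway-corridor cells and the planted
hotspots — co-occurrence weight counts shared active weeks, not geographic
closeness.

```r
cn <- crime_network(mapped, city$nmap)
igraph::graph_attr(cn, "components")
#>   component n_neighborhoods n_edges main_municipality count_in_main proportion main
#> 1         1              61     189               M03            23       0.38 TRUE

p99_by_year(mapped, city$highways)
#>   year n_events  p99_m
#> 1 2011      182 4966.3
#> 2 2012      196 4721.8
```

With events nearly everywhere, the contiguity network is one main sector
spanning 61 of 64 neighborhoods; the yearly 99th-percentile distance to the
highway summarises how tightly events hug the road (here ~5 km in an 8 km
city, because only 40% of the stream is road-biased).

The same stages run from one call — `run_all(run_config(city = cfg), "out/")`
— which also writes every table, the GraphML networks, and a JSON manifest;
`inst/scripts/homnet-cli.R` exposes the stages as shell subcommands
(`synth`, `map`, `correlate`, `spatial`, `networks`, `highways`, `run-all`).

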