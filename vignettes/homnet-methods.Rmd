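---
title: "Methods: spatio-temporal analysis of geolocated violent events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatio-temporal analysis of geolocated violent events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homnet)
```

`homnet` analyses an event table — one dated, geolocated casualty record per
row — against three geographic layers: a neighborhood polygon tessellation,
municipal populations, and highway polylines. This vignette documents the
statistical procedures, the parameters that matter, the numerical and design
choices where several conventions were defensible, and what the synthetic
generator does and does not emulate.

## Event mapping and contiguity

Events are assigned to neighborhoods by point-in-polygon (`map_events()`);
events outside every polygon are dropped and counted, which doubles as an
urban-area filter. A point lying exactly on a shared boundary is assigned to
the containing polygon whose id sorts first — an arbitrary but deterministic
tie-break. Boundary hits have probability zero under the continuous
coordinate distributions the generator uses, so the rule only matters for
hand-crafted inputs.

Contiguity (`adjacency()`) defaults to **queen** semantics: two polygons are
adjacent iff their boundaries share at least one point, which matches the
"touches" predicate of the common geospatial stacks. A `mode = "rook"`
switch additionally requires a shared border of positive length, excluding
corner-only contacts. Geometrically, the test is the minimum distance
between boundary segment pairs in a local projection, with a 1 m tolerance
to absorb coordinate noise in digitised shapefiles; on the synthetic grids
shared vertices are exact and the tolerance is irrelevant.

Distances between neighborhoods are great-circle (haversine, mean Earth
radius 6371.0088 km) between polygon **centroids**; "the distance between
two neighborhoods" has no canonical definition, and centroids are the
standard representative-point choice at metropolitan scale. Where planar
geometry is needed (point-to-segment distances, polygon areas) we use a
local equirectangular projection centred on the data bounding box: for a
study area spanning under 1.5 degrees the projection error is orders of
magnitude below the reported precision, and the convention is part of the
method definition (the dense-sampling oracle in the test suite shares it).

## Weekly municipal correlation

Weekly bins are consecutive 7-day intervals anchored at the **Monday
on-or-before the window start** (ISO convention). The anchor is a genuine
free choice — nothing in the data fixes it — so we document one and use it
everywhere (aggregation, co-occurrence weeks, yearly network assignment: a
week belongs to the calendar year containing its Monday).

`weekly_aggregate()` sums **casualties** by default (an event with three
victims contributes three), with `measure = "events"` as a switch.
`rate_per_100k()` rescales by `1e5 / P_m`; since Pearson correlation is
invariant under per-series affine maps, raw counts and per-100k rates give
identical correlation tables — the scaling matters only for display.

Significance uses a permutation null (`null_zscores()`): in each of
`n_iter = 1000` iterations every municipality's weekly vector is
independently reshuffled across weeks, the full PCC matrix is recomputed,
and each pair's observed PCC is scored as `Z = (PCC − mean) / sd` of its
null sample, flagging `Z > 3`. Two caveats are deliberate features of this
design rather than oversights:

* the reshuffle destroys autocorrelation as well as cross-correlation, so
  for strongly autocorrelated series the null is narrower than an
  autocorrelation-preserving (block or rotation) null and Z-scores are
  anti-conservative. Block nulls are a documented extension point, not
  implemented;
* pairs with a zero-variance series have undefined correlation and are
  reported as missing (`NA`), never coerced to zero.

Under independent series the Z-scores are approximately standard normal;
the test suite checks mean, spread, and the `|Z| > 3` tail rate over 500
simulated Poisson pairs of length 300 weeks with the full 1000 iterations.

## Spatial correlation

For a year $t$ and a set $N$ of unordered neighborhood pairs within a
distance interval $r$,

$$G(t, r) = \sum_{(i,j) \in N,\; i \ne j} \frac{(h_i - \mu)(h_j - \mu)}{|N|\,\sigma^2},$$

where $h_k$ is the per-capita count of neighborhood $k$ and $\mu, \sigma^2$
are the mean and variance of $h$. The implementation reads the moments as
**global** — over all neighborhoods with a valid denominator, including
zero-event ones — because the statistic is meant to compare a bin's pairs
against the city-wide field; an `active_only` flag restricts to event-bearing
neighborhoods as a sensitivity variant. $\sigma^2$ is the population
(divide-by-$n$) variance. With these conventions an exact identity holds:
summing $(h_i-\mu)(h_j-\mu)$ over *all* unordered pairs gives
$-\tfrac12\sum_k (h_k-\mu)^2$, so the binned values must satisfy
$\sum_b |N_b| G_b = -n/2$ to numerical precision. The suite enforces this at
`1e-10`; it is a strong global check that the binning partitions the pairs
and the normalisation is consistent. Two further closed forms are tested:
any two-neighborhood configuration gives $G = -1$ exactly, and $G$ is
invariant under positive affine transforms of $h$.

Per-capita denominators use the proxy $A_i \cdot P_m$ (neighborhood area in
km² times municipal population) — taken literally, units km²·persons. An
alternative reading allocates population by area share,
$(A_i / \sum_{k \in m} A_k) \cdot P_m$, restoring person units; both are
implemented (`percapita_proxy(mode = "area_fraction")`), the literal product
is the default. Since $G$ only uses $h$ through centred, variance-scaled
terms, any municipality-constant factor difference between the two modes
affects results only when municipalities differ — which is exactly why both
modes are kept available.

Distance bins are quantile bins: edges at the $0, 0.05, \ldots, 1$ quantiles
of the pairwise centroid-distance distribution, i.e. 20 intervals with equal
pair counts, half-open $[lo, hi)$ with the last closed. Duplicated edges
(heavily tied distances) are an error rather than silently merged bins —
with fewer than 20 distinct quantiles the statistic's resolution claim would
be false.

## The two network constructions

**Same-week co-occurrence (yearly).** For each week, every unordered pair
of distinct neighborhoods that *both* record at least one event gains +1
weight. The count is presence-based: a week with three events in one
neighborhood and two in the other contributes one co-occurrence, not six —
the weight is exactly the size of the intersection of the two
neighborhoods' active-week sets, which the suite verifies against an
independent set-intersection oracle. Weights are classed grey (1–2),
blue (3–7), red (8 and above); the red class is open-ended upward.
Co-occurrence deliberately ignores adjacency — its purpose is to surface
temporal coupling at *any* distance — but `adjacent_only = TRUE` offers the
restricted variant for users who want spatially-local same-week counting.

**Contiguity crime network (whole period).** Nodes are neighborhoods with
at least one event in the window; edges join adjacent violent
neighborhoods. Connected components are the crime sectors; a component with
strictly more than 10 edges is flagged a *main* component (the suite checks
the boundary with path components of exactly 10 and 11 edges). Each
component is summarised by its modal municipality, the modal count, and the
proportion of member neighborhoods in it; modal ties are broken
lexicographically and flagged.

## Highway proximity

Per-event distance to the nearest highway polyline is the minimum over all
segments of the point-to-segment distance in the local projection. The
yearly summary is the 99th percentile — chosen over the maximum to ignore
outliers — computed by linear interpolation between order statistics (R
quantile type 7); a nearest-rank option exists, and the two differ by under
a metre at a few hundred events. Which OSM way classes count as "highway"
is configurable; the default keeps `motorway`, `trunk`, `primary`. The
OSM-XML reader handles plain Overpass exports (nodes, ways, `highway`
tags) and clips ways to the configured bounding box.

## The synthetic city

The generator emulates the statistical structure the analysis assumes:

* a gap-free `n_rows × n_cols` grid of square cells (default 10 × 10,
  1 km side) near (−100.3, 25.7), so projection and spherical-distance code
  paths run at a realistic latitude. A grid — rather than, say, a Voronoi
  tessellation — makes contiguity analytically known, so adjacency tests
  are exact rather than approximate;
* municipalities as contiguous column blocks (default 4) with configurable
  populations (default 100 000 each);
* event counts per neighborhood-week drawn Poisson with rate
  `base_rate × hotspot_multiplier × wave(week)`. Defaults: base rate
  0.05 events/neighborhood/week — small enough that most neighborhoods are
  quiet in any week, as in real homicide data — hotspot multiplier 8, flat
  wave;
* planted same-week pairs: each pair `(a, b, n)` is forced to have both
  members active in `n` distinct weeks, with week sets **disjoint across
  all planted pairs**. Disjointness is what makes recovery exact: if two
  pairs sharing neighborhood `a` used a common week, the other two members
  would co-occur in that week and a spurious edge would appear;
* highway bias: a configured fraction of events is relocated uniformly
  within `d_h` (default 0.5 km) of the highway, rejection-sampled to stay
  inside the tessellation. Note the 99th percentile of a 90%-biased stream
  sits near the *90th* percentile of the unbiased field — bias compresses
  the bulk, and only drives p99 itself to the corridor scale as the biased
  fraction approaches 1;
* casualties default to exactly 1 per event; a zero-truncated geometric
  hook exists because multi-victim events occur in real data, but the
  casualty distribution is not a modelled quantity.

One seed drives everything; stages derive sub-seeds deterministically, and
generation restores the caller's RNG state. Identical configs produce
byte-identical written artifacts.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: irregular polygon shapes and sliver boundaries
(grid adjacency is exact; digitised shapefiles need the metre-level
tolerance), heavy-tailed and autocorrelated event streams (the permutation
null's anti-conservatism under autocorrelation is invisible on Poisson
streams), duplicate neighborhood names and broken geometries, and any form
of population heterogeneity *within* municipalities.

## Problem sizes and determinism

The test suite runs grids between 2 × 2 and 10 × 10 and series up to 372
weeks; the calibration checks use 500 pairs × 1000 permutations of
300-week series, and the acceptance script's pipeline run uses a 10 × 10
city over 372 weekly bins (comparable to an 86-month study window). These
sizes were chosen so each statistical check has enough replication to be
sharp while the whole suite stays fast enough to run habitually. All
stochastic tests fix seeds; the pipeline writes a config hash and seed into
its manifest so any run can be reproduced exactly.

## Known limitations

* The permutation null is exchangeable-weeks; block/rotation nulls that
  preserve autocorrelation are an extension point.
* Component analysis stops at connected components; no community detection.
* Distances are centroid-to-centroid and straight-line; no along-network
  distances.
* Multi-part (MultiPolygon) neighborhoods with more than one part are not
  supported by the GeoJSON reader.
* Edge direction in co-occurrence networks is unknowable from event data
  alone (no offender/victim attribution), so all graphs are undirected.
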