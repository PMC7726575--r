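Package: homnet
Title: Spatio-Temporal Network Analysis of Geolocated Homicide Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the spatio-temporal analysis of geolocated violent-event
    records in a metropolitan area tessellated into neighborhood polygons.
    Maps point events to neighborhoods, builds weekly municipal casualty
    series and scores their Pearson correlations against a permutation null,
    computes a distance-binned spatial correlation statistic over
    neighborhood pairs, constructs yearly same-week co-occurrence networks
    and whole-period contiguity crime networks with connected-component
    composition, and summarises event-to-highway distances by yearly upper
    percentiles. Includes a synthetic-city generator (gridded neighborhoods,
    inhomogeneous Poisson event streams with planted hotspots, waves,
    co-occurring pairs and highway bias) so the entire pipeline is testable
    without external downloads, plus readers and writers for the standard
    interchange formats (CSV events, GeoJSON polygons and polylines, minimal
    OSM XML).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    igraph,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
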