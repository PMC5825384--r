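Package: protconn
Title: Protected Area Connectivity Indicators (ProtConn Family)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates how well a country's terrestrial protected-area (PA)
    system is designed for connectivity. Builds a probabilistic spatial graph
    of PA polygons (negative-exponential dispersal kernel calibrated to
    probability 0.5 at the median dispersal distance, maximum-product
    dispersal paths, Equivalent Connected Area) and computes the Protected
    Connected indicator family: Prot, ProtConn, ProtConn_Bound, the
    partition of protected-but-unconnected land by cause (sea, foreign land,
    PA-system design) and the four ProtConn fractions (Within, Contig,
    Unprot, Trans). Includes a synthetic-scenario generator with analytically
    known indicator values, area-weighted regional aggregation, and the
    priority classification of countries (A1/A2/B1/B2/B3/C) against a
    coverage-and-connectivity target such as Aichi Target 11 (17%).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
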