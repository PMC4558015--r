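Package: csaccess
Title: Location-Allocation Analysis of Free Caesarean-Section Service Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates village-level demand for emergency obstetric care
    (obstetric bed-days derived from population and block-level crude birth
    rates), facility-level supply (obstetric beds times 365), road-network
    catchments at a configurable distance cutoff, and optimal placement of
    additional free caesarean-section centres by incremental (greedy)
    maximal-coverage selection with capacity classification.  Includes a
    synthetic health-geography generator (villages, blocks, road network,
    facilities) so the whole pipeline is testable without external data,
    plus serialization to GeoJSON/CSV and district summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
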