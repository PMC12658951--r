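Package: seaconn
Title: Seascape Connectivity, Vulnerability to Isolation, and Marine
    Protected Area Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Graph-based seascape connectivity modelling and systematic
    conservation planning for coastal species that disperse actively over
    water. Builds least-cost traversal graphs over raster seascapes (land
    is impassable, anthropogenic disturbance lowers conductance), evaluates
    negative-exponential dispersal kernels between habitat cells, assembles
    per-species connectivity matrices and their multi-generation powers,
    quantifies habitat vulnerability to isolation as the loss of
    connectivity imports under disturbance, assesses marine protected area
    (MPA) networks against random-allocation expectation, and ranks
    candidate cells for MPA expansion with a budgeted minimum-shortfall
    greedy selection. Includes a seeded synthetic-archipelago generator so
    the full workflow runs end-to-end without external spatial data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    mgcv,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
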