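Package: dagmap
Type: Package
Title: Consensus Genetic Linkage Maps via Directed Acyclic Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Integrates genetic linkage maps from multiple mapping
    populations into a consensus directed graph whose vertices are marker
    bins, detects marker-order conflicts as strongly connected components,
    simplifies conflict-free graphs to a minimal ordinally equivalent DAG
    (transitive edge reduction plus vertex coalescing), and linearizes the
    graph into a consensus map by weighted L1 (linear programming) or L2
    (quadratic programming) minimization of the deviation from the component
    maps under marker-order constraints. Includes a doubled-haploid
    simulation framework (Poisson crossovers without interference, Haldane's
    mapping function, LOD-weighted least-squares map estimation) for
    evaluating consensus-map accuracy, and a bundled worked example from the
    barley 5HS telomere region.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    quadprog,
    stats,
    utils
Suggests:
    igraph,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
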