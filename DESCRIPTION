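Package: restraintr
Title: Automated Selection of Inter-Molecular Distance Restraints for
    Linked Dual-Topology Free-Energy Calculations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects optimal inter-molecular distance restraints between
    pre-aligned small molecules for linked dual-topology alchemical
    free-energy calculations. Candidate restraints are cross-molecule
    ring-atom pairs within a distance cutoff; a greedy max-min dispersion
    scheme on the graph of restraint midpoints picks a well-spread,
    atom-disjoint subset. Includes exhaustive brute-force reference
    selectors (maximum summed midpoint distance and maximum convex-hull
    volume), a random baseline, a toy-system benchmark harness, a
    Kruskal-style chaining of many end-states into a restraint ring for
    multi-state methods, and writers for GROMOS and GROMACS restraint
    files plus a JSON interchange format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    igraph,
    withr,
    bio3d,
    ChemmineR,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    RcppTOML,
    callr
Config/testthat/edition: 3
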