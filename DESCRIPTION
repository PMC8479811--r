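Package: perttop
Title: Automated Alchemical Perturbation Topology Builder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds single-topology alchemical perturbation definitions for
    free-energy calculations by a penalty-scored, branch-and-bound maximum
    common substructure (MCS) search over force-field molecular topologies.
    Reads and writes GROMOS11 and GROMACS topology dialects, perceives and
    classifies ring systems (fused, bridged, spiro), scores candidate atom
    mappings by user-weighted perturbation penalties with an admissible
    lower bound for pruning, breaks score ties by coordinate RMSD, audits
    dummy-atom anchoring for redundant bonded terms, and generates pairwise
    perturbation topologies as well as multistate (enveloping distribution
    sampling) reference topologies and closed thermodynamic cycles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
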