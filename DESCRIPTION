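Package: reaxkit
Title: Reactive Force-Field Toolkit for Aqueous Iron-Sulfur Cluster Chemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained ReaxFF-style reactive force-field toolkit for
    H/O/Fe/S systems. Provides a bond-order potential evaluator with
    electronegativity-equalization (EEM) charges, per-term energy breakdowns
    and analytic forces; readers and writers for the fixed-format ReaxFF
    'ffield' parameter file, (extended) XYZ structures, tabular training sets
    and multi-frame trajectories; internal-coordinate scan generators and a
    particle-swarm parameter trainer with Gaussian-mutation respawn and
    Nelder-Mead polishing; geometry optimization and constant-temperature
    molecular dynamics with a Berendsen thermostat; and analysis utilities for
    permutation-inversion RMSD, hydrogen-bond counting, solvation statistics,
    correlation and partial-charge reports. Deterministic synthetic fixtures
    (toy force fields, solvated boxes, synthetic training sets) make every
    component testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
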