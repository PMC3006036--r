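Package: nucleoblob
Title: Locating Phosphates and Bases in Nucleic-Acid Electron-Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated interpretation of crystallographic electron-density
    maps of nucleic acids. Locates candidate density blobs by iterative
    centre-of-gravity convergence, characterises their shape with a
    moments-of-density eigendecomposition, fits standard purine and
    pyrimidine templates by simplex and gradient refinement, scores
    Watson-Crick pairings as an independent pruning filter, and ranks
    phosphate candidates with a tetrahedral-density score. Also computes
    C1'-based backbone geometry (distances, angles, eta'/theta'
    pseudo-torsions) with circular statistics, bimodal splitting and
    Gaussian histogram fits for chain tracing and direction assignment,
    and ships reference geometry tables for the A-, B- and Z-DNA and RNA
    helical families. A synthetic module builds ideal duplex coordinates
    and renders density maps so the whole pipeline runs offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
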