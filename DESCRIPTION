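Package: tadstruct
Title: 3D Structure Reconstruction and Structural Metrics for Topologically
    Associating Domains from Hi-C Contact Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs three-dimensional chromatin and TAD (topologically
    associating domain) structures from Hi-C contact matrices by metric
    multidimensional scaling under three objective functions, including one
    that places bead pairs with zero observed contacts at a target distance R
    derived either from graph shortest paths or from the maximum target
    distance. Provides structural metrics for the reconstructed models: a
    feature-mass-weighted radius of gyration (masses encoding TSS, H3K4me3 and
    RNA polymerase II density), an Estrada-index folding degree built on the
    third iterated line graph of the bead chain with dihedral-angle weights,
    and the contact-decay exponent of the contact matrix. Includes Kabsch
    superposition and RMSD, ICE-style matrix balancing, per-TAD genetic and
    epigenetic feature enrichment, chromatin-state fold enrichment with
    spectral clustering of TADs, observed/expected inter-TAD contact
    normalization, and a synthetic-data generator producing ground-truth
    structures, matrices and feature tracks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
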