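Package: ligninsim
Title: Stochastic Reconstruction of Lignin Polymer Structure Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds libraries of chemically valid lignin polymer structures that
    match experimentally measured monomer and linkage distributions (e.g. from
    2D-HSQC NMR), optional number-average molecular weight, and branching
    statistics. Polymers are represented as multiscale molecular graphs (an
    atom-level graph plus a coarse-grained graph with one node per monomer and
    one edge per linkage) and grown by rejection-free Metropolis Monte Carlo
    additions of monomers and intramolecular linkages. Includes per-polymer and
    population characterization (functional groups, molecular weight, branching
    coefficient), SMILES export, feedstock presets for pine, poplar and
    miscanthus lignin, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    igraph,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
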