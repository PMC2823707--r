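Package: hybtherm
Title: Multi-State Thermodynamic Modelling of Microarray Probe Hybridization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models oligonucleotide microarray signal as the outcome of a
    competition between probe-target duplex formation and the folding of
    probes, targets and probe-probe dimers.  Provides nearest-neighbor
    duplex thermodynamics with a salt- and formamide-corrected melting
    temperature, a partition-function secondary-structure engine for
    single strands and intermolecular duplexes (ensemble free energies,
    minimum-free-energy structures, binding-site opening energies), the
    effective interaction energy combining these terms, probe truncation
    scans, and a GUIDE-style regression-tree importance ranking with
    bootstrap error estimates.  A synthetic-data generator (tiling
    probes, Langmuir intensity simulation) makes the whole pipeline
    testable without array data, and a small command-line interface
    binds the steps together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rpart,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
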