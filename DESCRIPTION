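Package: nrf2prot
Title: Differential Proteomics and Antioxidant Response Element Scanning for
    Nrf2-Null Versus Wild-Type Liver
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for constitutive protein-expression profiling
    of Nrf2-knockout versus wild-type mouse liver. Implements iTRAQ reporter-ratio
    differential expression (per-animal run averaging, geometric-mean summaries
    with log-normal confidence intervals, fold changes, Shapiro-Wilk-gated
    t/Mann-Whitney testing and Benjamini-Hochberg acceptance), two-dimensional gel
    electrophoresis spot-intensity normalization and group statistics,
    cross-analysis concordance of significant protein lists, hypergeometric
    gene-set over-representation, and antioxidant response element (ARE) promoter
    scanning by degenerate consensus search and position-specific scoring matrix
    (patser-style log-odds) scanning. A synthetic-data generator with known
    ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
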