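Package: evoprofiler
Title: Evolutionary Profiling of Disease Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-set level analysis of evolutionary origin and selective
    constraint for disease predisposition genes. Assigns each gene a
    phylostratigraphic age index (PAI) from ortholog presence across a
    16-level taxon ladder, estimates dN/dS for Hominidae ortholog pairs by
    the Nei-Gojobori (1986) counting method and combines the ratios into a
    per-gene divergence index (DI), compares binned PAI/DI distributions of
    a gene set against the whole-proteome background with per-bin chi-square
    tests under Benjamini-Hochberg adjustment, and extracts and classifies
    hub genes from confidence-filtered protein-interaction networks.
    Includes seeded synthetic-data generators with ground-truth ledgers for
    every stage and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
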