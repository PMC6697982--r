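Package: synspread
Title: Quantification Pipeline for Alpha-Synuclein Cell-to-Cell Transfer Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify microglial involvement in alpha-synuclein
    cell-to-cell transfer experiments: segmentation of Iba-1-stained
    bright-field sections with an area-to-perimeter ("hydraulic radius")
    activation index, per-cell classification of human alpha-synuclein
    content in confocal z-stacks with percent-positive summaries, Iba-1
    cell density in regions of interest, optical-fractionator stereology
    with the Gundersen-Jensen error coefficient, and a count-matrix
    differential-expression workflow (CPM filtering, trimmed-mean-of-M
    normalization, precision-weighted moderated tests, Benjamini-Hochberg
    adjustment, reference-group z-scores, FPKM, multidimensional scaling,
    signature overlaps and hypergeometric gene-set enrichment). Synthetic
    generators for confocal stacks, stained sections and negative-binomial
    count matrices provide ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
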