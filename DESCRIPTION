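Package: generepo
Title: Headless Repository for Multi-Assay Genomics Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A headless library and command-line toolkit for curating
    genomics experiments across microarray and sequencing platforms.
    Provides structured experiment metadata with controlled vocabularies
    (experiments, bioassays, biomaterials, comparison groups, visibility
    levels), a gene/transcript/probeset/ortholog annotation model with
    cross-species symbol resolution, relational-style data tables for
    expression values, locus scores and fold-change statistics,
    processing routines (expression summarization, two-sample
    differential statistics with Benjamini-Hochberg FDR, windowed and
    per-transcript FPKM, promoter peak assignment), gene-centric query
    and heatmap/scatter table preparation, GEO SOFT import/export,
    ISA-Tab and GCT export, BED input, and seeded synthetic-data
    generators with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
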