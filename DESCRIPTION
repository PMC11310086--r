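Package: ophioregen
Title: Comparative Transcriptomics and Karyotype Evolution for Appendage Regeneration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cross-species comparison of appendage
    regeneration transcriptomes and echinoderm genome architecture. Provides
    trimmed-mean-of-M-values normalization and fuzzy c-means soft clustering of
    regeneration time courses with minimum-centroid-distance model selection;
    a constrained permutation test for cross-species conservation of
    co-expression clusters with Benjamini-Hochberg correction; hypergeometric
    enrichment and depletion tests with family-level annotation propagation and
    phylostratigraphic gene-age assignment; Fisher-exact macrosynteny painting
    against ancestral linkage groups with Dollo reconstruction of the ancestral
    karyotype and interchromosomal rearrangement rates; repeat divergence-to-age
    calibration, landscape binning, and region expansion and
    breakpoint-association tests; and categorization of differentially
    expressed genes from arm explant designs. A synthetic-data generator with
    planted ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    e1071,
    jsonlite
Config/testthat/edition: 3
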