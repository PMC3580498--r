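Package: hogseq
Title: Genome-Wide Analysis of RNA Polymerase II Redistribution and
    Hog1-Dependent Chromatin Remodeling upon Osmostress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse ChIP-Seq and MNase-Seq experiments probing the
    osmostress response in budding yeast: read deduplication and strand-aware
    extension, per-region quantification with trimmed-mean-of-M-values (TMM)
    normalized read densities (TRPK), MA-plot Z-score enrichment calling
    between conditions and strains, TSS-aligned nucleosome profiles with a
    simplified peak caller, nucleosome occupancy and eviction quantification
    with a paired test, and stress-response gene classification from
    expression fold changes.  A synthetic-data module generates toy genomes,
    ChIP reads, mononucleosome fragments and expression tables with known
    ground truth so that every step of the pipeline can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
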