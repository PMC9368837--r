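Package: g4scape
Title: Analysis of Cation-Favorable DNA G-Quadruplex Landscapes from
    BG4-DNA-IP-Seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of DNA G-quadruplex (G4)
    immunoprecipitation peak sets, as produced by BG4-antibody DNA-IP-seq
    under different monovalent-cation conditions. Provides a regex-style
    putative quadruplex sequence (PQS) scanner with loop-length subtype
    classification, replicate-reproducibility and condition-specific peak
    set operations, a seven-category subgenomic partition with peak
    assignment, shuffle-based fold-enrichment nulls, scaled-region GC/AT
    skew and GC-content profiles, peak-centered signal and
    cytosine-context methylation metaprofiles, expression association of
    peak-overlapping genes, and a synthetic-data generator that plants
    known PQSs, peak overlaps, methylation levels and expression effects
    so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
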