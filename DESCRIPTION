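Package: pioneerscan
Title: Pioneer-Factor Chromatin-Opening Analysis from ATAC-Seq, ChIP-Seq and
    RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated toolkit for studying how transcription factors
    shape open chromatin across developmental time points. Provides interval
    overlap statistics (Jaccard, summit-confocal co-occurrence with
    hypergeometric testing, genomic-feature enrichment, nearest-TSS
    annotation, knockout region loss), position weight matrix scanning with
    exact score p-values, PWM similarity (cor/ncor) and average-linkage
    clustering, known-motif binomial enrichment with randomization FDR, Tn5
    cut-profile analysis (simplified Poisson open-region calling, footprint
    detection and scoring, nucleosome occupancy, meta-profiles,
    NFR-nucleosome pairing), per-factor chromatin-opening indexes with
    pioneer-potential ranking, peak-to-gene integration with cell-type
    gene-set enrichment, and a synthetic-data generator with planted ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
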