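Package: bivalScore
Title: Bivalent Chromatin Domain Calling and Scoring with Expression Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls H3K4me3 and H3K27me3 enriched domains ("islands") from
    ChIP-seq tag data using a fixed-window Poisson background model with gap
    linking and a Monte-Carlo E-value calibrated score threshold, at a series
    of gap sizes. Computes a 0-5 bivalency score per gene by testing overlap
    of a TSS +/- 2 kb window against both marks' domains at each gap size,
    and integrates the scores with a microarray differential-expression stage
    (quantile normalisation, error-weighted one-way ANOVA, Benjamini-Hochberg
    FDR, signed linear fold changes, PCA) and comparative Ct (delta-delta-Ct)
    qPCR quantitation. Includes a synthetic-data module that plants enriched
    domains, gene classes, expression effects and Ct shifts with known ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    limma,
    rtracklayer,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
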