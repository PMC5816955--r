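Package: gonadomics
Title: Multi-Omic Analysis Toolkit for the Gonadotrope GnRH Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable implementations of the computational stages used to
    characterize the gonadotrope (LbT2) response to gonadotropin-releasing
    hormone across bulk RNA-seq, droplet single-cell RNA-seq, ATAC-seq and
    qPCR readouts: a synthetic multi-omic data generator with recorded
    ground truth; moderated-t bulk differential expression with
    fold-change/FDR selection and TPM; single-cell normalization,
    reproducibility (split-half and pseudobulk-versus-bulk) diagnostics,
    Poisson technical-noise decomposition and shrinkage negative-binomial
    (sSeq-style) exact-test differential expression; five-phase cell-cycle
    scoring, cyclic cell ordering and phase-conditioned response testing;
    ATAC fragment-length periodicity, peak feature classification, TSS
    meta-profiles, accessibility-expression integration, PWM scanning and
    transcription-factor footprint (notch) detection; and arbitrary-unit
    qPCR quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Biostrings,
    edgeR
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
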