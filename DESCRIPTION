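Package: crispracontext
Title: Chromatin-Context Analysis of Barcoded CRISPR Activation Reporter Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing massively parallel barcoded-reporter assays of
    CRISPR activation (CRISPRa) efficacy across chromatin contexts. Includes a
    fully parameterised synthetic-data generator with known ground truth;
    recovery of reporter insertion sites from inverse-PCR reads with
    two-enzyme reconciliation; cDNA/gDNA expression scoring with
    median-of-ratios normalisation and expression-dynamics classification;
    chromatin-state, ChIP-signal-window and TAD-level association analyses;
    an exponential-decay model of fold activation versus basal expression with
    chromatin-state enrichment of its residuals; single-cell CRISPRa guide
    assignment, QC and per-target activation testing; and a two-latent-state
    negative-binomial regression with log-total-UMI offset fitted by
    expectation-maximisation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    DESeq2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
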