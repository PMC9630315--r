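Package: TriplexKit
Title: Discovery and Validation Statistics for Triplex-Forming Long Noncoding RNAs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying and validating DNA:DNA:RNA
    triplex-forming long noncoding RNAs. Implements a Hoogsteen and
    reverse-Hoogsteen pairing code with a mismatch-tolerant search for
    triplex target sites (TTS) in duplex DNA, discovery of
    triplex-forming regions (TFRs) within an RNA using a
    region-shuffling empirical null, a Poisson peak-enrichment screen
    for prioritizing candidate lncRNAs from triplex sequencing summary
    tables, quantitative wet-lab validation statistics (delta-delta Ct
    fold changes, percent-input recovery, RNase-H resistance ratios),
    and biphasic melting-curve modelling with monophasic versus
    biphasic model selection as the spectroscopic triplex signature.
    A seeded synthetic-data module generates genomes with planted
    target sites, peak tables, Ct tables and melting curves with known
    ground truth, and a pipeline orchestrator ties all stages into a
    reproducible, manifest-logged run.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
biocViews: Software, Transcriptomics, Epigenetics, SequenceMatching,
    StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
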