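Package: gcstratify
Title: GC-Stratified Structural Annotation Assessment and Training-Set
    Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for assessing and improving structural genome annotation
    in species whose coding sequences have a bimodal GC-content
    distribution, as found throughout the grasses.  Profiles per-transcript
    CDS GC content, detects the two modes of the distribution with a
    smoothed integer-bin histogram, and uses the detected peaks as set
    points to partition transcript-derived gene models into high-GC and
    low-GC training sets for ab initio gene predictors.  Scores gene models
    against transcript and protein evidence with the annotation edit
    distance (AED), merges predictions from multiple predictor sources by
    choosing the best-supported model per locus, identifies novel and
    improved models between annotation sets, filters gene lists by evidence
    or Pfam-domain support and removes transposable-element-related
    predictions, evaluates codon usage bias (effective number of codons
    against GC3s), and computes TPM and translatome-enrichment-index
    summaries from count tables.  Includes a synthetic-genome simulator
    that reproduces the statistical structure these methods assume, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
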