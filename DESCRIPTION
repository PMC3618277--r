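Package: varcohort
Title: Variant Characterization for Whole-Genome Sequencing Cohorts
Version: 1.0.0
Authors@R: person("varcohort", "developers", role = c("aut", "cre"),
    email = "maintainer@varcohort.invalid")
Description: Downstream characterization of variant call sets from a
    whole-genome sequencing cohort: normalization and block-substitution
    merging of proximal variants, transcript-model based functional
    annotation under a CDS > UTR > splice > intron > intergenic hierarchy,
    loss-of-function and gene-knockout detection, gene ranking by
    deleterious-variant density, cross-catalog novelty with windowed indel
    matching, permutation-based discovery saturation curves, and windowed
    density/correlation tracks.  Ships a fully deterministic synthetic-cohort
    generator (reference, transcripts, diploid genotypes under a configurable
    site-frequency spectrum, planted functional classes and partial catalogs)
    with recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
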