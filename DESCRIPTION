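Package: germsoma
Title: Integrated Germline-Tumor Two-Hit Analysis for Familial Cancer Gene
    Prioritization
Version: 1.0.0
Authors@R:
    person("germsoma", "developers", email = "germsoma@example.org",
           role = c("aut", "cre"))
Description: Tools for paired germline-tumor whole-exome variant analysis
    aimed at prioritizing candidate tumor suppressor genes under Knudson's
    two-hit hypothesis.  Provides germline and somatic SNV/indel filter
    cascades driven by six pathogenicity predictors and population allele
    frequencies, loss-of-heterozygosity detection from allelic imbalance at
    germline-heterozygous sites (recursive binary segmentation with a
    permutation stopping rule, exact binomial site tests combined by
    Fisher's method), two-hit gene pairing and candidate tables, tumor
    mutational burden and 96-channel mutational-signature refitting by
    non-negative least squares, rare-variant case-control enrichment by
    Fisher's exact test, and a synthetic paired-cohort generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    optparse,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    rtracklayer,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
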