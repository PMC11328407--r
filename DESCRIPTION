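Package: editscan
Title: A-to-I RNA Editing Detection and Differential Editing Analysis for
    Time-Course RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects adenosine-to-inosine (A-to-I) RNA editing events from
    pileup-level allele counts, retains high-confidence events using a
    two-sample/known-site rule, annotates functional categories and coding
    (HGVS c./p.) consequences from transcript models, and tests for
    differential RNA editing across time-point groups with a dual criterion
    combining a binomial GLM likelihood-ratio test and an R x 2 Fisher exact
    test on pooled allele counts, with Benjamini-Hochberg FDR control and
    Tukey HSD post-hoc comparisons. Includes Spearman-based detection of
    time-dependent editing and of cis correlation between editing levels and
    edited-gene expression, TPM normalization with a simple group-wise
    differential-expression test, PCA summaries, and a synthetic-data
    generator that emulates an LPS time-course design with ground truth for
    recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
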