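Package: fupscreen
Title: Paired Tumor/Normal Differential-Regulation Screening with the
    Fraction-Upregulated Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A matched tumor/normal differential-regulation screen for
    pan-cancer cohorts. Implements the fraction-upregulated (f_up)
    sign-test statistic with exact binomial p-values and beta-distribution
    confidence intervals, per-sample proliferation (meta-PCNA) scoring,
    linear-model detrending of proliferation and tissue effects with a
    detrended f_up screen, rank-based (Mann-Whitney U) gene-set
    enrichment, co-differential-expression (cx) profiling and pathway
    ranking, and methylation/expression integration via median-split odds
    ratios at transcription-start-site and gene-body probes. Ships a
    synthetic matched-cohort simulator with planted ground truth so every
    pipeline stage has a recoverable target.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
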