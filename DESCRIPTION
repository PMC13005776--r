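Package: mirogtt
Title: Circulating MicroRNA Analysis for OGTT Biomarker Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for circulating microRNA biomarker studies
    built around the oral glucose tolerance test (OGTT), with a focus on
    cystic fibrosis-related diabetes. Provides glucose-tolerance
    classification from OGTT glucose series; RT-qPCR plate quality control
    (spike-in based interplate calibration, RT-inhibition, haemolysis and
    extraction-consistency gates with a participant inclusion rule); two
    endogenous-control normalization schemes (per-sample control-mean delta-Ct
    and delta-delta-Ct against an NGT baseline reference); per-timepoint
    volcano-style differential expression, across-group ANOVA with Tukey
    post hoc tests and mixed-effects OGTT time-course analysis; a paired
    log-ratio Wald test for group-by-timepoint differential glucose response
    on small-RNA count matrices with median-of-ratios normalization and
    Benjamini-Hochberg FDR; Spearman correlation of microRNA levels with
    clinical analytes (exact permutation p-values at small n); hypergeometric
    over-representation analysis of microRNA targets; and a synthetic-data
    generator emulating the cohort, plate and count structure such studies
    assume, for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4,
    lmerTest,
    emmeans,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
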