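# mirogtt

Circulating microRNAs are candidate biomarkers of metabolic disease, and
their serum levels can change within minutes of a glucose challenge.
`mirogtt` is an R package for analysing circulating-microRNA studies built
around the oral glucose tolerance test (OGTT), with cystic fibrosis-related
diabetes (CFRD) as the motivating setting: cohorts spanning normal (NGT),
indeterminate (INDET) and impaired (IGT) glucose tolerance and CFRD, sampled
serially during an OGTT, profiled by small-RNA sequencing and/or RT-qPCR
panels, and joined to clinical chemistry.

It is aimed at analysts who receive (a) long-format Ct tables from
spike-in-controlled LNA RT-qPCR panels, (b) miRNA count matrices from paired
baseline/post-load sequencing, and (c) OGTT glucose/insulin series with
liver and inflammation markers — and who need the whole path from plate QC
to interaction testing to be reproducible and testable without access to the
(typically undisclosable) participant-level data. A seeded synthetic-data
generator emulates the full cohort/plate/count structure so that every stage
runs and is validated offline.

## What it computes

**Glucose-tolerance classification.** From the 2 h diagnostic glucose
`G120` and the mid-OGTT samples (10/30/60 min):
CFRD if `G120 ≥ 11.1` mmol/l; IGT if `7.8 ≤ G120 < 11.1`; INDET if
`G120 < 7.8` but any mid-OGTT glucose `≥ 11.1`; otherwise NGT — evaluated in
exactly that precedence.

**Plate QC.** Interplate calibration subtracts each plate's UniSp3 deviation
from the global UniSp3 mean. Three gates then apply: RT inhibition
(UniSp6 Ct > 23 fails), haemolysis
(ΔCt = Ct[miR-23a-3p] − Ct[miR-451a] ≥ 7 fails) and extraction consistency
(per-spike-in UniSp2/4/5 Ct range > 3 cycles across a participant's samples
fails). A participant is included when the baseline sample and ≥ 2 further
OGTT samples pass.

**qPCR quantification.** Two normalization schemes: per-sample ΔCt against
the arithmetic mean of the endogenous controls miR-16-5p, miR-23a-3p and
miR-486-5p (feeding per-timepoint volcano comparisons: equal-variance t test,
class `up`/`down` at ≥ 1.5-fold and p < 0.05), and ΔΔCt against the NGT
baseline reference with fold `2^(−ΔΔCt)` (feeding one-way ANOVA + Tukey HSD
across groups and a REML mixed model with group × timepoint fixed effects,
per-participant random intercepts, and uncorrected per-timepoint contrasts).

**Count arm.** Median-of-ratios size factors, an expressed filter
(> 5 normalized counts in ≥ 50% of samples), baseline Welch tests, and a
paired log-ratio Wald test of the glucose differential response: per
participant `r_i = log2((n60 + ½)/(n0 + ½))`, interaction effect
`mean r(group) − mean r(NGT)`, `z = effect / SE`, BH FDR, volcano class at
≥ 2-fold and q < 0.05. This is a deliberate, documented simplification of a
negative-binomial GLM interaction test with the same estimand.

**Associations & targets.** Spearman correlation of miRNA levels with
glucose, insulin, ASAT/ALAT/ALP/γGT, CRP and LPK per group × timepoint
(exact permutation p-values for n ≤ 10, via compiled enumeration), and
hypergeometric over-representation of common validated miRNA targets within
an expressed-gene universe.

## Worked example

Simulate a cohort with the study's group sizes (NGT 18, INDET 6, IGT 12,
CFRD 14), inject a 2-fold baseline elevation of miR-122-5p in INDET and
CFRD and a +1.5 log2 glucose-response interaction for miR-223-3p in CFRD,
then run the full qPCR pipeline and the count-arm response test:

```r
library(mirogtt)

cfg <- sim_config(
  seed = 42,
  baseline_log2fc = data.frame(mirna = "miR-122-5p",
                               group = c("INDET", "CFRD"), log2fc = 1),
  response_log2fc = data.frame(mirna = "miR-223-3p",
                               group = "CFRD", log2fc = 1.5))
ds <- simulate_dataset(cfg)

g120 <- setNames(ds$cohort$participants$glucose_120_mmol_l,
                 ds$cohort$participants$participant_id)
res <- run_pipeline(ds$ct_records, ds$cohort$samples, g120,
                    out_dir = "run1")
#> classify: 50 participants (NGT=18, INDET=6, IGT=12, CFRD=14)
#> qc: 210/250 samples pass, 42/50 participants included
#> normalize: 2960 expression records
#> volcano: 240 comparisons

subset(res$volcano, mirna == "miR-122-5p" & timepoint_min == -1 &
                    grepl("CFRD", comparison))
#>          mirna      comparison timepoint_min   log2fc     fold            p volcano_class
#> 161 miR-122-5p CFRD_vs_NGT_t-1            -1 1.014531 2.020246 1.192875e-14            up

dr <- differential_response(ds$counts, ds$meta, "CFRD")
head(dr[order(dr$p), c("mirna", "effect", "z", "p", "q", "volcano_class")], 3)
#>            mirna effect     z        p        q volcano_class
#> 2     miR-223-3p  1.069  5.37 7.86e-08 1.56e-05            up
#> 155 null-mir-156  0.653  4.24 2.25e-05 2.23e-03            ns
#> 105 null-mir-106 -1.169 -3.04 2.35e-03 1.14e-01            ns
```

The QC report shows 210 of the 250 simulated samples surviving the three
gates (the defaults inject 10% haemolysis and 5% RT-inhibition artifacts)
and 42 of 50 participants meeting the inclusion rule. The injected 2-fold
miR-122-5p elevation is recovered as fold ≈ 2.02 and classed `up`; the
injected miR-223-3p interaction tops the response ranking at q < 0.05 while
the best null miRNA stays below the 2-fold volcano cut-off.

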