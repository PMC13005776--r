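---
title: "Methods and design of the mirogtt OGTT microRNA pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the mirogtt OGTT microRNA pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirogtt)
```

`mirogtt` analyses circulating microRNA measurements collected around an
oral glucose tolerance test (OGTT) in cohorts stratified by glucose
tolerance, with cystic fibrosis-related diabetes (CFRD) as the motivating
application. This vignette is the package's own account of the models it
fits, the thresholds it applies, the synthetic data it validates itself on,
and the design decisions taken where more than one reading was defensible.

## Glucose-tolerance classification

Participants are classified from OGTT glucose alone. With `G120` the 2 h
diagnostic glucose (mmol/l) and the mid-OGTT samples those drawn at 10, 30
and 60 min, `classify_glucose_tolerance()` applies, in order:

1. **CFRD** if `G120 >= 11.1`;
2. **IGT** if `7.8 <= G120 < 11.1`;
3. **INDET** if any mid-OGTT glucose `>= 11.1`;
4. **NGT** otherwise.

Three decisions are baked in. First, the IGT upper bound, printed
clinically as "7.8–11.0", is implemented as `G120 < 11.1` so the scale has
no gap between 11.0 and 11.1. Second, the sampling grid used throughout the
package (−1, 10, 30, 60, 180 min) does not contain 120 min, so `G120` is a
separate required input and is never interpolated from neighbouring draws;
a missing `G120` makes a participant unclassifiable rather than silently
NGT. Third, "mid-OGTT" means the sampled points strictly between baseline
and 2 h — the 180 min sample never triggers the INDET rule. A consequence
of the fixed precedence is that a participant with `G120 < 7.8`, mid-OGTT
values below 11.1 but a 180 min value at or above 11.1 is labelled NGT:
the four categories, as defined on 2 h and mid-OGTT glucose, assign no
other label to that trajectory. We regard this as a property of the
category definitions, not of the implementation.

## Plate quality control

qPCR panels carry five synthetic spike-ins: UniSp2/4/5 added before RNA
extraction, UniSp3 as the interplate calibrator, UniSp6 added at reverse
transcription. `interplate_calibrate()` subtracts from every Ct on a plate
the difference between that plate's mean UniSp3 Ct and the global UniSp3
mean, so all plates share the calibrator mean afterwards; the transform is
idempotent, and on a single plate it is the identity. Note that adding a
constant to one plate moves the *global* mean, so other plates' calibrated
Cts shift by a common constant — all within- and between-sample Ct
differences, which is what every downstream quantity is built from, are
unaffected.

Three gates follow, all evaluated on calibrated Cts (calibration first
standardizes reporting; the haemolysis index is a within-sample difference
and is unaffected by plate offsets either way):

* **RT inhibition**: UniSp6 Ct strictly above 23 cycles fails; an
  undetected UniSp6 fails (a silent control is a failed reaction, not a
  pass).
* **Haemolysis**: index `Ct(miR-23a-3p) − Ct(miR-451a)`; pass requires
  index `< 7` cycles, strictly. miR-451a is erythrocyte-enriched, so
  haemolysis pulls its Ct down and the index up. If either assay is
  undetected the sample fails with reason `haemolysis_unevaluable`.
* **Extraction consistency**: for each of UniSp2, UniSp4 and UniSp5
  separately, the Ct range (max − min) across all of a participant's OGTT
  samples must not exceed 3 cycles, strictly. We read the consistency
  requirement as cross-sample drift within a participant (the spike-ins are
  added per aliquot before extraction, so their stability across a
  participant's samples is what certifies comparable recovery); a failure
  on any spike-in excludes the participant entirely.

The inclusion rule: the baseline (−1 min) sample must pass all gates, and
at least two of the remaining timepoints must pass. Excluded samples and
participants always carry machine-readable reason codes. "Undetected" is
represented as a missing Ct (an empty field on disk), never as a sentinel
cycle number.

## Normalization schemes

Two schemes are provided because they serve different analyses.

**Control-mean ΔCt** (`normalize_control_mean()`): per sample,
`ΔCt = Ct(miRNA) − mean(Ct of miR-16-5p, miR-23a-3p, miR-486-5p)`
(arithmetic mean). Normalization must be in-sample to yield one value per
sample for a t test; this scheme feeds the per-timepoint volcano
comparisons. The three endogenous controls are used because of their
abundance and stability across the OGTT; the generator encodes that
assumption by giving them zero group and timepoint effects.

**ΔΔCt against the NGT baseline** (`normalize_ddct()`): the in-sample step
subtracts the geometric mean of the three control Ct values, taken on the
Ct scale exactly as that quantity is conventionally reported (Cts are
already logarithmic, so this is a deliberate convention, not an oversight).
The between-group step subtracts the NGT-baseline reference, computed as
the arithmetic mean of the NGT baseline ΔCt values — equivalently the log2
of the geometric mean of their relative-expression values `2^(−ΔCt)`,
which is the natural reading of "geometric mean" for expression data. This
choice makes the anchoring identity exact: the geometric mean of
`fold = 2^(−ΔΔCt)` over NGT baseline samples is 1 by construction (a
geometric mean of ΔCt values themselves would not achieve this and is
undefined when ΔCt changes sign).

## Differential expression

**Per-timepoint volcano** (`volcano_per_timepoint()`): per miRNA,
a two-sample Student's t test on ΔCt (equal variances by default — the
common qPCR-platform convention; Welch via `var_equal = FALSE`), with the
group fold change taken as the ratio of group arithmetic means of
`2^(−ΔCt)`. Class `up` requires fold ≥ 1.5 *and* p < 0.05; `down`
symmetrically at ≤ 1/1.5. The fold cut-off is inclusive, so a fold of
exactly 1.5 is significant — the boundary value stays on the flagged side.
Groups with fewer than two samples at a timepoint are skipped with a
reason, never silently.

**Across-group baseline comparison** (`baseline_group_anova()`): one-way
ANOVA on fold values across the four groups with Tukey HSD pairwise
comparisons (studentized range, via `stats::aov`/`stats::TukeyHSD`). Zero
within-group variance everywhere is a degenerate input and is refused.

**OGTT time course** (`dynamic_mixed_effects()`): a linear mixed model on
log2 expression (−ΔΔCt by default) with group, timepoint and their
interaction as fixed effects and a per-participant random intercept,
fitted by REML (`lmerTest::lmer`). Random slopes are not identifiable with
at most five timepoints under missingness and are deliberately omitted.
Per-timepoint pairwise group contrasts use Satterthwaite degrees of
freedom with *no* multiplicity correction — the uncorrected-Fisher
(Fisher's LSD) convention; the contrast table is exploratory by design.
Non-convergence is reported with the optimizer's messages, never silently.
On balanced complete data the fixed effects coincide with ordinary least
squares, which the test suite checks at tolerance 1e-6.

## The count arm and the differential-response statistic

Size factors use the median-of-ratios construction: per sample, the median
over reference miRNAs (positive in every sample) of the ratio of its count
to the miRNA's geometric mean across samples. Size factors are defined
only up to a common scale; all downstream quantities depend on ratios.
When no miRNA is positive everywhere the function stops and names the
documented fallback (`pseudo_reference = TRUE`, geometric means over
positive entries only). The expressed filter retains a miRNA with more
than five normalized counts (strict) in at least 50% of samples
(inclusive fraction).

The glucose differential response — whether a miRNA's baseline→60 min
change differs between a group and NGT — is tested with a paired log-ratio
Wald statistic: per participant `r_i = log2((n60 + ½)/(n0 + ½))` on
normalized counts, interaction effect `mean r(group) − mean r(NGT)`,
`z` = effect over the pooled standard error, two-sided normal p, BH FDR
across miRNAs, volcano class at |effect| ≥ 1 (2-fold) and q < 0.05.
Pairing within participant *is* the correction for participant
variability. This deliberately replaces a negative-binomial GLM with
dispersion shrinkage: the estimand (the group × timepoint interaction on
the log scale) is the same, the arithmetic is auditable against exhaustive
oracles, and no GLM machinery is needed. The cost is small-sample
behaviour: with three participants per group the pooled SE has four
degrees of freedom, the normal reference is optimistic in the tails, and
no information is shared across miRNAs. Under the global null the
statistic is t-like rather than normal, which makes nominal p < 0.05 rates
slightly anticonservative yet leaves the BH q < 0.05 fraction at or below
its nominal level in the calibration tests. Power to *top-rank* a true
interaction among hundreds of nulls at n = 3/group exists only in the
low-dispersion (near-Poisson) regime for an abundant miRNA — exactly the
regime the recovery tests use — and degrades quickly as biological
dispersion grows; that degradation is a property of the simplified
statistic and is documented rather than patched.

The pseudocount (default 0.5, configurable via the threshold list) keeps
log-ratios finite at zero counts and slightly shrinks extreme ratios at
low counts.

## Spearman correlations

`spearman_test()` computes rho from average ranks (midranks under ties).
For n ≤ 10 the two-sided p-value is exact: all n! permutations are
enumerated in compiled code, counting permutations whose |rho| reaches the
observed one (a 1e-9 relative tolerance guards ties in the permutation
statistic against rounding). Exactness matters here because group-stratum
sizes in such cohorts are small (an INDET stratum of six, say), where the
t approximation is materially off. Above n = 10 the usual
`t = rho * sqrt((n−2)/(1−rho²))` approximation on n − 2 df is used. A
constant vector makes rho undefined and it is reported as `NA`, never
coerced to zero. The correlation panel applies no multiplicity correction;
it mirrors exploratory practice and is labelled as such.

## Target over-representation

`common_targets()` takes, per miRNA, the union of its targets across
source databases (either database suffices to call a target validated —
the less restrictive reading, since requiring both would silently shrink
with database version skew), intersects across the miRNA list, and
restricts to the expressed-gene universe. The expression threshold that
defines "expressed in the tissue of interest" is a property of the
universe file the user supplies, not of this package.
`hypergeom_ora()` computes the upper-tail hypergeometric probability
`P[X ≥ k]` per pathway against that universe, with BH adjustment across
pathways. Database access is file-based (TSV targets, GMT pathways, plain
gene lists); the shipped fixtures under `inst/extdata/` are synthetic,
constructed for testing, and are labelled as such in their filenames.

## The synthetic-data generator

`sim_config()` fixes the study conditions; `simulate_cohort()`,
`simulate_ct_plates()` and `simulate_counts()` realize them
deterministically given a seed. Defaults, chosen once:

* **Cohort**: NGT 18, INDET 6, IGT 12, CFRD 14 (the qPCR-cohort group
  sizes); OGTT grid −1/10/30/60/180 min plus a separate 2 h glucose.
  Glucose trajectories are drawn per group with jitter and then clamped so
  that reclassification reproduces the intended group with certainty —
  e.g. a non-INDET participant's sampled values stay clear of the
  11.1 mmol/l mid-OGTT trigger with a safety margin. Clinical analytes
  (ASAT, ALAT, ALP, γGT, CRP, LPK) are drawn per group from scaled Beta
  distributions matched to the observed per-group baseline means and
  confined to the observed ranges.
* **Plates**: 15 samples per plate; plate offsets N(0, 0.25) cycles;
  per-well Ct noise N(0, 0.2) cycles, truncated at ±3 SD. Truncation is a
  design choice: injected artifacts are placed with more than 3 noise SDs
  of margin on the failing side of their gate (haemolysis shifts the index
  from 5 to 9 cycles against a gate at 7; RT inhibition shifts UniSp6 from
  20 to 24.5 against a gate at 23), so the gate-flagged set equals the
  injected artifact set exactly and QC tests are sharp, not probabilistic.
  Artifact rates default to 10% haemolysis and 5% RT inhibition —
  haemolysis is the dominant failure mode of serum panels.
* **Ct anchoring**: target Cts are generated as control-anchored ΔCt
  offsets minus the injected log2 effects (baseline effects at every
  timepoint; response effects at 60 min), so the normalization schemes
  exactly invert the construction at zero noise — parameter recovery is an
  identity, not an approximation, and is tested at tolerance 1e-9.
* **Counts**: negative binomial with dispersion 0.1 by default
  (variance = μ + 0.1 μ²; dispersion 0 gives Poisson), library sizes
  uniform on 0.8–1.2 million, per-participant lognormal factors (SD 0.3 on
  the log scale) encoding the pairing, 200 null miRNAs, and effect-carrying
  miRNAs fixed at 2000 counts per million — candidate biomarkers in serum
  sit near the top of the abundance distribution.
* **Analyte coupling**: a Gaussian copula ties a per-participant miRNA
  level offset (SD 0.5 log2 units) to a designated analyte at a requested
  Spearman strength, using the exact Gaussian-copula conversion
  `r = 2 sin(π ρ_s / 6)`; Spearman's rho is invariant to the marginal
  transforms, so the Beta-marginal analytes inherit the coupling exactly.

What the generator does *not* emulate, and what passing tests therefore do
not show: real hemolysis is graded, not a clean 4-cycle shift; real plate
effects can be assay-specific; amplification efficiencies differ from 2
per cycle; count dispersion varies per miRNA and exceeds the default for
inflammation-responsive species; glucose and insulin trajectories are
smoother and correlated within participants; and dropout ("undetected")
is absent by default. Green tests certify the algebra, thresholds and
statistical calibration of the pipeline under its own assumptions — not
clinical performance on real cohorts.

## Numerical choices and degenerate inputs

* Thresholds live in one named list (`default_thresholds()`) passed
  through every entry point; nothing is hard-coded at call sites.
* All gate and filter comparisons use the strictness stated above;
  boundary tests probe each on a grid and pin the flip point.
* Ct values are carried at full double precision end to end; the
  generator does not round them (the ΔΔCt inversion identity is tested at
  1e-9, which rounding would break).
* Errors are classed conditions (`mirogtt_validation`, `mirogtt_gate`,
  `mirogtt_schema`, …) so callers can discriminate failure modes;
  degenerate inputs (constant vectors, single-participant strata,
  all-zero references, missing baseline samples) are refused or skipped
  with reasons, never silently absorbed.
* Test and calibration problem sizes are chosen for a laptop-class run:
  null calibration uses 200 replicates of a 24-participant plate design
  and 200 replicates of the 12-participant count design; power recovery
  uses 100 seeds; copula recovery 200 replicates at n = 50. These sizes
  put Monte-Carlo error well inside the asserted bands.

## Known limitations

* The response statistic trades small-sample efficiency for auditability,
  as discussed above; with realistic dispersion and n = 3/group it has
  little ranking power, and a practitioner with more participants or a
  need for shrinkage should treat it as a screen.
* The mixed model assumes Gaussian residuals on the log2 scale and a
  single random intercept; strong mean–variance coupling or
  participant-specific OGTT shapes are not modelled.
* The correlation panel is uncorrected for multiplicity by design.
* Headline cohort counts from any particular study (numbers of expressed,
  candidate or validated miRNAs; samples surviving QC) depend on
  participant-level data and database snapshots and are not reproduction
  targets of this package; the reproducible surface is the set of decision
  thresholds and the statistical properties exercised by the test suite.
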