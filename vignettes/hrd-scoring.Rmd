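---
title: "Genomic instability scar scoring and HRD assay concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic instability scar scoring and HRD assay concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(giscar)
```

## The problem

Tumors with homologous recombination deficiency (HRD) cannot repair
double-strand breaks by homologous recombination and accumulate a
characteristic pattern of large chromosomal lesions — "genomic scars".
In high-grade epithelial ovarian cancer, HRD predicts benefit from PARP
inhibitors, and clinical assays call a tumor HRD-positive when it carries a
pathogenic *BRCA1/2* mutation and/or its genomic-instability (GI) score
exceeds a threshold. Different commercial platforms compute that score with
different rules and thresholds, so a laboratory adopting an alternative
platform needs (i) transparent implementations of the scoring rules and
(ii) the concordance statistics that compare a candidate assay to the
reference assay on the same tumors. This package provides both, plus a
synthetic-cohort generator to validate the whole chain by parameter
recovery.

## Inputs and conventions

Both scoring engines consume allele-specific copy-number (ASCN) segment
profiles — the output of upstream segmentation tools such as ASCAT or
SEQUENZA — with per-segment major/minor copy numbers, probe counts, and
per-sample purity and ploidy. Segmentation itself, and BRCA variant
calling, are out of scope: segments and mutation flags are inputs.

Coordinates are 1-based inclusive (the prevailing copy-number segment-file
dialect), so a segment's length is `end - start + 1`. States are stored
ordered (`major_cn >= minor_cn`); two segments with the same ordered state
are considered equal even if they arose from opposite haplotypes, which the
data cannot distinguish. Every engine first merges adjacent equal-state
segments, which makes all counters invariant under splitting a segment into
equal-state pieces — a property the test suite checks explicitly.

Chromosome geometry comes from a packaged table of the 22 hg19 autosomes
(lengths and centromere gap intervals; sex chromosomes are excluded because
the scores are defined over autosomal markers). The genome build used by
the original platform pipelines is not public; hg19 is the standard choice
for the SNP-array annotation in this setting and only the centromere and
terminus positions enter the rules. "Subtelomere" is operationalized as the
chromosome's terminal position: a region "extends to a subtelomere" iff it
contains position 1 or position `length`. No public definition gives a
subtelomere span for these rules, and terminal contact is the standard
operationalization for telomeric allelic imbalance. This presumes profiles
that cover chromosomes end to end, as ASCAT-style segmentations do.

## The scar-count engine

The GI score is the plain sum of three counts:

* **TAI** (telomeric allelic imbalance): maximal runs of adjacent
  allelic-imbalance segments (`major != minor`) that contain a terminal
  position, do not overlap the centromere interval, are longer than 11 Mb,
  and carry at least 126 probes — the probe minimum is the SNP-array
  adaptation of the rule. At most two per chromosome, one per terminus.
* **LOH**: maximal runs with `minor = 0` longer than 15 Mb that do not
  span the whole chromosome. A run must retain an allele somewhere
  (`major >= 1`); homozygous-deletion-only runs are not scars, though 0+0
  segments do participate in run merging.
* **LST** (large-scale state transitions): per chromosome arm, after
  discarding segments shorter than 3 Mb and re-merging equal-state flanks,
  junctions between consecutive segments of different state where both
  segments are at least 10 Mb.

The 15 Mb / 3 Mb / 10 Mb constants follow the established published scar
definitions, which the source description names but does not restate; all
of them are parameters of `scar_config()`, so a laboratory can reproduce a
vendor's variant exactly.

Two deliberate surface decisions:

* **Threshold comparator.** The reference assay's published rule is
  "GI score >= 42"; some pipeline descriptions write "> 42". The default is
  the inclusive rule, and `scar_config(threshold_inclusive = FALSE)` gives
  the strict one. The difference matters only at exactly 42 and is
  surfaced rather than hidden.
* **Chromosome-specific ploidy.** The modal total copy number per
  chromosome (by covered length, ties broken toward the sample ploidy and
  then downward) is computed and reported by `score_profile()`, but by
  default does not modify the counting rules: no public specification says
  how it enters the score, so silently coupling it to the counters would
  be invented behavior.

## The 28-feature GS engine

The Genomic Scar model classifies every merged copy-number event by length
(small = \[5, 10) Mb, middle = \[10, 15\] Mb, large = > 15 Mb), site
(telomere / centromere / other), and type (LOH / allele-specific /
allele-balanced), giving 27 cells, plus the genome-wide breakpoint count —
28 features. The 1+1 diploid state and 0+0 homozygous deletions are not
events; segments under 5 Mb contribute to breakpoints but to no cell (the
smallest published class starts at 5 Mb). Boundary assignment is
deterministic and documented: 10 Mb and 15 Mb fall in "middle" (reading
"10–15 Mb" as inclusive and ">15" as strict); a whole-chromosome segment is
"telomere" (terminal contact is the rarer, more informative site and the
tie must break deterministically).

The published model's coefficients are proprietary and unprinted, so
`gs_config()` takes a weight vector (plus intercept) and defaults to unit
weights with the published positivity threshold of 50 (inclusive). All
structural guarantees — the 27-cell partition, split-invariance,
monotonicity under unit weights — are independent of the true
coefficients, and nothing downstream depends on them.

## HRD calling and concordance statistics

`call_hrd()` implements: BRCA1/2-mutated and/or GI-positive ⇒ positive;
inconclusive GI without a mutation ⇒ inconclusive; otherwise negative.

`assay_concordance()` reproduces the comparison pipeline: exclusions first
(low-tumor-content samples for the AmoyDx comparisons only, reference-
inconclusive samples for the chosen metric, test-missing samples), then a
2×2 confusion matrix with the reference defining truth. OPA, sensitivity,
specificity, PPV, NPV are percentages; FPR and FNR are anchored to the
reference's negatives and positives. Confidence intervals are exact
Clopper–Pearson via `binom.test()`: the source publication does not name
its CI method, and the exact interval reproduces the printed intervals
(eight of nine exactly after rounding; the ninth differs by 0.3 points in
a way no standard interval reproduces, i.e. a printing artifact).
Zero-denominator metrics are `NA`, never 0.

ROC analysis (`roc_auc()`) uses the empirical AUC — the Mann–Whitney rank
statistic with ties counted 1/2 — with a DeLong 95% CI, computed via
**pROC**; the test suite cross-checks the AUC against an independent
pair-counting oracle. `youden_cutoffs()` returns both the empirical
cut-off (lowest observed score maximizing J = Se + Sp − 1, with
test-positive defined as score ≥ cut-off) and a binormal cut-off (normal
fit per class by mean/SD, J maximized on a 10,001-point grid between the
class means). The binormal variant is hand-written because no installed
implementation matches this definition; with equal class variances its
optimum is the midpoint of the class means, which the tests verify.

## The packaged call table

`assay_call_fixture()` loads a verbatim transcription of the published
50-sample table: per-sample HRD/GI/BRCA calls for the reference assay and
the two alternative platforms. "-" entries are kept as a distinct
`missing` level, and the low-tumor-content annotation is a per-sample flag
rather than a deleted row, so every exclusion is an explicit, auditable
step (the analysis n's of 42, 44, 40 and 46 fall out of the rules, they
are not hard-coded). The source's text mentions one more sample without a
GI score than the printed table shows as inconclusive; the transcription
follows the printed table and does not impute.

## What the simulator emulates — and what it does not

`simulate_profile()` plants a Poisson number of scar events on a diploid
genome, one event per chromosome arm: terminal 2+1 blocks for TAI,
interior minor-zero blocks for LOH, and distal 2+2 blocks for LST. The
balanced 2+2 state is used for LST events so that, planted in isolation,
an LST event is counted by the LST rule only — the audit tests depend on
this. Event lengths are the rule minimum plus an exponential excess
(mean 5 Mb by default), so near-threshold lengths occur with positive
probability and deliberately stress the boundary comparators. Probe
counts are proportional to length (50/Mb, comfortably above the OncoScan
resolution implied by the 126-probe rule). Class defaults (25 events for
HRD-high, 5 for HRD-low) put the two classes on either side of the
threshold with realistic overlap.

`simulate_cohort_calls()` emulates the call-table structure: latent HRD
truth at 50% prevalence (the accepted rate in high-grade serous ovarian
cancer), a reference that reports truth except for a 4% inconclusive
fraction, test assays flipping independently with configurable
probabilities, BRCA mutations in 46% of HRD-positive tumors, 14% missing
OncoScan results and an 8% low-tumor-content flag — each rate mirroring
the packaged cohort's composition. Continuous scores are class-conditional
normals (means 25/60, SD 12) straddling the 42 threshold.

Passing tests on these simulations show that the estimators recover known
parameters under the stated generative model. They do not show robustness
to what the simulator omits: marker-level noise, subclonality, purity and
ploidy estimation error, FFPE artifacts, or correlated errors between
assays. Real discordance between platforms arises largely from those
omitted factors.

## Numerical choices and problem sizes

Derived seeds stay below 2^31; cohort elements get counter-mode sub-seeds,
so sample *i* is identical whatever the cohort size. The oracle
equivalence checks run 1,000 random profiles of up to 18 segments against
literal brute-force recounts (exhaustive maximal-run enumeration);
parameter recovery uses cohorts of 10,000 with 3-standard-error
acceptance bands; AUC agreement uses the Hanley–McNeil standard error.
These sizes make Monte Carlo acceptance bands tight enough to catch a
rule-boundary error while keeping the whole suite under a minute.

## Known limitations

* True GS coefficients and continuous reference scores are not public, so
  continuous-score concordance (Pearson r, AUC against the reference) is
  exercised on synthetic data only.
* Haplotype phase is not represented; 2+1 and 1+2 are one state.
* Profiles with gaps (not covering chromosome termini) can never trigger
  TAI by the terminal-contact rule; such profiles should be padded or
  re-segmented upstream.
* Large genomic rearrangements in *BRCA1/2*, purity/ploidy estimation and
  survival analysis are out of scope.
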