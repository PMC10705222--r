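# giscar

Genomic instability scar scoring and HRD assay concordance.

Tumors with homologous recombination deficiency (HRD) — common in
high-grade epithelial ovarian cancer — accumulate large chromosomal scars
and respond to PARP inhibitors. Clinical assays call a tumor HRD-positive
when it carries a pathogenic *BRCA1/2* mutation and/or its
genomic-instability (GI) score reaches a threshold, but each platform
computes that score differently. `giscar` is for laboratories and
methodologists who need transparent, parameterized implementations of the
scoring rules and the statistics used to compare a candidate assay against
the reference assay on the same tumors.

The package implements, over allele-specific copy-number (ASCN) segment
profiles:

* **Scar-count engine** — the sum

  `GI = N_LOH + N_TAI + N_LST`

  where `N_LOH` counts loss-of-heterozygosity runs (> 15 Mb, minor copy
  number 0, not spanning a whole chromosome), `N_TAI` counts telomeric
  allelic imbalances (terminal runs with major ≠ minor, > 11 Mb, ≥ 126
  probes, not crossing the centromere) and `N_LST` counts large-scale
  state transitions (junctions between ≥ 10 Mb segments of different
  state, per arm, after 3 Mb smoothing). Positive at `GI ≥ 42`
  (configurable, including the strict `> 42` variant).
* **GS engine** — the 28-feature Genomic Scar model: copy-number events
  cross-classified by length (small/middle/large), site
  (telomere/centromere/other) and type (LOH/allele-specific/
  allele-balanced), 27 cells plus the genome-wide breakpoint count, scored
  linearly (`score = b0 + w · f`, positive at ≥ 50; weights configurable,
  unit weights by default since the published coefficients are
  proprietary).
* **HRD caller** — `HRD-positive ⇔ BRCA1/2 mutation ∨ GI-positive`, with
  inconclusive propagation.
* **Concordance statistics** — cohort exclusion rules, 2×2 confusion
  matrices with OPA/Se/Sp/PPV/NPV/FPR/FNR and exact (Clopper–Pearson) 95%
  CIs, Pearson correlation, empirical ROC/AUC with DeLong CI, and
  Youden-index cut-off selection (empirical and binormal).
* **Synthetic cohorts** — profile simulation with planted, auditable
  TAI/LOH/LST events, and multi-assay call-table simulation with known
  flip probabilities for parameter-recovery validation.

A transcription of the published 50-sample three-assay call table ships
with the package (`assay_call_fixture()`), so the published concordance
analysis is reproducible end to end.

## Worked example

Score a toy profile — one 12 Mb terminal 2+1 segment on an otherwise
diploid 100 Mb chromosome:

```r
library(giscar)
gb <- load_genome("toy3")
prof <- ascn_profile("s1", data.frame(
  chrom = "1", start = c(1, 12e6 + 1), end = c(12e6, 100e6),
  n_probes = c(600, 4400), major_cn = c(2, 1), minor_cn = c(1, 1)))
score_profile(prof, gb)
#> scar_scores s1: LOH 0 + TAI 1 + LST 1 = GI 2 (negative)
```

The terminal imbalance qualifies as one TAI (terminal, 12 Mb > 11 Mb, 600
probes ≥ 126, clear of the centromere) and its junction with the diploid
remainder of the p arm is one LST (both segments ≥ 10 Mb); GI = 2 is far
below the 42 threshold, so the profile is GI-negative.

Reproduce one row of the published comparison from the packaged call
table — AmoyDx GI status against the reference assay:

```r
calls <- assay_call_fixture()
assay_concordance(calls, "amoy", "gi_status")
#> n = 42   [tp 22  fp 6 | fn 1  tn 13]
#> OPA 83.3% (68.6-93.0)  Se 95.7% (78.1-99.9)  Sp 68.4% (43.4-87.4)
#> PPV 78.6%  NPV 92.9%  FPR 31.6%  FNR 4.3%
```

Of the 50 samples, 4 low-tumor-content samples and 4 reference-
inconclusive samples are excluded, leaving 42; the assays agree on 35
(OPA 83.3%). Sensitivity is high (22/23) while specificity is lower
(13/19): the alternative platform calls some reference-negative tumors
positive, which is the recurring pattern across both platforms.

## Analysis workflow

The `analysis/` scripts run the full study pipeline and write their
tables under `results/`:

1. `analysis/01_fixture_concordance.R` — all assay comparisons (GI, HRD
   and BRCA metrics) from the packaged call table, with exact CIs.
2. `analysis/02_synthetic_profiles.R` — simulated HRD-high/low tumor
   profiles scored by both engines; class separation.
3. `analysis/03_parameter_recovery.R` — flip-probability recovery,
   empirical vs closed-form AUC, Youden cut-offs on synthetic cohorts.

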