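# mircna

Integrated copy-number and miRNA expression analysis of AR-negative
triple-negative breast tumors.

## The problem

Triple-negative breast cancers (TNBC) that also lack androgen receptor
expression — quadruple-negative, QNBC — show more genomic instability than
their AR-positive counterparts, and part of that instability propagates to
the miRNA layer: miRNAs located inside recurrently gained or lost regions
can be up- or downregulated in cis. `mircna` is for analysts who want to
reproduce or extend this style of joint analysis: it takes probe-level
array-CGH tables and raw miRNA panel counts for two tumor groups and runs
the complete chain from aberration calling to a discriminating miRNA panel.

## What it computes

* **Aberration calling.** Per chromosome, noise is estimated by the
  derivative MAD, `sigma = MAD(diff(x)) / (0.6745 * sqrt(2))`; every
  interval *I* with score `S(I) = |mean(I)| * sqrt(|I|) / sigma >= 6.0` is a
  candidate; overlaps are resolved greedily by descending score and
  survivors are filtered (>= 3 probes, `|mean| > 0.25`). Calls are
  summarized per sample (unpaired t-test between groups) and as per-group
  cytoband frequencies.
* **CA20 / CIN25 signatures.** Per-gene copy-number comparison in
  mean-probe and interval modes, and summed log2 median-centered expression
  scores with percentile stratification (e.g. AR-low = below the 10th
  percentile).
* **miRNA normalization and DE.** Three-stage geometric-mean normalization
  (negative-control background, positive-control technical factor,
  all-endogenous content factor), then per-miRNA log2FC (QNBC − TNBC),
  Student t-test and Benjamini–Hochberg FDR with the dual threshold
  p < 0.05 and FDR < 0.25.
* **Two-step integration.** Significant miRNAs are mapped to cytoband
  ranges altered in >= 25% (or 30%) of QNBC samples and kept when their
  expression direction matches the copy-number direction; consensus
  predicted targets (>= 2 of 3 databases) are intersected with the genes in
  altered regions, with hypergeometric gene-set enrichment and
  score-filtered PPI networks downstream.
* **Discrimination.** Per-miRNA ROC (Mann–Whitney AUC, DeLong 95% CI) and a
  combined logistic panel (in-sample by default, cross-validated by flag),
  plus clinical covariate associations.

Because the original arrays and counts are not publicly deposited, the
package ships a seeded synthetic-cohort generator (`generate_cohort()`)
with a ground-truth manifest, emulating the study conditions: 19 + 14
arrays, 20 + 12 expression samples, an 827-probe panel, 184 planted group
effects, and eight miRNAs whose carrier-linked effects are
direction-concordant with their host regions.

## Worked example

```r
library(mircna)

dir <- file.path(tempdir(), "cohort")
manifest <- generate_cohort(simulation_config(seed = 1), dir)
report   <- run_pipeline(pipeline_config(dir))

str(report$counts)
```

```
List of 11
 $ n_acgh_samples     : int 33
 $ n_calls            : int 550
 $ n_regions          : int 13
 $ n_mirnas_tested    : int 827
 $ n_de_mirnas        : int 258
 $ n_mapped_records   : int 15
 $ n_mapped_mirnas    : int 15
 $ n_concordant_mirnas: int 8
 $ n_consensus_genes  : int 165
 $ n_surviving_genes  : int 60
 $ reduction_pct      : num 63.6
```

Reading: 33 arrays produced 550 aberration calls (QNBC mean 19.2 per
sample vs TNBC 13.2, t-test p = 8.4e-05 in `report$summary`); 258 of 827
miRNAs pass the dual DE threshold; 15 of them map to cytoband ranges
altered in >= 25% of QNBC samples, and 8 are direction-concordant — exactly
the eight planted in the manifest. Their consensus targets shrink from 165
genes to the 60 lying in altered regions (a 63.6% reduction), and the
eight-miRNA logistic panel separates the groups:

```r
tail(report$roc, 3)
```

```
              id       auc    ci_low ci_high
7    hsa-miR-613 0.8458333 0.6890889       1
8    hsa-miR-943 0.9625000 0.9000803       1
9 combined_panel 1.0000000 1.0000000       1
```

Individual AUCs are moderate; the combined in-sample panel reaches 1.0 on
this synthetic cohort (use `cv_folds` in `pipeline_config()` for a
cross-validated estimate).

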