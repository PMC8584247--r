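---
title: "Integrated copy-number and miRNA expression analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated copy-number and miRNA expression analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`mircna` implements a joint analysis of array-CGH copy-number profiles and
miRNA panel expression in androgen-receptor-negative (quadruple-negative,
QNBC) versus AR-positive triple-negative (TNBC) breast tumors. The analysis
has five stages:

1. **Aberration calling** on probe-level log2 ratios, with per-sample call
   summaries and per-cytoband, per-group frequency profiling.
2. **Signature copy number**: per-gene group comparison of the CA20
   (centrosome amplification) and CIN25 (chromosomal instability) gene sets,
   in both mean-probe and interval-based reporting modes; plus summed
   median-centered expression scores with percentile stratification for
   external expression cohorts.
3. **miRNA expression**: three-stage geometric-mean normalization of raw
   panel counts, differential expression with Benjamini–Hochberg FDR, and
   supervised hierarchical clustering.
4. **Integration**: mapping of differentially expressed miRNAs to frequent
   copy-number-altered cytobands with direction concordance, then
   intersection of consensus predicted targets with genes in altered
   regions, gene-set overlap enrichment, and PPI network filtering.
5. **Discrimination**: per-miRNA and combined-panel ROC, and association of
   miRNA expression with clinical covariates.

A seeded synthetic-cohort generator with a ground-truth manifest makes the
whole chain testable end to end without any external data.

# The aberration caller

Arrays report a log2 ratio per probe (tumor over reference). Commercial
pipelines segment these with proprietary algorithms whose published
descriptions reduce to an interval score compared against a threshold. We
implement that score family explicitly so every parameter is auditable:

* Per chromosome, the noise level is estimated by the **derivative MAD**:
  $\hat\sigma = \mathrm{MAD}(x_{i+1} - x_i) / (0.6745\sqrt{2})$. Differencing
  cancels segment means (a few boundary terms aside) and doubles the
  variance, hence the $\sqrt 2$; the $0.6745$ makes the MAD consistent for a
  normal scale. Chromosomes with fewer than 4 probes are skipped (the
  estimate is undefined) with a warning.
* Every interval $I$ with score $S(I) = |\bar x_I|\sqrt{|I|}/\hat\sigma \ge
  6.0$ is a candidate. Candidates are resolved greedily: accept the best
  remaining candidate (descending score, ties broken by leftmost start, then
  longest interval) and discard everything overlapping it. The tie-break
  makes the caller fully deterministic.
* Survivors are filtered: at least 3 probes and $|\bar x_I| > 0.25$; the
  direction is the sign of the interval mean. Filtering happens *after*
  greedy resolution, so a high-scoring but low-amplitude interval shadows
  its sub-intervals rather than yielding spurious fragments.

On a noise-free chromosome $\hat\sigma = 0$; we floor it at $10^{-8}$ so
that constant planted segments score effectively infinite and remain
callable, while flat background (mean exactly 0) still scores 0. The caller
is verified in the test suite against an exhaustive all-intervals oracle on
every instance up to 200 probes.

Recurrent regions are derived by merging all calls of one direction across
samples and rendering each merged interval as a cytoband range (first to
last overlapped band, e.g. `8q21-q24.3`). A sample is *affected* for a
(region, direction) pair if any of its calls of that direction overlaps the
region; frequencies are percentages per group.

# Count normalization

Raw panel counts are normalized per sample in three stages, mirroring the
standard codeset workflow (background from negative controls, technical
factor from positive controls, content factor from all endogenous probes):

1. subtract the sample's geometric mean of negative-control counts from
   every count, flooring at 0;
2. multiply by $\bar P / P_s$, where $P_s$ is the sample's geometric mean of
   positive controls and $\bar P$ the grand mean of the $P_s$;
3. multiply by the analogous factor computed over the endogenous rows of the
   *current* (background-subtracted, technically normalized) matrix;
4. take $\log_2(x + 1)$.

Two numerical choices matter. First, geometric means floor their inputs at 1
(a zero count would otherwise annihilate the mean). Second, the content
factor is computed on the post-stage-2 values, not the raw counts. Together
these make the chain *exactly* invariant to a per-sample scale factor
applied to all rows — the property a lane-correction procedure must have,
and one the test suite asserts at `1e-12` tolerance. An additive pseudocount
inside the geometric means would break this exactness, which is why the
floor form was chosen. The audit trail (per-sample background, positive-
control factor, content factor) is returned alongside the matrix.

# Differential expression and clustering

Per endogenous miRNA we report $\log_2$FC as mean(QNBC) − mean(TNBC) of the
log2 values (so negative values mean lower in QNBC), a two-sided unpaired
Student t-test (Welch available by flag), and Benjamini–Hochberg q-values
over all tested miRNAs. A miRNA is *significant* when $p < 0.05$ **and**
$q < 0.25$ — the dual threshold used throughout. Degenerate rows (zero
variance in both groups) get $p = 1$ when the means agree and $p = 0$
otherwise, keeping the noiseless limit well defined. No expression floor
filter is applied by default; the full panel enters the FDR correction.

Supervised clustering of the significant miRNAs uses Pearson correlation
distance ($1 - r$) with average linkage on both axes — the convention of the
desktop tools historically used for such heatmaps. The metric is
configurable; constant rows are dropped with a warning because their
correlations are undefined.

# Signatures

`ca20_signature()` and `cin25_signature()` ship the 20- and 25-gene sets as
printed in the source literature. Several CIN25 symbols are legacy
nomenclature (`CDC2`, `CNAP1`, `C20orf24-TGIF2`, `CDC45L`, `H2AFZ`); a
shipped alias table resolves them to current HGNC symbols, and unresolvable
symbols are reported as missing rather than silently dropped.

Copy-number comparison restricts the gene-level matrix (mean-probe or
interval mode; interval mode assigns 0, copy-neutral, to genes outside all
calls) to the signature and runs per-gene Student t-tests. Expression
scores subtract each gene's across-sample median and sum the centered
values per sample ("log2 median-centered, summed unweighted"); a sample at
every median scores exactly 0, and scores are additive over disjoint
signatures. Percentile stratification uses the linear-interpolation
quantile with a strict `<` cut — ties at the threshold go to "high" — and
reports the threshold used. With 90 distinct values and the 10th
percentile this yields a 9/81 split.

# Integration

Stage one pairs each significant miRNA, located by its annotated locus,
with every (cytoband range, direction) whose frequency in the QNBC group
reaches the threshold. The source analysis states both "more than 25%" and
"at least 30%" in different places; the default is 0.25 with 0.30 available
as a preset, and the group is configurable. A miRNA overlapping any band of
a range counts as inside it; one record is emitted per (miRNA, range) pair
and the concordant miRNA list is the distinct-miRNA projection. Concordance
means expression moving with copy number (gain ∧ up, or loss ∧ down);
$\log_2$FC exactly 0 is non-concordant.

Stage two keeps predicted (miRNA, target) pairs present in at least 2 of
the 3 supplied prediction tables, then intersects the consensus genes with
the genes located in retained CNA ranges, reporting the percent reduction.
Gene-set overlap uses the upper-tail hypergeometric test with an explicit
universe (the annotated gene loci) and BH correction; the PPI step drops
edges below score 0.9 and nodes left without connections, then attaches
miRNA→target edges as a second edge class.

Per-sample alteration counts need a definition of "altered expression",
which the source analysis does not give. We count a concordant miRNA as
altered in a sample when its log2 expression deviates from the
reference-group (TNBC) mean by more than $k$ reference SDs *in the
direction of its group-level fold change*, with $k = 1$ by default and
configurable.

# Discrimination

Single-marker AUC uses the rank (Mann–Whitney) formulation with tie
correction and a DeLong 95% CI; orientation is chosen so AUC ≥ 0.5 with the
flip recorded. The combined panel fits a logistic score on standardized
member expression; the default reports the in-sample (apparent) AUC —
matching how combined panels are conventionally reported at this cohort
size — with stratified k-fold cross-validation available. The CV score is
evaluated with a *fixed* orientation (higher score = case class): flipping
a cross-validated score would bias a null panel away from AUC 0.5, which
the permutation-null test would catch. Perfect separation triggers a
ridge-stabilized fallback (`glmnet`, $\alpha = 0$, $\lambda = 0.01$) and is
flagged.

Clinical comparisons select Fisher's exact test when any expected cell
count is below 5 and the chi-squared test (without continuity correction)
otherwise; continuous variables default to the t-test with a
Wilcoxon–Mann–Whitney flag, since the source analysis lists both without
assignment. miRNA–covariate associations use linear regression (miRNA as
outcome) for continuous covariates and report both t-test and logistic
routes for binary ones.

# The synthetic cohort

The study's arrays and counts are not publicly deposited, so the package
ships a generator whose defaults emulate the study conditions: 33 tumors
with aCGH (19 QNBC / 14 TNBC), 32 with miRNA counts (20 / 12), an
827-probe panel with 6 positive, 8 negative, 5 housekeeping and 5 spike-in
controls, and 184 planted group effects of which 112 are down- and 72
upregulated in QNBC.

* **Genome**: 11 toy chromosomes (675 Mb total) with a coarse cytoband
  grid; probes every 200 kb by default (tests use 0.5–1 Mb spacing; the
  spacing only changes probe counts, not the planted structure).
* **Planted regions**: eight recurrent regions, one per chromosome so calls
  from distinct regions can never merge into one interval. Each spans a
  full band run, has a direction, a constant amplitude (±0.6–0.8), and
  per-group carrier frequencies drawn per sample as Bernoulli variables and
  recorded in the manifest. The four regions hosting the eight concordant
  miRNAs use a strong frequency contrast (≈0.9 QNBC vs ≈0.15–0.21 TNBC):
  a carrier-linked expression effect is diluted by the frequency contrast,
  so host regions must be strongly differential for the planted concordant
  miRNAs to be recoverable — consistent with the fact that the eight
  reported miRNAs were themselves significantly differential. The remaining
  regions use frequency contrasts typical of recurrent-CNA tables.
* **Private segments**: per-sample Poisson numbers (mean 20 QNBC / 12.5
  TNBC) of short segments confined to two filler chromosomes that carry no
  gene or miRNA loci, so per-sample call counts average near the reported
  ~25 vs ~15 without ever contaminating the integration.
* **Counts**: log-normal; an endogenous count is
  $\mathrm{lane}_s \cdot 2^{\mu_i + e_{is} + N(0, 0.5)}$ with a per-sample
  lane factor $2^{N(0,0.15)}$. Ordinary planted miRNAs get their effect
  group-wide; the eight concordant miRNAs get theirs only in carrier
  samples of their host region, in the region's direction. Counts are kept
  continuous so the noiseless limit is exact (e.g. a planted $\log_2$FC of
  2 at zero dispersion gives an exact 4× ratio). Four concordant miRNAs
  additionally carry a +0.8 log2 shift in metastatic samples (one a −0.8
  shift), defining the planted clinical associations.
* **Targets, sets, edges**: every planted (miRNA, target) pair appears in 2
  or 3 of the three prediction tables, decoys in exactly 1, so consensus
  output is known by construction; gene sets are seeded with planted
  surviving genes; the PPI table has a connected high-confidence core and
  deliberately isolated genes.

The `noiseless_config()` preset zeroes every noise source and fixes host
frequencies at 1/0; `expected_integration()` then predicts the retained
regions, concordant miRNA set and surviving target genes in closed form
from the manifest, and the test suite asserts exact recovery.

**What the generator does not emulate**: scanner artifacts, GC waves,
tumor purity mixtures, FFPE degradation, probe-specific biases, and
count discreteness. Passing tests therefore demonstrate correctness of the
analysis logic under a clean generative model, not robustness to real
array or count pathologies.

# Problem sizes and runtime

Defaults were chosen so a full synthetic run is interactive: ~3,400 probes
per array at 200 kb spacing (about 45 s for generation plus the full
pipeline), with the test suite using coarser grids (0.5–1 Mb, a few
seconds per run). The caller's candidate enumeration is quadratic per
chromosome, which is comfortable at these sizes and exact — no heuristic
pruning is applied. Monte-Carlo checks use 15–20 seeds each: the
differential-expression type-I error check pools 16,000 null p-values, and
the permutation-null cross-validated panel check uses 20 permutations with
5-fold stratified CV.

# Known limitations

* The caller is an interval-score segmentation, not a reimplementation of
  any proprietary algorithm; with the same threshold semantics it will not
  reproduce another tool's calls probe-for-probe on real arrays.
* Interval-mode gene copy number assigns 0 to genes outside calls, which
  under-dispersions genes in borderline regions.
* The hypergeometric enrichment replaces service-based pathway analysis;
  results depend on the supplied universe and gene sets.
* In-sample panel AUC is optimistic by construction; use `cv_folds` for an
  honest estimate.
* Overlap is strand-blind throughout, as cytoband mapping is.
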