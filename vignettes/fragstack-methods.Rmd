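---
title: "Methods: cfDNA fragmentomics features and the stacked ensemble"
author: "fragstack maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA fragmentomics features and the stacked ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

fragstack classifies plasma samples as cancer-like or healthy-like from
shallow whole-genome sequencing of cell-free DNA (cfDNA). It extracts three
feature families per sample and combines them in a stacked ensemble:

- **CNV** — per-bin copy-number log2 ratios. The genome is tiled into 1-Mb
  bins; fragment counts per bin are GC-corrected, mappability-adjusted,
  depth-normalized, divided by a Panel of Normals (PoN), log2-transformed and
  median-centered so a diploid autosomal genome sits at 0. A heterozygous
  gain (copy number 3) diluted at tumor fraction $tf$ shifts its bins to
  approximately $\log_2(1 + tf/2)$; a single-copy loss to
  $\log_2(1 - tf/2)$.
- **FSD** — fragment size distributions per chromosome arm. Fragment lengths
  in the mono-nucleosomal range are histogrammed in 5-bp bins from 110 bp
  (24 bins per arm, covering [110, 230)); counts are GC-corrected across
  arms per size bin and z-scored per feature. Tumor-derived cfDNA is
  shorter than nucleosomally protected healthy cfDNA, so low-size bins gain
  mass in cancer samples.
- **FRAGMA** — 21 ratios of fragment 5' end motifs in Alu repeats, a proxy
  for CpG methylation: methylation shifts nuclease cleavage registers
  around CpG sites, which moves density between CGN-type and NCG-type
  3-mer end motifs and between the four cleavage registers of CGCG runs
  (NCG split by its flanking base, CGC, GCG, and CGN split by its trailing
  base). The ten CGCG-register ratios partition the CGCG-context events and
  sum to 1; two ratio-of-ratio features (CGC/NCG, CGN/CGC) complete the
  block.

Under the hg19 presets the blocks are 2,475 + 936 + 21 = 3,432 features.

# Coordinate and counting conventions

Internally everything lives in Bioconductor 1-based closed coordinates
(`GRanges`); BED input/output is converted at the boundary. Decisions that
the feature definitions leave open were fixed once and are part of the
contract:

- A fragment belongs to the bin/arm containing its **midpoint**
  (`floor((start0 + end0)/2)`), so boundary-straddling fragments count
  exactly once.
- Size bins are **half-open**: length 114 falls in bin "110", length 115 in
  bin "115". The 24-bin layout at 5 bp from 110 bp is a declared
  convention: it honors the 39 × 24 = 936 feature accounting over the
  nominal upper endpoint of the size range.
- Both fragment termini contribute a 5' end motif: the left end read on the
  forward strand, the right end as the reverse complement of the last three
  bases (5'→3' on the reverse strand). `endMode = "left_only"` restores a
  single-end reading.
- An end event enters FRAGMA only if its 5' terminal base lies inside an
  Alu interval and its motif is N-free. CGCG occurrences are located on
  both strands (the motif is its own reverse complement, so forward matches
  enumerate both orientations); an event matches a register only on the
  matching strand. Where chained occurrences (CGCGCG...) let one position
  claim two registers, the more specific class wins (CGC > GCG > NCG >
  CGN).
- The denominator of the ten CGCG-register ratios is the total number of
  CGCG-context events, making them a proper partition; zero denominators in
  ratio-of-ratio features fall back to a pseudo-count of 1 with a warning,
  so the feature matrix never contains NaN.

# Normalization choices

- LOESS ratio correction (`corrected = y * median(y) / fitted(y ~ gc)`)
  uses span 0.75 and **locally linear** fits: at arm-level sample sizes
  (tens of points) locally quadratic fits chase Poisson noise; the
  locally linear fit leaves a flat profile essentially unchanged while
  removing monotone GC trends. Degenerate covariates (all-equal GC) skip
  the correction with a warning. Guards: fewer than 20 kept bins (CNV) or
  10 arms (FSD) skip correction rather than extrapolate.
- The PoN is the per-bin **median** of GC-corrected, mappability-adjusted,
  sum-normalized healthy profiles; at least 3 samples are required, and
  zero medians are floored to the smallest positive panel value.
- FSD z-scores use mean and sample standard deviation (n − 1) **fitted on
  the training split only** and frozen into the model. Standardizing across
  all samples (the `normalization = "all"` switch) reproduces designs that
  pool cohorts but leaks validation statistics into the features; the
  default refuses that.
- GC bounds [0.28, 0.68] and mappability threshold 0.9 for bin keep rules
  are exposed configuration, not constants of nature.

# The ensemble

Six learner families are fitted per feature block: regularized logistic
regression (GLM; ridge by default), extremely randomized trees (XRT),
random forest (DRF), a feedforward neural network (DeepLearning), and two
gradient-boosting configurations (GBM: exact greedy trees with row
subsampling; XGBoost: histogram trees with column sampling and explicit
L1/L2 regularization). The neural network uses a single hidden layer with
weight decay on standardized inputs — at these sample sizes additional
depth adds variance, not capacity. Hyperparameters default to fixed
mid-grid values; `gridBudget > 1` draws random candidates per family and
keeps the best by out-of-fold AUC.

Training uses stratified 5-fold cross-validation: every training sample
receives an out-of-fold (OOF) score from every (block × family) model, the
OOF stacked score selects the best of the 7 non-empty block subsets, and
all base models are refit on the full training cohort for deployment. The
deployed score is the unweighted **mean** of base scores (`combination =
"meta_glm"` fits a second-layer logistic model on the OOF scores instead;
both are provided because score averaging and a GLM second layer are both
defensible stacking rules here). Ties in subset selection resolve toward
the fuller stack.

The decision cutoff is the smallest threshold at which the fraction of
healthy **OOF** training scores below it reaches the target specificity
(default 95%). OOF scores are training data but are not resubstitution
scores, so the anchored specificity is not optimistically biased. Samples
scoring at or above the cutoff are called cancer.

# Evaluation

AUC is the Mann–Whitney pairwise rank statistic (ties count ½); the ROC
curve enumerates observed scores as thresholds, and its trapezoidal area
equals the rank AUC by construction. Confusion metrics follow the standard
definitions (sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV, NPV,
accuracy), each with an exact Clopper–Pearson 95% interval; metrics with
zero denominators are reported as NA rather than NaN. Stratified reports
give per-stratum sensitivity among true cancers, pooling unknown stratum
labels and flagging strata below 5 samples.

# The simulator: what it emulates, and what it does not

`simulationConfig()` fixes the study conditions; `buildToyGenome()` and
`simulateCohort()` realize them. Defaults: 5 chromosomes × 3 Mb with a
sinusoidal GC field in [0.3, 0.7]; 300 Alu-like 300-bp regions per Mb
(roughly the genomic Alu fraction) with CGCG planted at 5× the background
rate; healthy lengths 0.95·N(167, 10) + 0.05·N(320, 20) clamped to
[60, 500]; tumor lengths N(145, 12); planted segments CN=3 over half of
chromosome 2 and CN=1 over half of chromosome 3 (balanced, so the dosage
closed form is exact); 15% of fragment ends cleaved at CpG sites in Alu,
with tumor-origin fragments up-weighting CGN-register cleavage 2:1; mean
coverage 0.3×. Each fragment is tumor-origin with probability tf;
tumor-origin fragments use the tumor length mode, dosage-weighted
positions, and the biased cleavage weights. Cleavage snapping moves an end
to the *nearest* CpG site, preserving the dosage field.

Cohort sizes default to the training-shaped 119 cancer / 112 healthy;
desk-scale studies in the tests and the acceptance script use 60+60
training and 30+30 validation samples (with 24+24 / 40+40 for null
calibration), sizes chosen so a full five-seed study runs on one CPU in
minutes while keeping binomial noise on AUC small. "Stage" is a
deterministic tumor-fraction tertile used only to exercise stratified
reporting.

The simulator carries exactly the three signal axes the extractors read
out, with truncated-normal size mixtures rather than nucleosome-ladder
models, no sequencing error or base-quality structure, no real Alu
consensus sequences, and no GC-coverage coupling. Passing tests therefore
demonstrate that the pipeline recovers planted signals of realistic effect
size and produces calibrated nulls — not that real-plasma performance
matches any published cohort.

# Reproducibility and numerical details

Every stochastic stage (genome realization, fragment draws, folds, grids,
learner internals) derives a child seed from one master seed; all learners
run single-threaded, so reruns are bit-identical. The hg19 presets ship as
data files; the bin keep-mask is a synthetic stand-in constructed from
centromere/gap geometry and calibrated once to the conventional 2,475-bin
autosomal feature space (real analyses should derive their own manifest
from GC and mappability tracks via `buildBinManifest()`). Known
limitations: no sex-chromosome handling, no absolute copy-number or
tumor-fraction estimation (the CNV block feeds the classifier directly; no
HMM segmentation), and no liftover between assemblies.
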