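# fragstack

Stacked-ensemble classification of plasma cfDNA fragmentomics profiles.

Tumor-derived cell-free DNA (cfDNA) leaves three complementary fingerprints
in shallow whole-genome sequencing of plasma: local coverage tracks somatic
copy-number dosage, fragment lengths shift toward sub-nucleosomal sizes, and
nuclease cleavage registers around CpG sites move with methylation state.
fragstack is for developers and evaluators of liquid-biopsy classifiers: it
extracts all three feature families from aligned fragments, trains a stacked
ensemble over six learner families, and evaluates it with the standard
screening metrics — plus a built-in cohort simulator with a tumor-fraction
dial so the whole pipeline can be exercised and audited without patient
data.

## The features and the model

Per sample, from fragment intervals (BAM or BED) and a reference genome:

- **CNV** (one feature per kept 1-Mb bin): fragment counts per bin →
  LOESS GC correction → mappability adjustment → depth normalization →
  division by a Panel of Normals (per-bin median over healthy samples) →
  log2, median-centered so diploid = 0. A CN=3 segment at tumor fraction
  *tf* sits near log2(1 + *tf*/2).
- **FSD** (24 size bins × included arms): fragment length histograms in
  [110, 230) bp at 5-bp steps per chromosome arm, GC-corrected across arms,
  z-scored with training-cohort statistics, z = (x − µ)/σ.
- **FRAGMA** (21 features): 5′ end-motif ratios in Alu repeats — the four
  CGN and four NCG 3-mer ratios and their CGN/NCG quotient, plus ten
  cleavage-register ratios around CGCG runs and the CGC/NCG and CGN/CGC
  quotients.

Under the shipped hg19 presets this is 2,475 + 936 + 21 = 3,432 features.
Each feature block feeds six base classifiers (regularized logistic
regression, extremely randomized trees, random forest, a feedforward net,
and two gradient-boosting configurations); stratified 5-fold out-of-fold
scores select the best block subset and anchor a decision cutoff at 95%
training specificity; the deployed cancer score is the mean of the base
scores (a second-layer logistic stacker is available). Evaluation reports
the Mann–Whitney AUC, ROC curves, and sensitivity / specificity / PPV /
NPV / accuracy with exact Clopper–Pearson intervals, overall and per
stratum.

## Worked example

```r
library(fragstack)

cfg    <- simulationConfig()              # 5 x 3 Mb toy genome, 0.3x depth
assets <- buildToyGenome(cfg, seed = 1)
res    <- runEndToEnd(seed = 1, assets = assets,
                      nTrain = c(60, 60), nVal = c(30, 30),
                      tfRange = c(0.05, 0.3))
res$valAuc
#> [1] 1
round(res$blockAuc, 3)
#>    cnv    fsd fragma
#>  0.993  1.000  0.969
res$model
#> TrainedEnsemble: 18 base models (cnv+fsd+fragma x GLM,XRT,DRF,DeepLearning,GBM,XGBoost)
#>   combination: mean; selected blocks: fsd
#>   cutoff 0.06616 (training specificity 0.95)
res$metrics$counts
#> tp fp tn fn
#> 30  1 29  0
```

Reading: on a simulated validation cohort (30 cancer at tumor fractions
0.05–0.3, 30 healthy) the stacked score separates the classes completely
(AUC 1); the fragment-size block is the strongest single family — here it
is strong enough that the out-of-fold block-subset search keeps it alone —
and at the training-derived 95%-specificity cutoff the model detects 30/30
cancers with one false positive. A null study (`tfRange = c(0, 0)`) gives AUC near
0.5 — the pipeline leaks no labels.

Feature-space accounting against the hg19 presets:

```r
featureSpaceDims(hg19BinManifest(), hg19ArmTable())
#>   cnv    fsd fragma  total
#>  2475    936     21   3432
```

A thin CLI over the same functions is in `inst/scripts/fragstack`
(subcommands `run`, `simulate`, `extract`, `evaluate`), and
`runPipeline()` drives the chain from a YAML config with run manifests and
output caching.

## Scope notes

The hg19 bin keep-mask is a labelled synthetic stand-in (constructed from
centromere/gap geometry, calibrated to the conventional 2,475-bin autosomal
space); derive a real manifest from GC/mappability tracks with
`buildBinManifest()` for production use. The simulator carries exactly the
three signal axes the extractors measure — see the methods vignette
(`vignettes/fragstack-methods.Rmd`) for what that does and does not
demonstrate about real plasma.
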