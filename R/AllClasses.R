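#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom GenomeInfoDb Seqinfo
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

#' Fragments of one cfDNA sample
#'
#' Container for the aligned fragments of a single plasma sample: a
#' \linkS4class{GRanges} of fragment intervals (1-based, closed; one range per
#' sequenced DNA molecule) carrying per-fragment metadata columns
#' \code{motifLeft} and \code{motifRight} (the two 5' terminal 3-mers, each
#' reported 5'->3' on its own strand) and \code{mapq}. Filter counters
#' accumulated while reading (duplicates, mapq failures, off-reference
#' fragments, N-containing motifs) are kept in \code{counters}.
#'
#' @slot sampleId single sample identifier.
#' @slot fragments \linkS4class{GRanges} with mcols \code{motifLeft},
#'   \code{motifRight}, \code{mapq}.
#' @slot counters named numeric vector of reader/filter counters.
#' @slot metadata free-form list.
#' @aliases SampleFragments
#' @exportClass SampleFragments
setClass("SampleFragments",
  slots = c(
    sampleId = "character",
    fragments = "GRanges",
    counters = "numeric",
    metadata = "list"
  )
)

setValidity("SampleFragments", function(object) {
  msg <- NULL
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-NA string")
  need <- c("motifLeft", "motifRight", "mapq")
  have <- colnames(S4Vectors::mcols(object@fragments))
  if (!all(need %in% have))
    msg <- c(msg, sprintf("fragments must carry mcols: %s",
                          paste(setdiff(need, have), collapse = ", ")))
  if (length(object@fragments) && any(GenomicRanges::width(object@fragments) < 1))
    msg <- c(msg, "all fragment widths must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Panel of Normals for CNV normalization
#'
#' Per-bin reference statistics from a panel of healthy cfDNA samples:
#' the median of GC-corrected, mappability-adjusted, depth-normalized bin
#' proportions across the panel. Log2 ratios of a test sample are taken
#' against these medians, cancelling platform and library-preparation depth
#' bias shared by all samples.
#'
#' @slot manifestHash md5 of the bin manifest the panel was built on; predict
#'   time refuses a mismatched manifest.
#' @slot medians per-kept-bin median normalized proportion (positive).
#' @slot panelSize number of healthy samples in the panel.
#' @aliases PanelOfNormals
#' @exportClass PanelOfNormals
setClass("PanelOfNormals",
  slots = c(
    manifestHash = "character",
    medians = "numeric",
    panelSize = "integer"
  )
)

setValidity("PanelOfNormals", function(object) {
  msg <- NULL
  if (any(!is.finite(object@medians)) || any(object@medians <= 0))
    msg <- c(msg, "all PoN medians must be finite and > 0")
  if (object@panelSize < 3L)
    msg <- c(msg, "panel too small: at least 3 healthy samples required")
  if (is.null(msg)) TRUE else msg
})

#' Per-feature z-score normalizer for FSD features
#'
#' Training-cohort mean and standard deviation (sample sd, n-1 denominator)
#' for every arm x size-bin feature, frozen at fit time and bundled with the
#' model so validation samples are standardized against training statistics
#' only. Features with zero training variance are flagged degenerate and
#' their z-scores forced to 0.
#'
#' @slot mu,sigma per-feature mean / sd over the training cohort.
#' @slot featureNames arm-major, bin-minor labels, e.g. \code{"1p_110"}.
#' @slot degenerate logical, TRUE where sigma was 0.
#' @aliases FsdNormalizer
#' @exportClass FsdNormalizer
setClass("FsdNormalizer",
  slots = c(
    mu = "numeric",
    sigma = "numeric",
    featureNames = "character",
    degenerate = "logical"
  )
)

setValidity("FsdNormalizer", function(object) {
  n <- length(object@mu)
  if (length(object@sigma) != n || length(object@featureNames) != n ||
      length(object@degenerate) != n)
    return("mu, sigma, featureNames and degenerate must have equal length")
  if (any(object@sigma < 0)) return("sigma must be non-negative")
  if (any(object@sigma[!object@degenerate] <= 0))
    return("non-degenerate features must have sigma > 0")
  TRUE
})

#' Per-sample fragmentomics feature matrix
#'
#' Thin wrapper around \linkS4class{SummarizedExperiment}: one assay
#' \code{"features"} with features in rows (grouped in named blocks
#' \code{cnv}, \code{fsd}, \code{fragma}; \code{rowData(x)$block}) and
#' samples in columns (\code{colData}: \code{label}, \code{split}, and any
#' simulator truth such as \code{tf} and \code{stage}). The FSD normalizer
#' and the PoN hash used during extraction ride along in \code{metadata()}
#' so prediction can reuse them without refitting.
#'
#' @aliases FragFeatureSet
#' @exportClass FragFeatureSet
setClass("FragFeatureSet", contains = "SummarizedExperiment")

setValidity("FragFeatureSet", function(object) {
  msg <- NULL
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!"block" %in% colnames(rd))
    msg <- c(msg, "rowData must carry a 'block' column")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("label", "split") %in% colnames(cd)))
    msg <- c(msg, "colData must carry 'label' and 'split'")
  else if (!all(cd$label %in% c("cancer", "healthy")))
    msg <- c(msg, "labels must be 'cancer' or 'healthy'")
  a <- SummarizedExperiment::assay(object, "features")
  if (length(a) && any(!is.finite(a)))
    msg <- c(msg, "feature matrix must be finite (extraction guards failed)")
  if (is.null(msg)) TRUE else msg
})

#' Fitted stacked ensemble
#'
#' The deployable model bundle: base classifiers for every retained
#' (feature-block x learner-family) pair refit on the full training cohort,
#' the out-of-fold score matrix they produced under stratified k-fold
#' cross-validation, the score combination rule (unweighted mean or a
#' second-layer logistic model), the block subset selected by out-of-fold
#' AUC, the decision cutoff anchored at the target training specificity, and
#' the frozen preprocessing (FSD normalizer, PoN) needed to featurize new
#' samples identically.
#'
#' @slot baseModels list keyed "block.family" of fitted base learners.
#' @slot families,blocks learner families and feature blocks trained.
#' @slot selectedBlocks block subset used by the deployed score.
#' @slot combination \code{"mean"} or \code{"meta_glm"}.
#' @slot metaModel second-layer logistic fit (empty list under "mean").
#' @slot cutoff decision threshold on the cancer score.
#' @slot cutoffSpecificity specificity achieved on training healthy scores.
#' @slot oofScores out-of-fold base score matrix (train samples x models).
#' @slot oofStacked out-of-fold stacked training scores.
#' @slot folds integer fold assignment of training samples.
#' @slot trainLabels training labels (for reporting only).
#' @slot preprocess list: \code{fsdNormalizer}, \code{pon}, feature layout.
#' @slot seed integer seed the fit derived all randomness from.
#' @aliases TrainedEnsemble
#' @exportClass TrainedEnsemble
setClass("TrainedEnsemble",
  slots = c(
    baseModels = "list",
    families = "character",
    blocks = "character",
    selectedBlocks = "character",
    combination = "character",
    metaModel = "list",
    cutoff = "numeric",
    cutoffSpecificity = "numeric",
    oofScores = "matrix",
    oofStacked = "numeric",
    folds = "integer",
    trainLabels = "character",
    preprocess = "list",
    seed = "integer"
  )
)

setValidity("TrainedEnsemble", function(object) {
  msg <- NULL
  if (!object@combination %in% c("mean", "meta_glm"))
    msg <- c(msg, "combination must be 'mean' or 'meta_glm'")
  if (length(object@cutoff) != 1L || object@cutoff < 0 || object@cutoff > 1 + 1e-9)
    msg <- c(msg, "cutoff must be a single value in [0, 1]")
  if (!all(object@selectedBlocks %in% object@blocks))
    msg <- c(msg, "selectedBlocks must be a subset of blocks")
  if (is.null(msg)) TRUE else msg
})

#' Toy genome bundle emitted by the simulator
#'
#' Reference sequence plus every manifest the extractors need, built once per
#' simulated study: chromosome table (as \linkS4class{Seqinfo}), arm table,
#' CNV bin manifest, and the planted Alu-like region set.
#'
#' @slot reference \code{DNAStringSet} of chromosome sequences.
#' @slot seqinfo \linkS4class{Seqinfo} (the chromosome table).
#' @slot arms arm \linkS4class{GRanges} (mcols \code{armId}, \code{excluded},
#'   \code{gc}).
#' @slot bins bin manifest \linkS4class{GRanges} (mcols \code{gc},
#'   \code{mappability}, \code{keep}).
#' @slot alu merged Alu-like region \linkS4class{GRanges}.
#' @slot config the \code{simulationConfig()} the genome was built from.
#' @aliases GenomeAssets
#' @exportClass GenomeAssets
setClass("GenomeAssets",
  slots = c(
    reference = "DNAStringSet",
    seqinfo = "Seqinfo",
    arms = "GRanges",
    bins = "GRanges",
    alu = "GRanges",
    config = "list"
  )
)
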