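#' Accessors for fragstack classes
#'
#' Small accessor layer so downstream code never touches slots directly:
#' \code{sampleId()} and \code{fragments()} for \linkS4class{SampleFragments};
#' \code{ponMedians()} / \code{panelSize()} for \linkS4class{PanelOfNormals};
#' \code{featureBlocks()} / \code{featureBlockNames()} for
#' \linkS4class{FragFeatureSet}; \code{modelCutoff()},
#' \code{selectedBlocks()} and \code{oofScores()} for
#' \linkS4class{TrainedEnsemble}.
#'
#' @param x an object of the corresponding class.
#' @param name for \code{featureBlocks}, a block name such as \code{"fsd"}.
#' @return The slot content (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "SampleFragments", function(x) x@sampleId)

#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setMethod("fragments", "SampleFragments", function(x) x@fragments)

#' @rdname accessors
#' @export
setGeneric("readCounters", function(x) standardGeneric("readCounters"))
#' @rdname accessors
#' @export
setMethod("readCounters", "SampleFragments", function(x) x@counters)

#' @rdname accessors
#' @export
setGeneric("ponMedians", function(x) standardGeneric("ponMedians"))
#' @rdname accessors
#' @export
setMethod("ponMedians", "PanelOfNormals", function(x) x@medians)

#' @rdname accessors
#' @export
setGeneric("panelSize", function(x) standardGeneric("panelSize"))
#' @rdname accessors
#' @export
setMethod("panelSize", "PanelOfNormals", function(x) x@panelSize)

#' @rdname accessors
#' @export
setGeneric("featureBlockNames", function(x) standardGeneric("featureBlockNames"))
#' @rdname accessors
#' @export
setMethod("featureBlockNames", "FragFeatureSet", function(x)
  unique(as.character(SummarizedExperiment::rowData(x)$block)))

#' @rdname accessors
#' @export
setGeneric("featureBlocks", function(x, name) standardGeneric("featureBlocks"))

#' @describeIn accessors samples-by-features matrix of one block (learner
#'   orientation: one row per sample).
#' @export
setMethod("featureBlocks", "FragFeatureSet", function(x, name) {
  blk <- as.character(SummarizedExperiment::rowData(x)$block)
  if (!name %in% blk) .stopf("unknown feature block '%s'", name)
  t(SummarizedExperiment::assay(x, "features")[blk == name, , drop = FALSE])
})

#' @rdname accessors
#' @export
setGeneric("modelCutoff", function(x) standardGeneric("modelCutoff"))
#' @rdname accessors
#' @export
setMethod("modelCutoff", "TrainedEnsemble", function(x) x@cutoff)

#' @rdname accessors
#' @export
setGeneric("selectedBlocks", function(x) standardGeneric("selectedBlocks"))
#' @rdname accessors
#' @export
setMethod("selectedBlocks", "TrainedEnsemble", function(x) x@selectedBlocks)

#' @rdname accessors
#' @export
setGeneric("oofScores", function(x) standardGeneric("oofScores"))
#' @rdname accessors
#' @export
setMethod("oofScores", "TrainedEnsemble", function(x) x@oofScores)

setMethod("show", "SampleFragments", function(object) {
  cat("SampleFragments '", object@sampleId, "': ",
      length(object@fragments), " fragments\n", sep = "")
  if (length(object@fragments)) {
    w <- GenomicRanges::width(object@fragments)
    cat("  length: median ", median(w), " bp, range [", min(w), ", ",
        max(w), "]\n", sep = "")
  }
  if (length(object@counters))
    cat("  counters:", paste(names(object@counters), object@counters,
                             sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PanelOfNormals", function(object) {
  cat("PanelOfNormals: ", length(object@medians), " kept bins, ",
      object@panelSize, " healthy samples\n", sep = "")
  cat("  manifest ", substr(object@manifestHash, 1, 8), "..., median of medians ",
      signif(median(object@medians), 4), "\n", sep = "")
})

setMethod("show", "FsdNormalizer", function(object) {
  cat("FsdNormalizer: ", length(object@mu), " features",
      if (any(object@degenerate))
        sprintf(" (%d degenerate)", sum(object@degenerate)) else "",
      "\n", sep = "")
})

setMethod("show", "TrainedEnsemble", function(object) {
  cat("TrainedEnsemble: ", length(object@baseModels), " base models (",
      paste(object@blocks, collapse = "+"), " x ",
      paste(object@families, collapse = ","), ")\n", sep = "")
  cat("  combination: ", object@combination,
      "; selected blocks: ", paste(object@selectedBlocks, collapse = "+"),
      "\n  cutoff ", signif(object@cutoff, 4), " (training specificity ",
      signif(object@cutoffSpecificity, 4), ")\n", sep = "")
})

setMethod("show", "GenomeAssets", function(object) {
  cat("GenomeAssets: ", length(object@reference), " chromosomes, ",
      sum(GenomeInfoDb::seqlengths(object@seqinfo)), " bp\n", sep = "")
  cat("  ", sum(object@bins$keep), "/", length(object@bins), " kept bins, ",
      sum(!object@arms$excluded), " included arms, ",
      length(object@alu), " Alu-like regions\n", sep = "")
})
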