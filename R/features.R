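#' Extract the three feature blocks of one sample
#'
#' Runs the CNV, FSD and FRAGMA extractors over one sample's fragments:
#' bin counts -> GC/mappability/PoN-normalized log2 ratios; per-arm size
#' histograms -> GC-corrected matrix (z-scoring is deferred to cohort
#' assembly, where the training normalizer lives); Alu end-motif ratios.
#'
#' @param x \linkS4class{SampleFragments}.
#' @param assets \linkS4class{GenomeAssets} (or any list-like with elements
#'   \code{reference}, \code{arms}, \code{bins}, \code{alu}).
#' @param pon \linkS4class{PanelOfNormals} built on \code{assets@bins}.
#' @param scheme size-bin scheme.
#' @param endMode FRAGMA end mode.
#' @return List with \code{cnv} (log2 ratios over kept bins),
#'   \code{fsdCorrected} (arms x bins matrix) and \code{fragma} (21 ratios).
#' @export
extractSampleFeatures <- function(x, assets, pon, scheme = sizeBinScheme(),
                                  endMode = "both") {
  counts <- countFragmentsPerBin(x, assets@bins)
  cnv <- suppressMessages(cnvProfile(counts, pon, assets@bins))
  raw <- fsdRaw(x, assets@arms, scheme)
  fsdC <- suppressWarnings(fsdGcCorrect(raw))
  frg <- suppressWarnings(fragmaFeatures(x, assets@alu, assets@reference,
                                         endMode = endMode,
                                         registers = assets@config$cgcgRegisters))
  list(cnv = as.numeric(cnv), fsdCorrected = fsdC, fragma = frg)
}

#' Assemble a cohort feature matrix
#'
#' Stacks per-sample extractions into a \linkS4class{FragFeatureSet}. The
#' FSD z-score normalizer is fitted on the training split only (unless a
#' frozen one is supplied, as at prediction time, or
#' \code{normalization = "all"} is requested for exact replication of
#' all-sample standardization). CNV bins are labelled chrom_start, FSD
#' features arm_sizebin, FRAGMA features by their canonical names.
#'
#' @param extracts named list (per sample) of results from
#'   \code{\link{extractSampleFeatures}}.
#' @param sheet data.frame with one row per sample: \code{sample},
#'   \code{label} ("cancer"/"healthy"), \code{split} ("train"/"validation"),
#'   plus any extra columns (tf, stage, ...) carried into \code{colData}.
#' @param assets \linkS4class{GenomeAssets} (for feature labels).
#' @param normalizer optional frozen \linkS4class{FsdNormalizer}.
#' @param normalization \code{"train_only"} (default) or \code{"all"}.
#' @return A \linkS4class{FragFeatureSet}; the fitted normalizer is stored
#'   in \code{metadata(x)$fsdNormalizer}.
#' @export
buildFeatureMatrix <- function(extracts, sheet, assets, normalizer = NULL,
                               normalization = c("train_only", "all")) {
  normalization <- match.arg(normalization)
  if (is.null(names(extracts)) || !setequal(names(extracts), sheet$sample))
    .stopf("extracts must be named by the sheet's sample ids")
  extracts <- extracts[as.character(sheet$sample)]
  if (is.null(normalizer)) {
    use <- if (normalization == "train_only") sheet$split == "train"
           else rep(TRUE, nrow(sheet))
    if (sum(use) < 3L)
      .stopf("need >= 3 samples in the normalization cohort, got %d", sum(use))
    normalizer <- suppressWarnings(
      fitFsdNormalizer(lapply(extracts[use], `[[`, "fsdCorrected")))
  }
  kept <- assets@bins[assets@bins$keep]
  cnvNames <- paste0(as.character(seqnames(kept)), "_", start(kept) - 1L)
  rows <- lapply(extracts, function(e) {
    c(setNames(e$cnv, cnvNames),
      fsdFeatures(e$fsdCorrected, normalizer),
      e$fragma)
  })
  m <- do.call(cbind, rows)  # features x samples
  colnames(m) <- as.character(sheet$sample)
  block <- c(rep("cnv", length(cnvNames)),
             rep("fsd", length(normalizer@featureNames)),
             rep("fragma", 21L))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = m),
    rowData = S4Vectors::DataFrame(block = block, row.names = rownames(m)),
    colData = S4Vectors::DataFrame(sheet[, setdiff(names(sheet), "sample"),
                                         drop = FALSE],
                                   row.names = as.character(sheet$sample)))
  out <- new("FragFeatureSet", se)
  S4Vectors::metadata(out)$fsdNormalizer <- normalizer
  validObject(out)
  out
}

#' Subset a feature set by cohort split
#' @param x \linkS4class{FragFeatureSet}.
#' @param split \code{"train"} or \code{"validation"}.
#' @return The subset \linkS4class{FragFeatureSet}.
#' @export
subsetSplit <- function(x, split) {
  x[, SummarizedExperiment::colData(x)$split == split]
}
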