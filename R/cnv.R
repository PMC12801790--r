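#' Count fragments per CNV bin
#'
#' Assigns every fragment to exactly one bin by its midpoint
#' (floor of (start + end) / 2 in 0-based coordinates) and counts fragments
#' in kept bins. Fragments whose midpoint falls in a dropped bin or outside
#' the manifest are discarded and reported in the \code{offManifest}
#' attribute, so assigned + off-manifest always equals the input total.
#'
#' @param x \linkS4class{SampleFragments}.
#' @param bins bin manifest \linkS4class{GRanges} (mcols \code{keep}).
#' @return Integer vector of counts over kept bins (manifest order), with
#'   attributes \code{offManifest} (count) and \code{sampleId}.
#' @export
countFragmentsPerBin <- function(x, bins) {
  gr <- fragments(x)
  # midpoint in 0-based half-open terms: floor((start0 + end0)/2), then +1
  mid0 <- floor(((start(gr) - 1) + end(gr)) / 2)
  mp <- GRanges(seqnames(gr), IRanges(mid0 + 1L, width = 1L))
  hit <- GenomicRanges::findOverlaps(mp, bins, select = "first")
  kept <- which(bins$keep)
  idx <- match(hit, kept)  # NA for dropped bins / off-manifest
  counts <- tabulate(idx[!is.na(idx)], nbins = length(kept))
  off <- sum(is.na(idx))
  if (off) message(sprintf("%s: %d fragments off-manifest", sampleId(x), off))
  structure(as.integer(counts), offManifest = off, sampleId = sampleId(x))
}

## Shared LOESS ratio correction: corrected = y * median(y) / fitted(y ~ x).
## Returns y unchanged (with a warning) when x is degenerate; non-positive
## fitted values are floored to a small positive fraction of the median so
## corrected counts stay finite and non-negative.
.loessCorrect <- function(y, x, span = 0.75, what = "GC") {
  if (length(unique(x)) < 2L) {
    .warnf("%s correction skipped: covariate is degenerate", what)
    return(y)
  }
  med <- median(y)
  if (med <= 0) {
    .warnf("%s correction skipped: median count is zero", what)
    return(y)
  }
  fit <- tryCatch(loess(y ~ x, span = span, degree = 1,
                        family = "symmetric",
                        control = stats::loess.control(surface = "direct")),
                  error = function(e) NULL)
  if (is.null(fit)) {
    .warnf("%s correction skipped: LOESS fit failed", what)
    return(y)
  }
  f <- fitted(fit)
  bad <- f <= med * 1e-3
  if (any(bad)) {
    .warnf("%s correction: %d bins with non-positive fitted value floored",
           what, sum(bad))
    f[bad] <- med * 1e-3
  }
  pmax(y * med / f, 0)
}

#' GC-correct bin counts
#'
#' Locally-weighted regression of count on bin GC over kept bins; each count
#' is rescaled by median(count) / fitted(GC), removing the smooth
#' amplification bias that tracks base composition. With fewer than 20 kept
#' bins or a degenerate GC covariate the counts are returned unchanged with
#' a warning.
#'
#' @param counts integer vector over kept bins (from
#'   \code{\link{countFragmentsPerBin}}).
#' @param bins bin manifest \linkS4class{GRanges}.
#' @param span LOESS span (default 0.75).
#' @return Non-negative corrected counts (real), kept-bin order.
#' @export
gcCorrectBins <- function(counts, bins, span = 0.75) {
  gc <- bins$gc[bins$keep]
  if (length(counts) != length(gc))
    .stopf("counts length (%d) does not match kept-bin count (%d)",
           length(counts), length(gc))
  if (length(counts) < 20L) {
    .warnf("GC correction skipped: fewer than 20 kept bins")
    return(as.numeric(counts))
  }
  .loessCorrect(as.numeric(counts), gc, span = span, what = "GC")
}

## full per-sample normalization chain shared by PoN construction and
## profile computation: GC-correct, divide by mappability, scale to sum 1.
.normalizedBinProportions <- function(counts, bins, span = 0.75) {
  corr <- suppressWarnings(gcCorrectBins(counts, bins, span = span))
  mp <- bins$mappability[bins$keep]
  corr <- corr / pmax(mp, 1e-6)
  tot <- sum(corr)
  if (tot <= 0) .stopf("sample has no usable fragments in kept bins")
  corr / tot
}

#' Build a Panel of Normals
#'
#' Each healthy sample's bin counts are GC-corrected, mappability-adjusted
#' and scaled to sum one; the panel value per bin is the median across
#' samples. Zero medians are floored to the smallest positive panel value
#' with a warning so downstream log2 ratios stay finite.
#'
#' @param panelCounts list of kept-bin count vectors (>= 3 healthy samples).
#' @param bins bin manifest \linkS4class{GRanges}.
#' @param span LOESS span for the GC correction.
#' @return A \linkS4class{PanelOfNormals}.
#' @export
buildPanelOfNormals <- function(panelCounts, bins, span = 0.75) {
  if (length(panelCounts) < 3L)
    .stopf("panel too small: need >= 3 healthy samples, got %d",
           length(panelCounts))
  props <- vapply(panelCounts, .normalizedBinProportions, numeric(sum(bins$keep)),
                  bins = bins, span = span)
  med <- apply(props, 1L, median)
  if (any(med <= 0)) {
    floorv <- min(med[med > 0])
    .warnf("PoN: %d zero-median bins floored to %.3g", sum(med <= 0), floorv)
    med[med <= 0] <- floorv
  }
  new("PanelOfNormals", manifestHash = .manifestHash(bins), medians = med,
      panelSize = length(panelCounts))
}

#' Per-bin CNV log2-ratio profile
#'
#' The sample's normalized bin proportions are divided by the panel medians
#' and log2-transformed, then median-centered over autosomal kept bins so a
#' diploid genome sits at log2 ratio 0. A heterozygous gain present at tumor
#' fraction tf shifts its bins to about log2(1 + tf/2).
#'
#' @param counts kept-bin counts of the test sample.
#' @param pon \linkS4class{PanelOfNormals} built on the same manifest.
#' @param bins bin manifest \linkS4class{GRanges}.
#' @param span LOESS span for the GC correction.
#' @return Numeric log2-ratio vector over kept bins; attribute
#'   \code{sampleId} is propagated from the counts when present.
#' @export
cnvProfile <- function(counts, pon, bins, span = 0.75) {
  if (.manifestHash(bins) != pon@manifestHash)
    .stopf("bin manifest does not match the one the PoN was built on")
  prop <- .normalizedBinProportions(counts, bins, span = span)
  r <- log2(pmax(prop, 1e-12) / ponMedians(pon))
  r <- r - median(r)
  structure(r, sampleId = attr(counts, "sampleId"))
}
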