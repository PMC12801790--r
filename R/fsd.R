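#' Fragment-size bin scheme
#'
#' Half-open 5-bp length bins covering the mono-nucleosomal cfDNA size
#' range: bin k spans [lower + k*width, lower + (k+1)*width). The default
#' (lower 110, width 5, 24 bins) covers [110, 230) and yields 24 features
#' per chromosome arm.
#'
#' @param lower smallest fragment length covered (bp).
#' @param width bin width (bp).
#' @param nBins number of bins.
#' @return A list with elements lower, width, nBins, breaks and labels.
#' @export
sizeBinScheme <- function(lower = 110L, width = 5L, nBins = 24L) {
  .assertScalarNumber(lower, "lower", lower = 1)
  .assertScalarNumber(width, "width", lower = 1)
  .assertScalarNumber(nBins, "nBins", lower = 1)
  breaks <- lower + width * (0:nBins)
  list(lower = as.integer(lower), width = as.integer(width),
       nBins = as.integer(nBins), breaks = as.integer(breaks),
       labels = as.character(breaks[-length(breaks)]))
}

#' Raw per-arm fragment size histograms
#'
#' Counts fragments into an included-arms x size-bins matrix: a fragment
#' contributes to arm a and bin k iff its midpoint lies in arm a and its
#' length falls in bin k's half-open interval. Fragments outside the size
#' support or on excluded arms are ignored.
#'
#' @param x \linkS4class{SampleFragments}.
#' @param arms arm \linkS4class{GRanges} (excluded arms emit nothing).
#' @param scheme from \code{\link{sizeBinScheme}}.
#' @return Integer matrix (arms x bins) with arm ids as rownames, bin lower
#'   bounds as colnames, and attribute \code{armGc} when arms carry a
#'   \code{gc} mcol.
#' @export
fsdRaw <- function(x, arms, scheme = sizeBinScheme()) {
  inc <- includedArms(arms)
  gr <- fragments(x)
  w <- GenomicRanges::width(gr)
  insupp <- w >= scheme$breaks[1] & w < scheme$breaks[length(scheme$breaks)]
  gr <- gr[insupp]; w <- w[insupp]
  mid0 <- floor(((start(gr) - 1) + end(gr)) / 2)
  mp <- GRanges(seqnames(gr), IRanges(mid0 + 1L, width = 1L),
                seqinfo = GenomeInfoDb::seqinfo(arms))
  armIdx <- GenomicRanges::findOverlaps(mp, inc, select = "first")
  ok <- !is.na(armIdx)
  binIdx <- (w[ok] - scheme$lower) %/% scheme$width + 1L
  m <- matrix(0L, nrow = length(inc), ncol = scheme$nBins,
              dimnames = list(inc$armId, scheme$labels))
  if (any(ok)) {
    tab <- table(factor(armIdx[ok], levels = seq_along(inc)),
                 factor(binIdx, levels = seq_len(scheme$nBins)))
    m[] <- as.integer(tab)
  }
  if (!is.null(inc$gc)) attr(m, "armGc") <- setNames(inc$gc, inc$armId)
  m
}

#' GC-correct an FSD matrix
#'
#' Within each size bin, counts are regressed on arm GC across arms with
#' locally-weighted regression and rescaled by bin median / fitted value.
#' With fewer than 10 arms or a degenerate GC covariate the matrix is
#' returned unchanged with a warning.
#'
#' @param raw arms x bins count matrix from \code{\link{fsdRaw}}.
#' @param armGc per-arm GC fraction (defaults to the matrix's \code{armGc}
#'   attribute).
#' @param span LOESS span.
#' @return Non-negative corrected matrix, same shape.
#' @export
fsdGcCorrect <- function(raw, armGc = attr(raw, "armGc"), span = 0.75) {
  if (is.null(armGc)) .stopf("armGc is required (none attached to the matrix)")
  if (length(armGc) != nrow(raw))
    .stopf("armGc length (%d) does not match arm count (%d)",
           length(armGc), nrow(raw))
  if (nrow(raw) < 10L || length(unique(armGc)) < 2L) {
    .warnf("FSD GC correction skipped: need >= 10 arms with varying GC")
    out <- raw * 1.0
    attr(out, "armGc") <- armGc
    return(out)
  }
  out <- raw * 1.0
  for (k in seq_len(ncol(raw)))
    out[, k] <- suppressWarnings(
      .loessCorrect(as.numeric(raw[, k]), as.numeric(armGc),
                    span = span, what = sprintf("FSD bin %s", colnames(raw)[k])))
  attr(out, "armGc") <- armGc
  out
}

.fsdFeatureNames <- function(mat) {
  # arm-major, bin-minor flattening order
  as.vector(t(outer(rownames(mat), colnames(mat), paste, sep = "_")))
}

.fsdFlatten <- function(mat) {
  setNames(as.vector(t(mat)), .fsdFeatureNames(mat))
}

#' Fit the FSD z-score normalizer on a training cohort
#'
#' Per-feature mean and sample standard deviation (n - 1 denominator) over
#' the GC-corrected training matrices. Zero-variance features are flagged
#' degenerate; their z-scores are forced to 0 at application time.
#'
#' @param training list of >= 3 corrected arms x bins matrices with
#'   identical dimnames.
#' @return A \linkS4class{FsdNormalizer}.
#' @export
fitFsdNormalizer <- function(training) {
  if (length(training) < 3L)
    .stopf("need >= 3 training samples to fit the normalizer, got %d",
           length(training))
  flat <- vapply(training, .fsdFlatten, numeric(length(.fsdFlatten(training[[1L]]))))
  mu <- apply(flat, 1L, mean)
  sigma <- apply(flat, 1L, sd)
  degenerate <- sigma == 0
  if (any(degenerate))
    .warnf("FSD normalizer: %d degenerate (zero-variance) features flagged",
           sum(degenerate))
  sigma[degenerate] <- 1  # placeholder; z forced to 0 for these
  new("FsdNormalizer", mu = mu, sigma = sigma,
      featureNames = rownames(flat), degenerate = degenerate)
}

#' FSD feature block of one sample
#'
#' Flattens the corrected matrix arm-major and standardizes each feature
#' with the frozen training statistics: z = (x - mu) / sigma; degenerate
#' features yield 0.
#'
#' @param corrected corrected arms x bins matrix.
#' @param normalizer fitted \linkS4class{FsdNormalizer}.
#' @return Named numeric vector of z-scores, length arms x bins.
#' @export
fsdFeatures <- function(corrected, normalizer) {
  flat <- .fsdFlatten(corrected)
  if (!identical(names(flat), normalizer@featureNames))
    .stopf("FSD feature layout does not match the normalizer (%d vs %d features)",
           length(flat), length(normalizer@featureNames))
  z <- (flat - normalizer@mu) / normalizer@sigma
  z[normalizer@degenerate] <- 0
  z
}

#' Per-arm GC from a reference
#'
#' G+C fraction among non-N bases over each arm interval; attached to the
#' arm table as mcol \code{gc} for the FSD GC correction.
#'
#' @param arms arm \linkS4class{GRanges}.
#' @param reference \code{DNAStringSet} named by chromosome.
#' @return The arm \linkS4class{GRanges} with a \code{gc} mcol.
#' @export
armGcFromReference <- function(arms, reference) {
  gc <- vapply(seq_along(arms), function(i) {
    ch <- as.character(seqnames(arms))[i]
    v <- subseq(reference[[ch]], start(arms)[i], end(arms)[i])
    f <- letterFrequency(v, c("G", "C", "A", "T"))
    tot <- sum(f)
    if (tot == 0) 0.5 else sum(f[c("G", "C")]) / tot
  }, numeric(1))
  mcols(arms)$gc <- gc
  arms
}
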