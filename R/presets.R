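#' hg19 presets
#'
#' Coordinate scaffolding for the GRCh37/hg19 autosomes, shipped as versioned
#' data files so the feature-space size is reproducible bit-exactly:
#' \itemize{
#'   \item \code{hg19ChromTable()}: the 22 autosomes with their hg19 lengths.
#'   \item \code{hg19ArmTable()}: 44 autosomal arms split at the standard
#'     centromere positions; the 5 repeat-dominated acrocentric p-arms (13p,
#'     14p, 15p, 21p, 22p) are flagged excluded, leaving 39 arms that emit
#'     FSD features.
#'   \item \code{hg19BinManifest()}: the 1-Mb tiling of the autosomes with a
#'     frozen keep-mask yielding the conventional 2,475 usable bins.
#' }
#'
#' The keep-mask is a \emph{synthetic} stand-in (see
#' \code{inst/extdata/hg19_bins_synthetic.tsv}): real usable-bin lists are
#' derived from GC and mappability tracks, which this package does not
#' vendor. The shipped mask drops bins around centromeres, across acrocentric
#' p-arms and the chr1/chr9/chr16 heterochromatin gaps, and each
#' chromosome's first and terminal bin. GC and mappability columns of the
#' preset are placeholders (smooth synthetic GC in [0.38, 0.52], mappability
#' 1 for kept / 0.5 for dropped bins); real analyses should build their own
#' manifest from a reference with \code{\link{buildBinManifest}}.
#'
#' @return See each function above.
#' @name hg19Presets
NULL

.extdata <- function(f) {
  p <- system.file("extdata", f, package = "fragstack")
  if (!nzchar(p)) .stopf("preset file %s not found (package not installed?)", f)
  p
}

#' @rdname hg19Presets
#' @export
hg19ChromTable <- function() loadChromTable(.extdata("hg19_chroms.tsv"))

#' @rdname hg19Presets
#' @export
hg19ArmTable <- function() loadArmTable(.extdata("hg19_arms.tsv"), hg19ChromTable())

#' @rdname hg19Presets
#' @export
hg19BinManifest <- function() {
  si <- hg19ChromTable()
  df <- .readTsv(.extdata("hg19_bins_synthetic.tsv"), "hg19 bin mask", 3L,
                 header = TRUE)
  grl <- lapply(seq_len(nrow(df)), function(i) {
    ch <- df$chrom[i]
    nb <- as.integer(df$n_bins[i])
    st <- (seq_len(nb) - 1) * 1e6
    en <- pmin(st + 1e6, seqlengths(si)[[ch]])
    keep <- rep(TRUE, nb)
    if (!is.na(df$dropped[i]) && nzchar(df$dropped[i]))
      keep[as.integer(strsplit(df$dropped[i], ",", fixed = TRUE)[[1L]]) + 1L] <- FALSE
    gr <- GRanges(ch, IRanges(st + 1, en), seqinfo = si)
    # synthetic placeholder tracks: smooth GC, binary-ish mappability
    mcols(gr)$gc <- 0.45 + 0.07 * sin(seq_len(nb) / 7)
    mcols(gr)$mappability <- ifelse(keep, 1, 0.5)
    mcols(gr)$keep <- keep
    gr
  })
  do.call(c, grl)
}
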