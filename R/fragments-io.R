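#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement subseq letterFrequency vmatchPattern extractAt
#' @importFrom Rsamtools ScanBamParam scanBamFlag scanBam asBam
NULL

## Look up both 5' terminal 3-mers of each fragment from the reference.
## Left end: reference at the first three fragment bases, forward strand.
## Right end: reverse complement of the last three bases, i.e. the 3-mer read
## 5'->3' on the reverse strand. Fragments shorter than 3 bp or running off
## the chromosome get "NNN" (later excluded from FRAGMA, kept for CNV/FSD).
.attachMotifs <- function(gr, reference) {
  n <- length(gr)
  ml <- rep("NNN", n)
  mr <- rep("NNN", n)
  if (n) {
    chr <- as.character(seqnames(gr))
    bad <- !(chr %in% names(reference))
    if (any(bad)) .stopf("fragment chromosome missing from reference: %s",
                         chr[bad][1L])
    chrlen <- vapply(reference, length, integer(1))[chr]
    okL <- start(gr) + 2 <= chrlen & GenomicRanges::width(gr) >= 3
    okR <- end(gr) >= 3 & GenomicRanges::width(gr) >= 3
    if (any(okL)) {
      at <- GRanges(chr[okL], IRanges(start(gr)[okL], width = 3))
      ml[okL] <- as.character(.extractSeqs(reference, at))
    }
    if (any(okR)) {
      at <- GRanges(chr[okR], IRanges(end(gr)[okR] - 2, width = 3))
      mr[okR] <- as.character(reverseComplement(.extractSeqs(reference, at)))
    }
  }
  mcols(gr)$motifLeft <- ml
  mcols(gr)$motifRight <- mr
  gr
}

.extractSeqs <- function(reference, at) {
  chr <- as.character(seqnames(at))
  out <- DNAStringSet(rep("", length(at)))
  for (ch in unique(chr)) {
    i <- chr == ch
    out[i] <- extractAt(reference[[ch]], IRanges::ranges(at)[i])
  }
  out
}

.newSampleFragments <- function(sampleId, gr, counters = numeric(),
                                metadata = list()) {
  new("SampleFragments", sampleId = sampleId, fragments = gr,
      counters = counters, metadata = metadata)
}

#' Read fragments from a BED-like file
#'
#' Reads a fragment interval file (columns chrom, start, end; 0-based
#' half-open; extra columns ignored), converts to 1-based coordinates, and
#' attaches both 5' end motifs from the reference so downstream behaviour is
#' identical to the BAM path.
#'
#' @param path BED-like fragment file.
#' @param reference \code{DNAStringSet} (named by chromosome) or path to a
#'   FASTA file.
#' @param seqinfo \linkS4class{Seqinfo}; fragments must lie on its
#'   chromosomes and within bounds.
#' @param sampleId sample identifier (default: file base name).
#' @return A \linkS4class{SampleFragments}.
#' @export
readFragmentsBed <- function(path, reference, seqinfo,
                             sampleId = sub("\\.bed$", "", basename(path))) {
  if (is.character(reference)) reference <- readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  df <- .readTsv(path, "fragment BED", 3L)
  if (!nrow(df)) {
    gr <- GRanges(seqinfo = seqinfo)
    mcols(gr)$mapq <- integer()
    return(.newSampleFragments(sampleId, .attachMotifs(gr, reference)))
  }
  s <- .numCol(df[[2L]], "fragment BED", df[[2L]])
  e <- .numCol(df[[3L]], "fragment BED", df[[3L]])
  if (any(s >= e))
    .stopf("fragment BED parse error at line %d: start >= end", which(s >= e)[1L])
  if (!all(df[[1L]] %in% GenomeInfoDb::seqnames(seqinfo)))
    .stopf("fragment BED parse error at line %d: unknown chromosome '%s'",
           which(!(df[[1L]] %in% GenomeInfoDb::seqnames(seqinfo)))[1L],
           setdiff(df[[1L]], GenomeInfoDb::seqnames(seqinfo))[1L])
  lim <- seqlengths(seqinfo)[df[[1L]]]
  if (any(e > lim))
    .stopf("fragment BED parse error at line %d: interval outside chromosome",
           which(e > lim)[1L])
  gr <- GRanges(df[[1L]], IRanges(s + 1L, e), seqinfo = seqinfo)
  mcols(gr)$mapq <- rep(60L, length(gr))
  gr <- .attachMotifs(gr, reference)
  .newSampleFragments(sampleId, gr,
                      counters = c(read = length(gr)))
}

#' Read fragments from a coordinate-sorted BAM
#'
#' One fragment per properly-paired, primary, non-duplicate read pair passing
#' the mapping-quality filter. The fragment interval is
#' [leftmost aligned base, leftmost base + template length); pairs with
#' non-positive or over-long template length are skipped and counted. End
#' motifs are attached from the reference exactly as in the BED path.
#'
#' @param path indexed BAM of paired-end reads.
#' @param reference \code{DNAStringSet} or FASTA path.
#' @param seqinfo \linkS4class{Seqinfo} of the analysis chromosomes; pairs on
#'   other contigs are counted as off-reference and dropped.
#' @param minMapq minimum mapping quality (default 30).
#' @param maxLength maximum template length (default 1000).
#' @param sampleId sample identifier.
#' @return A \linkS4class{SampleFragments} with filter counters.
#' @export
readFragmentsBam <- function(path, reference, seqinfo, minMapq = 30L,
                             maxLength = 1000L,
                             sampleId = sub("\\.bam$", "", basename(path))) {
  if (is.character(reference)) reference <- readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path)))
    .stopf("BAM index not found for %s", path)
  flag <- scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                      isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
                      isSecondaryAlignment = FALSE, isDuplicate = FALSE,
                      isSupplementaryAlignment = FALSE)
  p <- ScanBamParam(flag = flag, what = c("rname", "pos", "isize", "mapq"))
  b <- scanBam(path, param = p)[[1L]]
  keepLeft <- !is.na(b$isize) & b$isize > 0  # leftmost mate carries +TLEN
  rname <- as.character(b$rname)[keepLeft]
  pos <- b$pos[keepLeft]
  isize <- b$isize[keepLeft]
  mapq <- b$mapq[keepLeft]
  counters <- c(pairs = sum(keepLeft))
  ok <- mapq >= minMapq
  counters["low_mapq"] <- sum(!ok)
  rname <- rname[ok]; pos <- pos[ok]; isize <- isize[ok]; mapq <- mapq[ok]
  ok <- isize <= maxLength
  counters["overlong"] <- sum(!ok)
  rname <- rname[ok]; pos <- pos[ok]; isize <- isize[ok]; mapq <- mapq[ok]
  ok <- rname %in% GenomeInfoDb::seqnames(seqinfo)
  counters["off_reference"] <- sum(!ok)
  rname <- rname[ok]; pos <- pos[ok]; isize <- isize[ok]; mapq <- mapq[ok]
  gr <- GRanges(rname, IRanges(pos, width = isize), seqinfo = seqinfo)
  mcols(gr)$mapq <- as.integer(mapq)
  gr <- sort(.attachMotifs(gr, reference))
  counters["read"] <- length(gr)
  .newSampleFragments(sampleId, gr, counters = counters)
}

#' Down-sample fragments to a target fraction
#'
#' Keeps each fragment independently with probability \code{targetFraction}
#' (the fragment-level analogue of depth down-sampling: to reach a target
#' mean coverage, pass \code{target / meanCoverage(x, genomeSize)}).
#' Deterministic given \code{seed}; order preserved.
#'
#' @param x a \linkS4class{SampleFragments}.
#' @param targetFraction keep probability in (0, 1].
#' @param seed integer seed.
#' @return A \linkS4class{SampleFragments} with the retained subset.
#' @export
subsampleFragments <- function(x, targetFraction, seed) {
  .assertScalarNumber(targetFraction, "targetFraction", lower = 0, upper = 1,
                      lowerOpen = TRUE)
  if (targetFraction == 1) return(x)
  gr <- fragments(x)
  set.seed(as.integer(seed))
  keep <- runif(length(gr)) < targetFraction
  cnt <- x@counters
  cnt["subsampled_out"] <- sum(!keep)
  .newSampleFragments(sampleId(x), gr[keep], counters = cnt,
                      metadata = x@metadata)
}

#' Mean coverage implied by a fragment set
#'
#' Sum of fragment lengths divided by genome size -- the depth proxy used to
#' convert between target depths and subsampling fractions.
#'
#' @param x \linkS4class{SampleFragments}.
#' @param genomeSize total genome length in bp.
#' @return Mean coverage (real).
#' @export
meanCoverage <- function(x, genomeSize) {
  sum(as.numeric(GenomicRanges::width(fragments(x)))) / genomeSize
}

#' Write fragments as BED3 / as BAM
#'
#' \code{writeFragmentsBed} emits the 0-based half-open fragment intervals.
#' \code{writeFragmentsBam} emits each fragment as a properly-paired read
#' pair (SEQ omitted) via SAM text and \code{Rsamtools::asBam}; it exists to
#' exercise the BAM reading path against the BED path, not to emulate a
#' sequencer.
#'
#' @param x \linkS4class{SampleFragments}.
#' @param path output path (for BAM, without the .bam suffix additions of
#'   \code{asBam}).
#' @param seqinfo \linkS4class{Seqinfo} for the BAM header.
#' @param readLength nominal read length for the synthetic pairs.
#' @return The written path, invisibly (for BAM, the indexed BAM path).
#' @export
writeFragmentsBed <- function(x, path) {
  gr <- fragments(x)
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeFragmentsBed
#' @export
writeFragmentsBam <- function(x, path, seqinfo, readLength = 60L) {
  gr <- fragments(x)
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", GenomeInfoDb::seqnames(seqinfo),
                   seqlengths(seqinfo)))
  o <- order(as.factor(seqnames(gr)), start(gr))
  gr <- gr[o]
  rl <- pmin(readLength, GenomicRanges::width(gr))
  qn <- sprintf("frag%07d", seq_along(gr))
  chr <- as.character(seqnames(gr))
  r1 <- sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*",
                qn, chr, start(gr), rl, end(gr) - rl + 1L,
                GenomicRanges::width(gr))
  r2 <- sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*",
                qn, chr, end(gr) - rl + 1L, rl, start(gr),
                -GenomicRanges::width(gr))
  body <- as.vector(rbind(r1, r2))
  # coordinate order: interleave then re-sort by position
  pos <- as.vector(rbind(start(gr), end(gr) - rl + 1L))
  chr2 <- rep(chr, each = 2L)
  body <- body[order(match(chr2, GenomeInfoDb::seqnames(seqinfo)), pos)]
  writeLines(c(hdr, body), sam)
  bam <- asBam(sam, destination = sub("\\.bam$", "", path),
               overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  invisible(bam)
}
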