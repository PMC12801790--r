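#' @importFrom GenomicRanges GRanges width start end seqnames mcols
#'   mcols<- findOverlaps tileGenome reduce
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqnames seqlevels
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.readTsv <- function(path, what, nCols, header = FALSE, colNames = NULL) {
  if (!file.exists(path)) .stopf("%s file not found: %s", what, path)
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln)]
  if (header && length(ln)) {
    colNames <- strsplit(ln[1L], "\t", fixed = TRUE)[[1L]]
    ln <- ln[-1L]
  }
  if (!length(ln)) {
    df <- as.data.frame(matrix(nrow = 0, ncol = nCols))
    if (!is.null(colNames)) names(df) <- colNames
    return(df)
  }
  parts <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < nCols)
  if (length(bad))
    .stopf("%s parse error at line %d: expected >= %d tab-separated fields, got %d",
           what, bad[1L] + header, nCols, lengths(parts)[bad[1L]])
  df <- as.data.frame(do.call(rbind, lapply(parts, `[`, seq_len(nCols))),
                      stringsAsFactors = FALSE)
  if (!is.null(colNames)) names(df) <- colNames[seq_len(nCols)]
  df
}

.numCol <- function(x, what, lines, header = 0L) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v))
    .stopf("%s parse error at line %d: non-numeric value '%s'",
           what, which(is.na(v))[1L] + header, x[which(is.na(v))[1L]])
  v
}

#' Load a chromosome table
#'
#' Reads a two-column tab-separated file of chromosome name and length (bp)
#' into a \linkS4class{Seqinfo}. Order is preserved and reused by every
#' downstream feature vector; duplicate names or non-positive lengths are
#' rejected.
#'
#' @param path TSV with columns name, length. Lines starting with '#' are
#'   skipped.
#' @return A \linkS4class{Seqinfo}.
#' @examples
#' tf <- tempfile()
#' writeLines(c("chr1\t3000000", "chr2\t3000000"), tf)
#' loadChromTable(tf)
#' @export
loadChromTable <- function(path) {
  df <- .readTsv(path, "chromosome table", 2L)
  if (!nrow(df)) .stopf("chromosome table is empty: %s", path)
  len <- .numCol(df[[2L]], "chromosome table", df[[2L]])
  if (anyDuplicated(df[[1L]]))
    .stopf("chromosome table parse error: duplicate chromosome name '%s'",
           df[[1L]][anyDuplicated(df[[1L]])])
  if (any(len <= 0 | len != floor(len)))
    .stopf("chromosome table parse error at line %d: length must be a positive integer",
           which(len <= 0 | len != floor(len))[1L])
  Seqinfo(seqnames = df[[1L]], seqlengths = len)
}

#' Construct or load a chromosome-arm table
#'
#' An arm table is a \linkS4class{GRanges} with one range per arm and mcols
#' \code{armId} (e.g. \code{"1p"}) and \code{excluded}. Excluded arms (the
#' repeat-dominated short arms of acrocentric chromosomes in the hg19 preset)
#' are carried for bookkeeping but never emit FSD features. Arms within a
#' chromosome must be disjoint and ordered.
#'
#' @param df data.frame with columns armId, chrom, start, end (0-based
#'   half-open, as in the on-disk TSV), excluded (logical or 0/1).
#' @param seqinfo \linkS4class{Seqinfo} the arms must lie within.
#' @return Arm \linkS4class{GRanges}.
#' @export
makeArmTable <- function(df, seqinfo) {
  need <- c("armId", "chrom", "start", "end", "excluded")
  if (!all(need %in% names(df)))
    .stopf("arm table needs columns: %s", paste(need, collapse = ", "))
  if (!all(df$chrom %in% GenomeInfoDb::seqnames(seqinfo)))
    .stopf("arm table chromosome not in chromosome table: %s",
           setdiff(df$chrom, GenomeInfoDb::seqnames(seqinfo))[1L])
  gr <- GRanges(df$chrom, IRanges(as.numeric(df$start) + 1L, as.numeric(df$end)),
                seqinfo = seqinfo)
  mcols(gr)$armId <- as.character(df$armId)
  mcols(gr)$excluded <- as.logical(df$excluded)
  if (any(end(gr) > seqlengths(seqinfo)[as.character(seqnames(gr))]))
    .stopf("arm extends past its chromosome end")
  bychr <- split(gr, seqnames(gr))
  for (g in bychr) {
    if (length(g) > 1L) {
      if (is.unsorted(start(g))) .stopf("arms within a chromosome must be ordered")
      if (any(start(g)[-1L] <= end(g)[-length(g)]))
        .stopf("arms within a chromosome must be disjoint")
    }
  }
  gr
}

#' @rdname makeArmTable
#' @param path 5-column TSV (armId, chrom, start, end, excluded).
#' @export
loadArmTable <- function(path, seqinfo) {
  df <- .readTsv(path, "arm table", 5L,
                 colNames = c("armId", "chrom", "start", "end", "excluded"))
  df$start <- .numCol(df$start, "arm table", df$start)
  df$end <- .numCol(df$end, "arm table", df$end)
  df$excluded <- as.logical(as.integer(df$excluded))
  makeArmTable(df, seqinfo)
}

#' Arms that emit features
#' @param arms arm \linkS4class{GRanges} from \code{makeArmTable}.
#' @return The non-excluded subset, original order.
#' @export
includedArms <- function(arms) arms[!arms$excluded]

#' Tile a genome into CNV bins and apply keep rules
#'
#' Tiles every chromosome left to right into fixed-width bins (the terminal
#' bin of a chromosome may be shorter), attaches per-bin GC fraction and
#' mappability, and sets \code{keep = FALSE} for bins failing any rule:
#' mappability below \code{mapThreshold}, GC outside \code{gcBounds}, or
#' overlap with a configured exclusion interval (centromere / assembly-gap
#' list). Only kept bins enter the CNV feature vector, so the kept count
#' defines the CNV block width.
#'
#' @param seqinfo chromosome table (\linkS4class{Seqinfo}).
#' @param binWidth bin width in bp (default 1 Mb).
#' @param reference optional \code{DNAStringSet} named by chromosome; per-bin
#'   GC is the G+C fraction among non-N bases. Without it GC is set to 0.5
#'   and the GC rule is inactive.
#' @param mappability optional numeric vector, one value per bin in tiling
#'   order (default 1 everywhere).
#' @param gcBounds keep bins with GC inside this closed interval.
#' @param mapThreshold keep bins with mappability >= this value.
#' @param exclude \linkS4class{GRanges} of intervals whose overlapping bins
#'   are dropped.
#' @return Bin manifest \linkS4class{GRanges} with mcols \code{gc},
#'   \code{mappability}, \code{keep}.
#' @export
buildBinManifest <- function(seqinfo, binWidth = 1e6, reference = NULL,
                             mappability = NULL, gcBounds = c(0.28, 0.68),
                             mapThreshold = 0.9, exclude = GRanges()) {
  .assertScalarNumber(binWidth, "binWidth", lower = 1)
  bins <- GenomicRanges::tileGenome(seqinfo, tilewidth = binWidth,
                                    cut.last.tile.in.chrom = TRUE)
  bins <- sort(bins)
  if (is.null(mappability)) mappability <- rep(1, length(bins))
  if (length(mappability) != length(bins))
    .stopf("mappability must have one value per bin (%d)", length(bins))
  gc <- rep(0.5, length(bins))
  if (!is.null(reference)) {
    chr <- as.character(seqnames(bins))
    if (!all(chr %in% names(reference)))
      .stopf("reference/chromosome name mismatch: %s",
             setdiff(chr, names(reference))[1L])
    gc <- vapply(seq_along(bins), function(i) {
      v <- Biostrings::subseq(reference[[chr[i]]], start(bins)[i], end(bins)[i])
      f <- Biostrings::letterFrequency(v, c("G", "C", "A", "T"))
      tot <- sum(f)
      if (tot == 0) NA_real_ else sum(f[c("G", "C")]) / tot
    }, numeric(1))
    gc[is.na(gc)] <- -1  # all-N bin: fails the GC rule
  }
  keep <- mappability >= mapThreshold
  if (!is.null(reference)) keep <- keep & gc >= gcBounds[1] & gc <= gcBounds[2]
  if (length(exclude)) keep <- keep & !overlapsAny(bins, exclude)
  mcols(bins)$gc <- gc
  mcols(bins)$mappability <- mappability
  mcols(bins)$keep <- keep
  message(sprintf("bin manifest: %d bins, %d kept", length(bins), sum(keep)))
  bins
}

#' Read / write a bin manifest as TSV
#'
#' Six columns with header: chrom, start (0-based), end, gc, mappability,
#' keep.
#'
#' @param path TSV path.
#' @param seqinfo chromosome table the bins must lie within.
#' @return \code{loadBinManifest}: bin \linkS4class{GRanges};
#'   \code{writeBinManifest}: the path, invisibly.
#' @export
loadBinManifest <- function(path, seqinfo) {
  df <- .readTsv(path, "bin manifest", 6L, header = TRUE)
  need <- c("chrom", "start", "end", "gc", "mappability", "keep")
  if (!all(need %in% names(df)))
    .stopf("bin manifest needs header columns: %s", paste(need, collapse = ", "))
  gr <- GRanges(df$chrom,
                IRanges(.numCol(df$start, "bin manifest", df$start, 1L) + 1L,
                        .numCol(df$end, "bin manifest", df$end, 1L)),
                seqinfo = seqinfo)
  mcols(gr)$gc <- .numCol(df$gc, "bin manifest", df$gc, 1L)
  mcols(gr)$mappability <- .numCol(df$mappability, "bin manifest", df$mappability, 1L)
  mcols(gr)$keep <- as.logical(as.integer(df$keep))
  gr
}

#' @rdname loadBinManifest
#' @param bins bin manifest \linkS4class{GRanges}.
#' @export
writeBinManifest <- function(bins, path) {
  df <- data.frame(chrom = as.character(seqnames(bins)),
                   start = start(bins) - 1L, end = end(bins),
                   gc = bins$gc, mappability = bins$mappability,
                   keep = as.integer(bins$keep))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.manifestHash <- function(bins) {
  .md5Object(list(as.character(seqnames(bins)), start(bins), end(bins), bins$keep))
}

#' Load a region set (BED3)
#'
#' Reads a 3-column BED (0-based half-open), converts to 1-based
#' \linkS4class{GRanges}, sorts and merges overlapping or adjacent intervals.
#' The merge is idempotent; intervals with start >= end are a parse error.
#'
#' @param path BED3 file.
#' @param seqinfo optional \linkS4class{Seqinfo}; when given, intervals must
#'   lie within their chromosome.
#' @return Reduced, sorted \linkS4class{GRanges}.
#' @export
loadRegionSet <- function(path, seqinfo = NULL) {
  df <- .readTsv(path, "region BED", 3L)
  if (!nrow(df))
    return(GRanges(seqinfo = seqinfo %||% Seqinfo()))
  s <- .numCol(df[[2L]], "region BED", df[[2L]])
  e <- .numCol(df[[3L]], "region BED", df[[3L]])
  if (any(s >= e))
    .stopf("region BED parse error at line %d: start >= end", which(s >= e)[1L])
  gr <- GRanges(df[[1L]], IRanges(s + 1L, e))
  if (!is.null(seqinfo)) {
    if (!all(as.character(seqnames(gr)) %in% GenomeInfoDb::seqnames(seqinfo)))
      .stopf("region BED chromosome not in chromosome table")
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(seqinfo)
    GenomeInfoDb::seqinfo(gr) <- seqinfo
    if (any(end(gr) > seqlengths(seqinfo)[as.character(seqnames(gr))]))
      .stopf("region BED parse error at line %d: interval outside chromosome",
             which(end(gr) > seqlengths(seqinfo)[as.character(seqnames(gr))])[1L])
  }
  reduce(sort(gr))
}

#' Feature-space accounting
#'
#' Widths of the three feature blocks implied by a bin manifest, arm table
#' and size-bin scheme: kept CNV bins, included arms x size bins for FSD,
#' and the fixed 21 end-motif ratios for FRAGMA.
#'
#' @param bins bin manifest \linkS4class{GRanges}.
#' @param arms arm \linkS4class{GRanges}.
#' @param scheme size-bin scheme from \code{\link{sizeBinScheme}}.
#' @return Named integer vector \code{c(cnv, fsd, fragma, total)}.
#' @examples
#' \dontrun{featureSpaceDims(hg19BinManifest(), hg19ArmTable())}
#' @export
featureSpaceDims <- function(bins, arms, scheme = sizeBinScheme()) {
  cnv <- sum(bins$keep)
  fsd <- length(includedArms(arms)) * scheme$nBins
  c(cnv = cnv, fsd = fsd, fragma = 21L, total = cnv + fsd + 21L)
}
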