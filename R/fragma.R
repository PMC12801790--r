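## Canonical motif families. CGN and NCG partition disjoint 3-mer sets
## (note GCG belongs to NCG, CGC to CGN).
.CGN <- c("CGA", "CGC", "CGG", "CGT")
.NCG <- c("ACG", "CCG", "GCG", "TCG")

#' FRAGMA feature names
#' @return The 21 canonical feature names, fixed order: 8 Alu-wide motif
#'   ratios, the CGN/NCG ratio, 10 CGCG-context register ratios, and the two
#'   CGCG-context ratio-of-ratios.
#' @export
fragmaFeatureNames <- function() {
  c(paste0("r_", .CGN), paste0("r_", .NCG), "r_CGN_over_NCG",
    paste0("c_NCG_", c("A", "C", "G", "T")), "c_CGC", "c_GCG",
    paste0("c_CGN_", c("A", "C", "G", "T")),
    "c_CGC_over_NCG", "c_CGN_over_CGC")
}

#' Collect 5' end events in Alu regions
#'
#' Every fragment contributes up to two 5' end events: its left end on the
#' forward strand and its right end on the reverse strand (under
#' \code{endMode = "left_only"}, only the former). An event is retained iff
#' its 5' terminal base lies inside an Alu interval; events whose 3-mer
#' motif contains an ambiguous base are dropped and counted.
#'
#' @param x \linkS4class{SampleFragments} with motifs attached.
#' @param alu merged Alu \linkS4class{GRanges} (must be non-empty).
#' @param endMode \code{"both"} (default) or \code{"left_only"}.
#' @return data.frame with columns chrom, pos (0-based position of the 5'
#'   terminal base), strand, motif; attribute \code{droppedN} counts
#'   N-motif events discarded.
#' @export
collectEndEvents <- function(x, alu, endMode = c("both", "left_only")) {
  endMode <- match.arg(endMode)
  if (length(alu) == 0L) .stopf("no regions: the Alu region set is empty")
  gr <- fragments(x)
  chrom <- as.character(seqnames(gr))
  ev <- data.frame(chrom = chrom, pos = start(gr) - 1L, strand = "+",
                   motif = gr$motifLeft, stringsAsFactors = FALSE)
  if (endMode == "both")
    ev <- rbind(ev, data.frame(chrom = chrom, pos = end(gr) - 1L,
                               strand = "-", motif = gr$motifRight,
                               stringsAsFactors = FALSE))
  pt <- GRanges(ev$chrom, IRanges(ev$pos + 1L, width = 1L))
  inAlu <- overlapsAny(pt, alu)
  ev <- ev[inAlu, , drop = FALSE]
  valid <- grepl("^[ACGT]{3}$", ev$motif)
  dropped <- sum(!valid)
  ev <- ev[valid, , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, droppedN = dropped)
}

#' Alu-wide end-motif ratios
#'
#' The fraction of Alu end events carrying each of the four CGN and four NCG
#' motifs (denominator: all retained Alu events), plus the ratio of total
#' CGN to total NCG events. A zero NCG denominator falls back to a
#' pseudo-count of 1 with a warning so the feature matrix never contains
#' NaN.
#'
#' @param events data.frame from \code{\link{collectEndEvents}}.
#' @return Named numeric vector of 9 ratios.
#' @export
fragmaAluRatios <- function(events) {
  nm <- c(paste0("r_", .CGN), paste0("r_", .NCG))
  total <- nrow(events)
  if (total == 0L) {
    .warnf("no Alu end events: Alu-wide motif ratios set to 0")
    return(setNames(numeric(9), c(nm, "r_CGN_over_NCG")))
  }
  cnt <- table(factor(events$motif, levels = c(.CGN, .NCG)))
  r <- setNames(as.numeric(cnt) / total, nm)
  cgn <- sum(cnt[.CGN])
  ncg <- sum(cnt[.NCG])
  if (ncg == 0) {
    .warnf("no NCG end events: CGN/NCG ratio uses pseudo-count 1 denominator")
    ncg <- 1
  }
  c(r, r_CGN_over_NCG = cgn / ncg)
}

## Register table for all CGCG occurrences inside Alu intervals, both
## strands (CGCG is its own reverse complement, so forward matches
## enumerate both orientations). For an occurrence at 0-based p:
##   + strand cleavage registers: p-1 -> NCG (N = base p-1), p -> CGC,
##     p+1 -> GCG, p+2 -> CGN (N = base p+4)
##   - strand registers (mirror):  p+4 -> NCG (N = comp base p+4),
##     p+3 -> CGC, p+2 -> GCG, p+1 -> CGN (N = comp base p-1)
## Overlapping occurrences (CGCGCG...) can claim one (pos, strand) for two
## classes; the more specific class wins: CGC > GCG > NCG > CGN.
#' @rdname fragmaCgcgRatios
#' @export
cgcgRegisters <- function(alu, reference) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list()
  for (ch in unique(as.character(seqnames(alu)))) {
    if (!ch %in% names(reference)) .stopf("chromosome %s missing from reference", ch)
    hits <- Biostrings::matchPattern("CGCG", reference[[ch]])
    if (!length(hits)) next
    occ <- GRanges(ch, IRanges::ranges(hits))
    within <- overlapsAny(occ, alu[seqnames(alu) == ch], type = "within")
    if (!any(within)) next
    p0 <- start(hits)[within] - 1L  # 0-based occurrence starts
    chrlen <- length(reference[[ch]])
    baseAt <- function(pos0) {
      b <- rep(NA_character_, length(pos0))
      ok <- pos0 >= 0 & pos0 < chrlen
      if (any(ok)) {
        ex <- extractAt(reference[[ch]], IRanges(pos0[ok] + 1L, width = 1L))
        b[ok] <- as.character(ex)
      }
      b
    }
    bL <- baseAt(p0 - 1L)
    bR <- baseAt(p0 + 4L)
    n <- length(p0)
    tab <- data.frame(
      chrom = ch,
      pos = c(p0, p0 + 1L, p0 + 3L, p0 + 2L, p0 - 1L, p0 + 2L, p0 + 4L, p0 + 1L),
      strand = rep(c("+", "+", "-", "-", "+", "+", "-", "-"), each = n),
      class = rep(c("CGC", "GCG", "CGC", "GCG", "NCG", "CGN", "NCG", "CGN"),
                  each = n),
      n = c(rep(NA_character_, 4L * n), bL, bR,
            unname(comp[bR]), unname(comp[bL])),
      stringsAsFactors = FALSE)
    tab <- tab[tab$pos >= 0 & tab$pos < chrlen, , drop = FALSE]
    tab <- tab[tab$class %in% c("CGC", "GCG") |
                 tab$n %in% c("A", "C", "G", "T"), , drop = FALSE]
    out[[ch]] <- tab
  }
  tab <- do.call(rbind, out)
  if (is.null(tab) || !nrow(tab)) return(NULL)
  prec <- c(CGC = 1L, GCG = 2L, NCG = 3L, CGN = 4L)
  tab <- tab[order(tab$chrom, tab$pos, tab$strand, prec[tab$class]), , drop = FALSE]
  tab <- tab[!duplicated(tab[, c("chrom", "pos", "strand")]), , drop = FALSE]
  rownames(tab) <- NULL
  tab$key <- paste(tab$chrom, tab$pos, tab$strand, sep = ":")
  tab
}

#' CGCG-context cleavage-register ratios
#'
#' Locates every CGCG occurrence inside the Alu intervals (both strands) and
#' classifies end events falling on its four cleavage registers: the
#' position before the run (NCG motif, split by the flanking base N), the
#' first CG (CGC), between the CGs (GCG) and the second CG (CGN, split by
#' the trailing base). The ten register counts are divided by the total
#' number of CGCG-context events, so they sum to 1 whenever at least one
#' such event exists; two ratio-of-ratio features (CGC/NCG and CGN/CGC,
#' pseudo-count 1 denominators) complete the block.
#'
#' @param events data.frame from \code{\link{collectEndEvents}}.
#' @param alu merged Alu \linkS4class{GRanges}.
#' @param reference \code{DNAStringSet} named by chromosome.
#' @param registers optional precomputed register table from
#'   \code{cgcgRegisters} (a per-genome constant; precompute it when
#'   extracting many samples).
#' @return \code{fragmaCgcgRatios}: named numeric vector of 12 features;
#'   \code{cgcgRegisters}: data.frame chrom / pos (0-based) / strand /
#'   class / n, one row per claimable cleavage register.
#' @export
fragmaCgcgRatios <- function(events, alu, reference, registers = NULL) {
  nm <- c(paste0("c_NCG_", c("A", "C", "G", "T")), "c_CGC", "c_GCG",
          paste0("c_CGN_", c("A", "C", "G", "T")))
  zero <- setNames(numeric(12), c(nm, "c_CGC_over_NCG", "c_CGN_over_CGC"))
  reg <- registers %||% cgcgRegisters(alu, reference)
  if (is.null(reg)) {
    .warnf("no CGCG occurrences in the Alu regions: CGCG-context features set to 0")
    return(zero)
  }
  regKey <- reg$key %||% paste(reg$chrom, reg$pos, reg$strand, sep = ":")
  idx <- match(paste(events$chrom, events$pos, events$strand, sep = ":"),
               regKey)
  hit <- reg[idx[!is.na(idx)], , drop = FALSE]
  cls <- ifelse(hit$class %in% c("NCG", "CGN"),
                paste("c", hit$class, hit$n, sep = "_"),
                paste0("c_", hit$class))
  cnt <- table(factor(cls, levels = nm))
  total <- sum(cnt)
  if (total == 0L) {
    .warnf("no end events on CGCG registers: CGCG-context ratios set to 0")
    return(zero)
  }
  r <- setNames(as.numeric(cnt) / total, nm)
  ncg <- sum(cnt[paste0("c_NCG_", c("A", "C", "G", "T"))])
  cgc <- as.numeric(cnt["c_CGC"])
  cgn <- sum(cnt[paste0("c_CGN_", c("A", "C", "G", "T"))])
  if (ncg == 0) .warnf("CGC/NCG: zero NCG register count, pseudo-count 1 used")
  if (cgc == 0) .warnf("CGN/CGC: zero CGC register count, pseudo-count 1 used")
  c(r, c_CGC_over_NCG = cgc / max(ncg, 1), c_CGN_over_CGC = cgn / max(cgc, 1))
}

#' The 21 FRAGMA features of one sample
#'
#' Concatenation of the 9 Alu-wide end-motif ratios and the 12 CGCG-context
#' features, in the fixed order of \code{\link{fragmaFeatureNames}}.
#'
#' @param x \linkS4class{SampleFragments}.
#' @param alu merged Alu \linkS4class{GRanges}.
#' @param reference \code{DNAStringSet} or FASTA path.
#' @param endMode passed to \code{\link{collectEndEvents}}.
#' @param registers optional precomputed \code{\link{cgcgRegisters}} table.
#' @return Named numeric vector of 21 features.
#' @export
fragmaFeatures <- function(x, alu, reference, endMode = c("both", "left_only"),
                           registers = NULL) {
  if (is.character(reference)) {
    reference <- readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  ev <- collectEndEvents(x, alu, endMode = match.arg(endMode))
  out <- c(fragmaAluRatios(ev),
           fragmaCgcgRatios(ev, alu, reference, registers = registers))
  stopifnot(identical(names(out), fragmaFeatureNames()))
  out
}
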