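#' Simulation configuration
#'
#' Study conditions for the synthetic cfDNA cohorts. The healthy fragment
#' population is a truncated normal length mixture centered on the
#' mono-nucleosomal mode (167 bp, sd 10) with a 5\% di-nucleosomal mode at
#' 320 bp; tumor-derived fragments are shorter (mode 145 bp, sd 12). Tumor
#' copy-number segments rescale local fragment density (a CN=3 segment at
#' tumor fraction tf sits at density 1 + tf/2 relative to diploid
#' background). A fraction of fragment 5' ends is cleaved at CpG sites in
#' Alu-like regions; tumor-origin fragments up-weight cleavage producing CGN
#' end motifs by \code{motifEffect}, emulating the methylation-linked
#' cleavage shift FRAGMA reads out.
#'
#' @param nChroms,chromLength toy genome shape (chromLength >= 2 Mb so arms
#'   are non-degenerate).
#' @param gcMid,gcAmplitude,gcPeriod smooth sinusoidal GC field of the
#'   reference (clamped to [0.3, 0.7]).
#' @param aluDensity Alu-like regions per Mb; \code{aluLength} bp each.
#' @param aluGc GC of Alu-like sequence.
#' @param cgcgEnrichment multiplier on the background CGCG rate inside Alu.
#' @param healthySizeMode,healthySizeSd,longMode,longSd,longWeight healthy
#'   length mixture.
#' @param tumorSizeMode,tumorSizeSd tumor length component.
#' @param cnvSegments data.frame chrom/start/end/cn (0-based half-open;
#'   cn in 0, 1, 3, 4) planted in cancer genomes.
#' @param motifEffect multiplier on CGN-register cleavage for tumor-origin
#'   fragments.
#' @param snapProb probability that a fragment end is cleaved at a CpG site
#'   rather than at its background position.
#' @param depth target mean coverage of a simulated sample.
#' @param lengthRange all fragment lengths clamped to this range.
#' @return Classed list of settings, validated.
#' @export
simulationConfig <- function(nChroms = 5L, chromLength = 3e6,
                             gcMid = 0.5, gcAmplitude = 0.1, gcPeriod = 1e6,
                             aluDensity = 300, aluLength = 300L, aluGc = 0.6,
                             cgcgEnrichment = 5,
                             healthySizeMode = 167, healthySizeSd = 10,
                             longMode = 320, longSd = 20, longWeight = 0.05,
                             tumorSizeMode = 145, tumorSizeSd = 12,
                             cnvSegments = NULL,
                             motifEffect = 2, snapProb = 0.15,
                             depth = 0.3, lengthRange = c(60L, 500L)) {
  if (chromLength < 2e6) .stopf("chromLength < 2 Mb: arms would be degenerate")
  if (nChroms < 2L) .stopf("need at least 2 chromosomes")
  if (is.null(cnvSegments)) {
    half <- floor(chromLength / 2)
    cnvSegments <- data.frame(
      chrom = c("sim2", "sim3"),
      start = c(0, half), end = c(half, chromLength),
      cn = c(3L, 1L))
  }
  if (!all(cnvSegments$cn %in% c(0L, 1L, 3L, 4L)))
    .stopf("planted copy numbers must be in {0, 1, 3, 4}")
  cfg <- list(nChroms = as.integer(nChroms), chromLength = as.numeric(chromLength),
              gcMid = gcMid, gcAmplitude = gcAmplitude, gcPeriod = gcPeriod,
              aluDensity = aluDensity, aluLength = as.integer(aluLength),
              aluGc = aluGc, cgcgEnrichment = cgcgEnrichment,
              healthySizeMode = healthySizeMode, healthySizeSd = healthySizeSd,
              longMode = longMode, longSd = longSd, longWeight = longWeight,
              tumorSizeMode = tumorSizeMode, tumorSizeSd = tumorSizeSd,
              cnvSegments = cnvSegments, motifEffect = motifEffect,
              snapProb = snapProb, depth = depth,
              lengthRange = as.numeric(lengthRange))
  class(cfg) <- "fragstackSimConfig"
  cfg
}

#' Build a toy genome and its manifests
#'
#' Realizes the configured reference: a sinusoidal GC field, Alu-like
#' GC-rich intervals planted at the configured density with CGCG sites
#' enriched, arm boundaries at chromosome midpoints, and a 1-Mb bin
#' manifest with GC computed from the emitted sequence. CpG ("CG"
#' dinucleotide) positions inside Alu are pre-indexed for the fragment
#' simulator's cleavage model. Deterministic given \code{seed}.
#'
#' @param cfg \code{\link{simulationConfig}}.
#' @param seed integer seed.
#' @return A \linkS4class{GenomeAssets}.
#' @export
buildToyGenome <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "fragstackSimConfig"))
  set.seed(.childSeed(seed, "genome"))
  L <- cfg$chromLength
  chromNames <- paste0("sim", seq_len(cfg$nChroms))
  seqs <- vector("list", cfg$nChroms)
  aluAll <- vector("list", cfg$nChroms)
  bg <- 0.25^4  # background CGCG rate at balanced composition
  letters4 <- c("A", "T", "C", "G")
  for (ci in seq_len(cfg$nChroms)) {
    gc <- cfg$gcMid +
      cfg$gcAmplitude * sin(2 * pi * seq_len(L) / cfg$gcPeriod + ci * 1.7)
    gc <- pmin(pmax(gc, 0.3), 0.7)
    # index into A/T/C/G: GC-flag picks the pair, a coin picks within it
    base <- letters4[1L + 2L * (runif(L) < gc) + (runif(L) < 0.5)]
    nAlu <- round(cfg$aluDensity * L / 1e6)
    aluStart <- sort(sample.int(L - cfg$aluLength - 8L, nAlu))  # 0-based
    aLen <- cfg$aluLength
    idx <- rep(aluStart, each = aLen) + seq_len(aLen)
    base[idx] <- letters4[1L + 2L * (runif(length(idx)) < cfg$aluGc) +
                            (runif(length(idx)) < 0.5)]
    nPlant <- max(1L, round(aLen * bg * (cfg$cgcgEnrichment - 1)))
    nPlant <- min(nPlant, aLen %/% 8L)
    offs <- matrix(replicate(nAlu, sample.int(aLen - 4L, nPlant)),
                   nrow = nPlant)
    at <- rep(aluStart, each = nPlant) + as.vector(offs)
    base[rep(at, each = 4L) + rep(0:3, length(at))] <-
      rep(c("C", "G", "C", "G"), length(at))
    seqs[[ci]] <- paste(base, collapse = "")
    aluAll[[ci]] <- data.frame(chrom = chromNames[ci], start = aluStart + 1L)
  }
  reference <- DNAStringSet(unlist(seqs))
  names(reference) <- chromNames
  si <- Seqinfo(chromNames, rep(L, cfg$nChroms))
  aluDf <- do.call(rbind, aluAll)
  alu <- reduce(sort(GRanges(aluDf$chrom,
                             IRanges(aluDf$start, width = cfg$aluLength),
                             seqinfo = si)))
  mid <- floor(L / 2)
  armDf <- data.frame(
    armId = as.vector(rbind(paste0(seq_len(cfg$nChroms), "p"),
                            paste0(seq_len(cfg$nChroms), "q"))),
    chrom = rep(chromNames, each = 2L),
    start = rep(c(0, mid), cfg$nChroms),
    end = rep(c(mid, L), cfg$nChroms),
    excluded = FALSE)
  arms <- armGcFromReference(makeArmTable(armDf, si), reference)
  bins <- suppressMessages(buildBinManifest(si, 1e6, reference = reference))
  # CpG cleavage site index: 0-based positions of the C of each CG inside Alu
  sites <- lapply(chromNames, function(ch) {
    m <- Biostrings::matchPattern("CG", reference[[ch]])
    p <- start(m) - 1L
    inAlu <- overlapsAny(GRanges(ch, IRanges(p + 1L, width = 2L)), alu)
    sort(p[inAlu])
  })
  names(sites) <- chromNames
  new("GenomeAssets", reference = reference, seqinfo = si, arms = arms,
      bins = bins, alu = alu,
      config = c(cfg, list(cgSites = sites,
                           cgcgRegisters = cgcgRegisters(alu, reference))))
}

.truncLengths <- function(n, mode, sdv, longMode, longSd, longWeight, range) {
  isLong <- runif(n) < longWeight
  len <- ifelse(isLong, rnorm(n, longMode, longSd), rnorm(n, mode, sdv))
  as.integer(pmin(pmax(round(len), range[1]), range[2]))
}

#' Simulate one cfDNA sample
#'
#' Draws fragments from the mixture the tumor-fraction dial controls:
#' each fragment is tumor-origin with probability tf; tumor-origin
#' fragments use the shorter length mode, a copy-number-weighted genomic
#' position (planted segments), and CGN-biased CpG cleavage; healthy-origin
#' fragments use the healthy mixture and uniform positions. A healthy label
#' requires tf = 0.
#'
#' @param assets \linkS4class{GenomeAssets} from \code{\link{buildToyGenome}}.
#' @param label \code{"healthy"} or \code{"cancer"}.
#' @param tf tumor fraction in [0, 1].
#' @param seed integer seed.
#' @param sampleId sample identifier.
#' @param depth override of the configured mean coverage.
#' @return A \linkS4class{SampleFragments} (metadata: label, tf).
#' @export
simulateSample <- function(assets, label = c("healthy", "cancer"), tf = 0,
                           seed = 1L, sampleId = NULL, depth = NULL) {
  label <- match.arg(label)
  cfg <- assets@config
  .assertScalarNumber(tf, "tf", lower = 0, upper = 1)
  if (label == "healthy" && tf > 0)
    .stopf("a healthy sample must have tf = 0 (got %g)", tf)
  depth <- depth %||% cfg$depth
  sampleId <- sampleId %||% sprintf("%s_tf%03d_s%d", label, round(tf * 1000), seed)
  set.seed(.childSeed(seed, paste0("frag", sampleId)))
  chromNames <- GenomeInfoDb::seqnames(assets@seqinfo)
  L <- cfg$chromLength
  G <- L * cfg$nChroms
  n <- round(depth * G / cfg$healthySizeMode)
  tumor <- runif(n) < tf
  len <- integer(n)
  len[!tumor] <- .truncLengths(sum(!tumor), cfg$healthySizeMode,
                               cfg$healthySizeSd, cfg$longMode, cfg$longSd,
                               cfg$longWeight, cfg$lengthRange)
  if (any(tumor))
    len[tumor] <- .truncLengths(sum(tumor), cfg$tumorSizeMode, cfg$tumorSizeSd,
                                cfg$longMode, cfg$longSd, cfg$longWeight,
                                cfg$lengthRange)
  ## positions: healthy-origin uniform; tumor-origin weighted by copy number
  chromIdx <- integer(n)
  pos0 <- numeric(n)
  hi <- which(!tumor)
  chromIdx[hi] <- sample.int(cfg$nChroms, length(hi), replace = TRUE)
  pos0[hi] <- floor(runif(length(hi), 0, L - cfg$lengthRange[2]))
  ti <- which(tumor)
  if (length(ti)) {
    seg <- cfg$cnvSegments
    regions <- data.frame(chrom = rep(chromNames, each = 1L),
                          start = 0, end = L, cn = 2)
    # split chromosomes carrying segments into constant-cn pieces
    reg <- list()
    for (ch in chromNames) {
      s <- seg[seg$chrom == ch, , drop = FALSE]
      cuts <- sort(unique(c(0, L, s$start, s$end)))
      for (j in seq_len(length(cuts) - 1L)) {
        a <- cuts[j]; b <- cuts[j + 1L]
        cn <- 2
        m <- s$start <= a & s$end >= b
        if (any(m)) cn <- s$cn[which(m)[1L]]
        reg[[length(reg) + 1L]] <- data.frame(chrom = ch, start = a, end = b,
                                              cn = cn)
      }
    }
    reg <- do.call(rbind, reg)
    w <- reg$cn * (reg$end - reg$start)
    ri <- sample.int(nrow(reg), length(ti), replace = TRUE, prob = w)
    chromIdx[ti] <- match(reg$chrom[ri], chromNames)
    pos0[ti] <- floor(reg$start[ri] +
                        runif(length(ti)) * pmax(reg$end[ri] - reg$start[ri] -
                                                   cfg$lengthRange[2], 1))
  }
  ## CpG cleavage: snap a fraction of 5' ends to the nearest CG site in Alu.
  ## Family CGN vs NCG decides the register offset; tumor-origin fragments
  ## up-weight CGN by motifEffect.
  snapL <- runif(n) < cfg$snapProb
  snapR <- !snapL & runif(n) < cfg$snapProb
  pCGN <- ifelse(tumor, cfg$motifEffect / (cfg$motifEffect + 1), 0.5)
  famCGN <- runif(n) < pCGN
  for (ci in seq_len(cfg$nChroms)) {
    sites <- cfg$cgSites[[ci]]
    if (length(sites) < 2L) next
    onchr <- chromIdx == ci
    iL <- which(onchr & snapL)
    if (length(iL)) {
      s <- .nearestSite(sites, pos0[iL])
      pos0[iL] <- ifelse(famCGN[iL], s, s - 1L)
    }
    iR <- which(onchr & snapR)
    if (length(iR)) {
      s <- .nearestSite(sites, pos0[iR] + len[iR])
      endx <- ifelse(famCGN[iR], s + 2L, s + 3L)
      pos0[iR] <- endx - len[iR]
    }
  }
  ok <- pos0 >= 0 & (pos0 + len) <= L
  chromIdx <- chromIdx[ok]; pos0 <- pos0[ok]; len <- len[ok]
  gr <- GRanges(chromNames[chromIdx], IRanges(pos0 + 1L, width = len),
                seqinfo = assets@seqinfo)
  mcols(gr)$mapq <- rep(60L, length(gr))
  gr <- sort(.attachMotifs(gr, assets@reference))
  .newSampleFragments(sampleId, gr,
                      counters = c(read = length(gr), clipped = sum(!ok)),
                      metadata = list(label = label, tf = tf, seed = seed))
}

.nearestSite <- function(sites, pos) {
  i <- findInterval(pos, sites)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(sites))
  ifelse(abs(sites[lo] - pos) <= abs(sites[hi] - pos), sites[lo], sites[hi])
}

#' Simulate a cohort
#'
#' Cancer samples draw tumor fractions uniformly from \code{tfRange};
#' healthy samples are tf = 0. The default cohort shape mirrors a
#' training-sized case/control study (119 cancer / 112 healthy). Cancer
#' samples receive a deterministic stage proxy (tf tertile: I/II/III) used
#' by the stratified evaluation. With \code{dir}, per-sample BED3 files, a
#' cohort sheet TSV and a truth JSON are written; otherwise the fragments
#' stay in memory.
#'
#' @param assets \linkS4class{GenomeAssets}.
#' @param nCancer,nHealthy cohort sizes (>= 2 each).
#' @param tfRange tumor-fraction range for cancers (may be degenerate,
#'   e.g. c(0, 0) for a null cohort).
#' @param split split label written to the sheet.
#' @param seed integer seed; the cohort is bit-reproducible from it.
#' @param dir optional output directory.
#' @param depth override of configured depth.
#' @return List: \code{samples} (named list of
#'   \linkS4class{SampleFragments}, or file paths when \code{dir} is given),
#'   \code{sheet} (sample/label/split/tf/stage), \code{truth}.
#' @export
simulateCohort <- function(assets, nCancer = 119L, nHealthy = 112L,
                           tfRange = c(0.05, 0.3), split = "train",
                           seed = 1L, dir = NULL, depth = NULL) {
  if (nCancer < 2L || nHealthy < 2L)
    .stopf("need at least 2 samples per class")
  set.seed(.childSeed(seed, paste0("cohort", split)))
  tfs <- runif(nCancer, tfRange[1], tfRange[2])
  stage <- if (diff(range(tfs)) > 0) {
    q <- quantile(tfs, c(1 / 3, 2 / 3))
    ifelse(tfs <= q[1], "I", ifelse(tfs <= q[2], "II", "III"))
  } else rep("I", nCancer)
  sheet <- data.frame(
    sample = c(sprintf("%s_cancer%03d", split, seq_len(nCancer)),
               sprintf("%s_healthy%03d", split, seq_len(nHealthy))),
    label = c(rep("cancer", nCancer), rep("healthy", nHealthy)),
    split = split,
    tf = c(tfs, rep(0, nHealthy)),
    stage = c(stage, rep(NA_character_, nHealthy)),
    stringsAsFactors = FALSE)
  samples <- vector("list", nrow(sheet))
  names(samples) <- sheet$sample
  for (i in seq_len(nrow(sheet))) {
    sf <- simulateSample(assets,
                         label = sheet$label[i],
                         tf = if (sheet$label[i] == "cancer") sheet$tf[i] else 0,
                         seed = .childSeed(seed, sheet$sample[i]),
                         sampleId = sheet$sample[i], depth = depth)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      p <- file.path(dir, paste0(sheet$sample[i], ".bed"))
      writeFragmentsBed(sf, p)
      samples[[i]] <- p
    } else samples[[i]] <- sf
  }
  truth <- list(seed = seed, split = split, tf = setNames(sheet$tf, sheet$sample),
                cnvSegments = assets@config$cnvSegments,
                motifEffect = assets@config$motifEffect)
  if (!is.null(dir)) {
    write.table(sheet, file.path(dir, "cohort_sheet.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  list(samples = samples, sheet = sheet, truth = truth)
}
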