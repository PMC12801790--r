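.fragmaSample <- function(refStr, frags0, name = "fg") {
  seqs <- c(fg1 = refStr)
  fragmentsFromBed(data.frame("fg1", frags0$start, frags0$end),
                   Biostrings::DNAStringSet(seqs), seqinfoFor(seqs),
                   sampleId = name)
}

.aluGr <- function(alu0) {
  GenomicRanges::GRanges("fg1", IRanges::IRanges(
    vapply(alu0, `[`, numeric(1), 1) + 1,
    vapply(alu0, `[`, numeric(1), 2)))
}

test_that("end events respect per-end Alu membership", {
  refStr <- paste(rep("ACGT", 150), collapse = "")  # 600 bp
  sf <- .fragmaSample(refStr, data.frame(start = c(100, 400, 40),
                                         end = c(267, 560, 260)))
  alu <- .aluGr(list(c(0, 300)))
  ev <- collectEndEvents(sf, alu)
  # fragment 1: both ends in [0,300) -> 2 events at 100 (+) and 266 (-)
  # fragment 2: both ends outside -> 0; fragment 3: left in, right in -> 2
  expect_equal(sort(ev$pos[ev$strand == "+"]), c(40, 100))
  expect_equal(sort(ev$pos[ev$strand == "-"]), c(259, 266))
  # left end in, right end out
  sf2 <- .fragmaSample(refStr, data.frame(start = 200, end = 500))
  ev2 <- collectEndEvents(sf2, alu)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$strand, "+")
  expect_error(collectEndEvents(sf, GenomicRanges::GRanges()), "no regions")
})

test_that("Alu-wide motif ratios follow hand counts", {
  ev <- data.frame(chrom = "fg1", pos = 1:10, strand = "+",
                   motif = c("CGA", "CGA", "ACG", rep("TTT", 7)))
  r <- fragmaAluRatios(ev)
  expect_equal(unname(r["r_CGA"]), 0.2)
  expect_equal(unname(r["r_ACG"]), 0.1)
  expect_equal(unname(r["r_CGN_over_NCG"]), 2.0)
  # all-CGT events
  ev2 <- transform(ev, motif = "CGT")
  expect_warning(r2 <- fragmaAluRatios(ev2), "pseudo-count")
  expect_equal(unname(r2["r_CGT"]), 1.0)
  expect_equal(sum(r2[1:8]), 1.0)
  expect_equal(unname(r2["r_CGN_over_NCG"]), 10)  # pseudo-count denominator
})

test_that("CGCG registers classify single placed events as specified", {
  refStr <- "AACGCGTT"   # one CGCG at 0-based position 2
  alu <- .aluGr(list(c(0, 8)))
  ref <- Biostrings::DNAStringSet(c(fg1 = refStr))
  # event at pos 2 (+): motif CGC -> c_CGC = 1, ratio-of-ratios guard at 0
  ev <- data.frame(chrom = "fg1", pos = 2L, strand = "+", motif = "CGC")
  r <- suppressWarnings(fragmaCgcgRatios(ev, alu, ref))
  expect_equal(unname(r["c_CGC"]), 1.0)
  expect_equal(sum(r[1:10]), 1.0)
  expect_equal(unname(r["c_CGN_over_CGC"]), 0)
  # event at pos 1 (+): register p-1, motif ACG -> c_NCG_A = 1
  ev2 <- data.frame(chrom = "fg1", pos = 1L, strand = "+", motif = "ACG")
  r2 <- suppressWarnings(fragmaCgcgRatios(ev2, alu, ref))
  expect_equal(unname(r2["c_NCG_A"]), 1.0)
  # no events on registers -> zeros with warning
  ev3 <- data.frame(chrom = "fg1", pos = 7L, strand = "+", motif = "TTA")
  expect_warning(r3 <- fragmaCgcgRatios(ev3, alu, ref), "no end events")
  expect_equal(sum(r3), 0)
})

test_that("all 21 features match the exhaustive oracle on a toy genome", {
  set.seed(42)
  # 200 bp reference rich in CG/CGCG content plus random sequence
  refStr <- paste0(
    "ATTACGCGTTGGCGCGCGATCCGTACGTTAACGGCGCATCGCGTATTGCC",
    paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = ""),
    "TTCGCGGACGTTACGCGTAGCCGATTGGCACGCGTTACCGGTTAACGCGA",
    "ACGTACGCGT", "GGCCTTAAGG")
  alu0 <- list(c(0, 60), c(120, 200))
  frags0 <- data.frame(
    start = c(0, 3, 10, 14, 25, 38, 55, 70, 90, 121, 128, 130, 143, 150,
              155, 160, 170, 2, 33, 47),
    end = c(50, 40, 130, 60, 140, 150, 160, 180, 196, 170, 190, 198, 180,
            197, 199, 200, 198, 36, 70, 90))
  sf <- .fragmaSample(refStr, frags0)
  alu <- .aluGr(alu0)
  got <- suppressWarnings(
    fragmaFeatures(sf, alu, Biostrings::DNAStringSet(c(fg1 = refStr))))
  want <- fragmaOracle(refStr, frags0, alu0)
  expect_equal(got, want[names(got)], tolerance = 1e-12)
  expect_length(got, 21L)
  # partition invariants
  expect_lte(sum(got[paste0("r_", c("CGA","CGC","CGG","CGT",
                                    "ACG","CCG","GCG","TCG"))]), 1 + 1e-12)
  cg10 <- got[10:19]
  expect_equal(sum(cg10), 1.0, tolerance = 1e-12)
})

test_that("features are invariant under exact fragment duplication", {
  a <- cachedToyGenome()
  s <- simulateSample(a, "cancer", tf = 0.15, seed = 77, sampleId = "dup",
                      depth = 0.03)
  f1 <- suppressWarnings(fragmaFeatures(s, a@alu, a@reference,
                                        registers = a@config$cgcgRegisters))
  gr2 <- rep(fragments(s), 2)
  s2 <- new("SampleFragments", sampleId = "dup2", fragments = gr2,
            counters = c(read = length(gr2)), metadata = list())
  f2 <- suppressWarnings(fragmaFeatures(s2, a@alu, a@reference,
                                        registers = a@config$cgcgRegisters))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("tumor motif bias raises the CGN/NCG ratio", {
  a <- cachedToyGenome()
  rr <- vapply(1:6, function(i) {
    ca <- simulateSample(a, "cancer", tf = 0.3, seed = 900 + i,
                         sampleId = paste0("m", i), depth = 0.08)
    he <- simulateSample(a, "healthy", seed = 950 + i,
                         sampleId = paste0("n", i), depth = 0.08)
    fc <- suppressWarnings(fragmaFeatures(ca, a@alu, a@reference,
                                          registers = a@config$cgcgRegisters))
    fh <- suppressWarnings(fragmaFeatures(he, a@alu, a@reference,
                                          registers = a@config$cgcgRegisters))
    fc["r_CGN_over_NCG"] - fh["r_CGN_over_NCG"]
  }, numeric(1))
  expect_gt(mean(rr), 0)
  expect_true(all(rr > 0))
})
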