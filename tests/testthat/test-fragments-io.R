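toySeqs <- c(toy1 = paste0("ACGTT", paste(rep("ACGT", 60), collapse = ""),
                           "AACCGGTT"),
             toy2 = paste(rep("TGCA", 70), collapse = ""))

test_that("BED fragments get lengths and reference motifs", {
  si <- seqinfoFor(toySeqs)
  ref <- Biostrings::DNAStringSet(toySeqs)
  sf <- fragmentsFromBed(data.frame("toy1", c(10, 0), c(177, 167)), ref, si)
  gr <- fragments(sf)
  expect_equal(GenomicRanges::width(gr), c(167L, 167L))
  # reference "ACGTT...": fragment starting at 0 has left motif ACG
  expect_equal(gr$motifLeft[GenomicRanges::start(gr) == 1], "ACG")
  # right motif is the reverse complement of the last three bases
  last3 <- substr(toySeqs[["toy1"]], 165, 167)
  expect_equal(gr$motifRight[GenomicRanges::end(gr) == 167], revcompStr(last3))
})

test_that("fragment BED parse errors name the offending line", {
  si <- seqinfoFor(toySeqs)
  ref <- Biostrings::DNAStringSet(toySeqs)
  p <- tempfile()
  writeLines(c("toy1\t0\t100", "toy1\t50"), p)
  expect_error(readFragmentsBed(p, ref, si), "line 2")
  writeLines("toy1\t100\t999999", p)
  expect_error(readFragmentsBed(p, ref, si), "outside chromosome")
  writeLines("nope\t0\t100", p)
  expect_error(readFragmentsBed(p, ref, si), "unknown chromosome")
})

test_that("BAM and BED routes yield identical fragments and motifs", {
  skip_if_not_installed("Rsamtools")
  a <- cachedToyGenome()
  s <- simulateSample(a, "healthy", seed = 5, sampleId = "io", depth = 0.02)
  bed <- tempfile(fileext = ".bed")
  writeFragmentsBed(s, bed)
  viaBed <- readFragmentsBed(bed, a@reference, a@seqinfo, sampleId = "io")
  bam <- writeFragmentsBam(s, tempfile(fileext = ".bam"), a@seqinfo)
  viaBam <- readFragmentsBam(bam, a@reference, a@seqinfo, sampleId = "io")
  grBed <- fragments(viaBed)
  grBam <- fragments(viaBam)
  expect_equal(length(grBed), length(grBam))
  expect_identical(as.character(GenomicRanges::seqnames(grBed)),
                   as.character(GenomicRanges::seqnames(grBam)))
  expect_identical(GenomicRanges::start(grBed), GenomicRanges::start(grBam))
  expect_identical(GenomicRanges::width(grBed), GenomicRanges::width(grBam))
  expect_identical(grBed$motifLeft, grBam$motifLeft)
  expect_identical(grBed$motifRight, grBam$motifRight)
  # and the downstream FRAGMA block agrees exactly
  fBed <- suppressWarnings(fragmaFeatures(viaBed, a@alu, a@reference))
  fBam <- suppressWarnings(fragmaFeatures(viaBam, a@alu, a@reference))
  expect_equal(fBed, fBam)
})

test_that("BAM reader applies mapq and duplicate filters", {
  si <- GenomeInfoDb::Seqinfo("toy1", nchar(toySeqs[["toy1"]]))
  ref <- Biostrings::DNAStringSet(toySeqs["toy1"])
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:toy1\tLN:%d", nchar(toySeqs[["toy1"]])),
    "a\t99\ttoy1\t1\t60\t20M\t=\t148\t167\t*\t*",
    "b\t99\ttoy1\t2\t10\t20M\t=\t149\t167\t*\t*",   # fails mapq
    "c\t1123\ttoy1\t3\t60\t20M\t=\t150\t167\t*\t*", # duplicate flag
    "a\t147\ttoy1\t148\t60\t20M\t=\t1\t-167\t*\t*",
    "b\t147\ttoy1\t149\t10\t20M\t=\t2\t-167\t*\t*",
    "c\t1171\ttoy1\t150\t60\t20M\t=\t3\t-167\t*\t*"), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  sf <- readFragmentsBam(bam, ref, si)
  expect_equal(length(fragments(sf)), 1L)
  expect_equal(unname(readCounters(sf)["low_mapq"]), 1)
  expect_equal(GenomicRanges::start(fragments(sf)), 1L)
  expect_equal(GenomicRanges::width(fragments(sf)), 167L)
})

test_that("subsampling is a seeded Bernoulli thinning", {
  a <- cachedToyGenome()
  s <- simulateSample(a, "healthy", seed = 6, sampleId = "sub", depth = 0.12)
  n <- length(fragments(s))
  expect_gt(n, 5000)
  # identity at fraction 1
  expect_identical(fragments(subsampleFragments(s, 1, seed = 9)), fragments(s))
  # determinism
  s1 <- subsampleFragments(s, 0.5, seed = 42)
  s2 <- subsampleFragments(s, 0.5, seed = 42)
  expect_identical(fragments(s1), fragments(s2))
  # kept count within 3 binomial SDs of n/2
  k <- length(fragments(s1))
  expect_lt(abs(k - n / 2), 3 * sqrt(n * 0.25))
  # composition: 0.8 then 0.5 averages to fraction 0.4 over seeds
  fr <- vapply(1:30, function(sd) {
    length(fragments(subsampleFragments(
      subsampleFragments(s, 0.8, seed = sd), 0.5, seed = sd + 1000))) / n
  }, numeric(1))
  se <- sqrt(0.4 * 0.6 / n) / sqrt(30)
  expect_lt(abs(mean(fr) - 0.4), 5 * se)
  expect_error(subsampleFragments(s, 0, seed = 1), "targetFraction")
  expect_error(subsampleFragments(s, 1.2, seed = 1), "targetFraction")
})

test_that("end motifs mirror on a palindromic reference", {
  # palindrome: reverse complement of the whole sequence equals itself
  pal <- "ACGCGT"
  seqs <- c(p1 = paste(rep(pal, 20), collapse = ""))
  ref <- Biostrings::DNAStringSet(seqs)
  si <- seqinfoFor(seqs)
  L <- nchar(seqs[["p1"]])
  # fragment and its mirror about the sequence center
  s0 <- 12; e0 <- 60
  sf <- fragmentsFromBed(data.frame("p1", c(s0, L - e0), c(e0, L - s0)),
                         ref, si)
  gr <- fragments(sf)
  expect_identical(gr$motifRight[1], gr$motifLeft[2])
  expect_identical(gr$motifLeft[1], gr$motifRight[2])
})
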