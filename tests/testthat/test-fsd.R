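.fsdFixture <- function(nArms = 12L, armLen = 1e6) {
  nCh <- nArms / 2L
  seqs <- setNames(rep(2 * armLen, nCh), paste0("f", seq_len(nCh)))
  si <- GenomeInfoDb::Seqinfo(names(seqs), unname(seqs))
  df <- data.frame(
    armId = as.vector(rbind(paste0(seq_len(nCh), "p"), paste0(seq_len(nCh), "q"))),
    chrom = rep(names(seqs), each = 2),
    start = rep(c(0, armLen), nCh), end = rep(c(armLen, 2 * armLen), nCh),
    excluded = FALSE)
  arms <- makeArmTable(df, si)
  S4Vectors::mcols(arms)$gc <- seq(0.35, 0.6, length.out = nArms)
  list(si = si, arms = arms)
}

.fsdSample <- function(fx, intervals, sampleId = "s") {
  ref <- Biostrings::DNAStringSet(setNames(
    rep(strrep("A", unname(GenomeInfoDb::seqlengths(fx$si))[1]),
        length(GenomeInfoDb::seqnames(fx$si))),
    GenomeInfoDb::seqnames(fx$si)))
  fragmentsFromBed(intervals, ref, fx$si, sampleId = sampleId)
}

test_that("size bins are half-open and the support is enforced", {
  fx <- .fsdFixture()
  sf <- .fsdSample(fx, data.frame("f1",
                                  c(100, 200, 300, 400, 5e5 + 10),
                                  c(100 + 110, 200 + 114, 300 + 115,
                                    400 + 90, 5e5 + 10 + 229)))
  m <- fsdRaw(sf, fx$arms)
  expect_identical(dim(m), c(12L, 24L))
  # 110 and 114 -> bin "110"; 115 -> bin "115"; 90 ignored; 229 -> last bin
  expect_equal(m["1p", "110"], 2L)
  expect_equal(m["1p", "115"], 1L)
  expect_equal(m["1p", "225"], 1L)
  expect_equal(sum(m), 4L)
  # conservation: row sums equal in-support fragments per arm
  w <- GenomicRanges::width(fragments(sf))
  expect_equal(sum(m["1p", ]), sum(w >= 110 & w < 230))
})

test_that("midpoint decides the arm and excluded arms emit nothing", {
  fx <- .fsdFixture(nArms = 4L)
  # fragment straddling the arm boundary: midpoint in q arm
  sf <- .fsdSample(fx, data.frame("f1", 1e6 - 50, 1e6 + 100))
  m <- fsdRaw(sf, fx$arms)
  expect_equal(m["1q", "150"], 1L)
  expect_equal(sum(m["1p", ]), 0L)
  # exclusion: drop 1p from the included set entirely
  arms2 <- fx$arms
  S4Vectors::mcols(arms2)$excluded <- c(TRUE, FALSE, FALSE, FALSE)
  m2 <- fsdRaw(sf, arms2)
  expect_identical(rownames(m2), c("1q", "2p", "2q"))
})

test_that("per-size-bin GC correction flattens arm-GC trends", {
  fx <- .fsdFixture(nArms = 20L)
  gc <- fx$arms$gc
  set.seed(2)
  # counts proportional to gc in every size bin
  raw <- sapply(1:24, function(k) rpois(20, 400 * gc))
  dimnames(raw) <- list(fx$arms$armId, sizeBinScheme()$labels)
  attr(raw, "armGc") <- setNames(gc, fx$arms$armId)
  corr <- fsdGcCorrect(raw)
  slopes <- vapply(1:24, function(k) coef(lm(corr[, k] ~ gc))[2], numeric(1))
  slopes0 <- vapply(1:24, function(k) coef(lm(raw[, k] ~ gc))[2], numeric(1))
  expect_lt(median(abs(slopes)), median(abs(slopes0)) * 0.2)
  expect_true(all(corr >= 0))
  # flat counts: near-identity
  flat <- matrix(rpois(20 * 24, 500), 20, dimnames = dimnames(raw))
  attr(flat, "armGc") <- attr(raw, "armGc")
  corrFlat <- fsdGcCorrect(flat)
  expect_lt(max(abs(corrFlat - flat) / flat), 0.12)
  # degenerate gc: identity + warning
  attr(flat, "armGc") <- setNames(rep(0.5, 20), fx$arms$armId)
  expect_warning(same <- fsdGcCorrect(flat), "skipped")
  expect_equal(unname(same[, 1]), unname(flat[, 1]))
})

test_that("normalizer uses training-only sample statistics (n-1 sd)", {
  dn <- list(c("1p", "1q"), as.character(sizeBinScheme()$labels))
  mk <- function(v) matrix(v, 2, 24, dimnames = dn)
  tr <- list(mk(10), mk(20), mk(30))
  nz <- fitFsdNormalizer(tr)
  expect_equal(unname(nz@mu[1]), 20)
  expect_equal(unname(nz@sigma[1]), 10)  # sample sd of {10,20,30}
  z <- fsdFeatures(mk(30), nz)
  expect_equal(unname(z[1]), 1.0)
  expect_length(z, 48L)
  # round-trip: z * sigma + mu recovers the corrected counts
  x <- mk(17.5)
  z2 <- fsdFeatures(x, nz)
  expect_equal(unname(z2 * nz@sigma + nz@mu), rep(17.5, 48), tolerance = 1e-9)
  # z of the training cohort has mean 0, sd 1 per feature
  ztr <- sapply(tr, fsdFeatures, normalizer = nz)
  expect_equal(unname(rowMeans(ztr)), rep(0, 48), tolerance = 1e-12)
  expect_equal(unname(apply(ztr, 1, sd)), rep(1, 48), tolerance = 1e-12)
  # degenerate training: all z forced to zero
  expect_warning(nzd <- fitFsdNormalizer(list(mk(5), mk(5), mk(5))),
                 "degenerate")
  expect_equal(unname(fsdFeatures(mk(9), nzd)), rep(0, 48))
  # shape mismatch refused
  bad <- matrix(1, 3, 24, dimnames = list(c("1p", "1q", "2p"), dn[[2]]))
  expect_error(fsdFeatures(bad, nz), "layout")
})

test_that("shorter cancer fragments shift low-size-bin z-scores upward", {
  a <- cachedToyGenome()
  nPer <- 12L
  mats <- list()
  lab <- character(0)
  for (i in seq_len(nPer)) {
    h <- simulateSample(a, "healthy", seed = 300 + i,
                        sampleId = paste0("h", i), depth = 0.1)
    c_ <- simulateSample(a, "cancer", tf = 0.2, seed = 600 + i,
                         sampleId = paste0("c", i), depth = 0.1)
    mats[[paste0("h", i)]] <- suppressWarnings(fsdGcCorrect(fsdRaw(h, a@arms)))
    mats[[paste0("c", i)]] <- suppressWarnings(fsdGcCorrect(fsdRaw(c_, a@arms)))
    lab <- c(lab, "healthy", "cancer")
  }
  # tail size-bins can be empty at this depth; the zero-variance guard warns
  nz <- suppressWarnings(fitFsdNormalizer(mats[lab == "healthy"]))
  scheme <- sizeBinScheme()
  short <- rep(as.integer(scheme$labels) < 150, length(includedArms(a@arms)))
  zshort <- vapply(mats, function(m) mean(fsdFeatures(m, nz)[short]), numeric(1))
  expect_lt(wilcox.test(zshort[lab == "cancer"], zshort[lab == "healthy"],
                        alternative = "greater")$p.value, 0.01)
})
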