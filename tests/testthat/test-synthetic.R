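test_that("toy genome geometry follows the configuration", {
  cfg <- simulationConfig(nChroms = 4L, chromLength = 3e6,
                          cnvSegments = data.frame(chrom = "sim2", start = 0,
                                                   end = 1.5e6, cn = 3L))
  a <- buildToyGenome(cfg, seed = 5)
  expect_length(a@reference, 4L)
  expect_length(a@arms, 8L)
  expect_length(a@bins, 12L)
  expect_true(all(GenomicRanges::width(a@bins) == 1e6))
  expect_error(simulationConfig(chromLength = 1e6), "2 Mb")
  expect_error(simulationConfig(cnvSegments = data.frame(
    chrom = "sim1", start = 0, end = 1e6, cn = 2L)), "copy numbers")
})

test_that("genome realization is deterministic and CGCG-enriched in Alu", {
  cfg <- simulationConfig(nChroms = 2L, chromLength = 2e6)
  a1 <- buildToyGenome(cfg, seed = 9)
  a2 <- buildToyGenome(cfg, seed = 9)
  expect_identical(as.character(a1@reference), as.character(a2@reference))
  a3 <- buildToyGenome(cfg, seed = 10)
  expect_false(identical(as.character(a1@reference), as.character(a3@reference)))
  # CGCG density in Alu at least 3x the genome-background rate
  cgcgIn <- function(gr) {
    v <- Biostrings::extractAt(a1@reference[["sim1"]],
                               IRanges::ranges(gr[GenomicRanges::seqnames(gr) == "sim1"]))
    sum(Biostrings::vcountPattern("CGCG", v))
  }
  aluW <- sum(GenomicRanges::width(a1@alu[GenomicRanges::seqnames(a1@alu) == "sim1"]))
  dAlu <- cgcgIn(a1@alu) / aluW
  dGenome <- Biostrings::countPattern("CGCG", a1@reference[["sim1"]]) / 2e6
  expect_gte(dAlu / dGenome, 3)
})

test_that("healthy fragment lengths match the mixture expectation", {
  a <- cachedToyGenome()
  s <- simulateSample(a, "healthy", seed = 21, sampleId = "len", depth = 0.2)
  want <- 167 * 0.95 + 320 * 0.05
  expect_lt(abs(mean(GenomicRanges::width(fragments(s))) - want), 2)
  # tumor-fraction dial shifts the mean down
  sc <- simulateSample(a, "cancer", tf = 0.5, seed = 21, sampleId = "lenc",
                       depth = 0.2)
  expect_lt(mean(GenomicRanges::width(fragments(sc))),
            mean(GenomicRanges::width(fragments(s))) - 5)
})

test_that("a tf = 0 cancer draw is statistically a healthy draw", {
  a <- cachedToyGenome()
  s0 <- simulateSample(a, "cancer", tf = 0, seed = 31, sampleId = "null",
                       depth = 0.55)
  sh <- simulateSample(a, "healthy", seed = 32, sampleId = "hh", depth = 0.55)
  expect_gt(length(fragments(s0)), 48000)
  ks <- suppressWarnings(
    ks.test(GenomicRanges::width(fragments(s0)),
            GenomicRanges::width(fragments(sh))))
  expect_gt(ks$p.value, 0.01)
  ksPos <- suppressWarnings(
    ks.test(GenomicRanges::start(fragments(s0)),
            GenomicRanges::start(fragments(sh))))
  expect_gt(ksPos$p.value, 0.01)
  expect_error(simulateSample(a, "healthy", tf = 0.1, seed = 1), "tf = 0")
})

test_that("planted CN=3 segments carry the closed-form density excess", {
  a <- cachedToyGenome()
  # default truth: sim2 [0, 1.5 Mb) at CN 3; background diploid elsewhere
  for (tf in c(0.3)) {
    s <- simulateSample(a, "cancer", tf = tf, seed = 41, sampleId = "cn",
                        depth = 0.4)
    gr <- fragments(s)
    mid <- (GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2
    seg <- as.character(GenomicRanges::seqnames(gr)) == "sim2" & mid < 1.5e6
    bgd <- as.character(GenomicRanges::seqnames(gr)) %in% c("sim1", "sim4", "sim5")
    dens <- (sum(seg) / 1.5e6) / (sum(bgd) / (3 * 3e6))
    expect_equal(dens, 1 + tf / 2, tolerance = 0.03)
  }
})

test_that("cohorts are reproducible, staged by tf tertile, and well-formed", {
  a <- cachedToyGenome()
  co <- simulateCohort(a, nCancer = 6L, nHealthy = 3L, tfRange = c(0.05, 0.3),
                       seed = 51, depth = 0.02)
  expect_equal(nrow(co$sheet), 9L)
  expect_setequal(unique(co$sheet$label), c("cancer", "healthy"))
  expect_true(all(co$sheet$tf[co$sheet$label == "healthy"] == 0))
  tfs <- co$sheet$tf[co$sheet$label == "cancer"]
  st <- co$sheet$stage[co$sheet$label == "cancer"]
  expect_true(all(tfs >= 0.05 & tfs <= 0.3))
  # stage proxy is monotone in tf
  expect_lte(max(tfs[st == "I"]), min(tfs[st != "I"]))
  expect_lte(max(tfs[st != "III"]), min(tfs[st == "III"]))
  co2 <- simulateCohort(a, nCancer = 6L, nHealthy = 3L, tfRange = c(0.05, 0.3),
                        seed = 51, depth = 0.02)
  h1 <- vapply(co$samples, function(s) length(fragments(s)), integer(1))
  h2 <- vapply(co2$samples, function(s) length(fragments(s)), integer(1))
  expect_identical(h1, h2)
  expect_identical(co$sheet, co2$sheet)
  expect_error(simulateCohort(a, nCancer = 1L, nHealthy = 3L), "at least 2")
})

test_that("cohort directories round-trip through BED identically", {
  a <- cachedToyGenome()
  dir <- tempfile()
  co <- simulateCohort(a, nCancer = 2L, nHealthy = 3L, tfRange = c(0.2, 0.3),
                       seed = 61, dir = dir, depth = 0.02)
  expect_true(file.exists(file.path(dir, "cohort_sheet.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  coMem <- simulateCohort(a, nCancer = 2L, nHealthy = 3L,
                          tfRange = c(0.2, 0.3), seed = 61, depth = 0.02)
  s1 <- readFragmentsBed(co$samples[[1]], a@reference, a@seqinfo,
                         sampleId = sampleId(coMem$samples[[1]]))
  expect_identical(GenomicRanges::granges(fragments(s1)),
                   GenomicRanges::granges(fragments(coMem$samples[[1]])))
  expect_identical(fragments(s1)$motifLeft,
                   fragments(coMem$samples[[1]])$motifLeft)
})
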