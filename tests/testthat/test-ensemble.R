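## synthetic feature set with a controllable class signal, no simulator
makeFeatureSet <- function(n = 40L, signal = 1, seed = 1L,
                           blocks = c(cnv = 12L, fsd = 48L, fragma = 21L),
                           split = "train") {
  set.seed(seed)
  lab <- rep(c("cancer", "healthy"), length.out = n)
  p <- sum(blocks)
  m <- matrix(rnorm(p * n), p, n)
  # first 5 features of every block carry the signal
  off <- cumsum(c(0, blocks))[seq_along(blocks)]
  for (o in off) m[o + 1:5, lab == "cancer"] <- m[o + 1:5, lab == "cancer"] + signal
  rn <- paste0(rep(names(blocks), blocks), "_", sequence(blocks))
  dimnames(m) <- list(rn, sprintf("s%03d", seq_len(n)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = m),
    rowData = S4Vectors::DataFrame(block = rep(names(blocks), blocks),
                                   row.names = rn),
    colData = S4Vectors::DataFrame(label = lab, split = split,
                                   row.names = colnames(m)))
  new("FragFeatureSet", se)
}

test_that("base-model training yields 18 models and a complete OOF matrix", {
  fs <- makeFeatureSet(n = 30L, signal = 1.5)
  base <- trainBaseModels(fs, k = 5L, seed = 3L)
  expect_length(base$models, 18L)
  expect_identical(dim(base$oof), c(30L, 18L))
  expect_false(anyNA(base$oof))
  expect_true(all(base$oof >= 0 & base$oof <= 1))
  expect_setequal(unique(base$folds), 1:5)
  # stratified: both classes in every fold
  for (f in 1:5)
    expect_setequal(unique(base$labels[base$folds == f]), c("cancer", "healthy"))
})

test_that("training is deterministic given the seed", {
  fs <- makeFeatureSet(n = 24L, signal = 1)
  m1 <- trainEnsemble(fs, families = c("GLM", "XRT", "XGBoost"), seed = 11L)
  m2 <- trainEnsemble(fs, families = c("GLM", "XRT", "XGBoost"), seed = 11L)
  expect_identical(m1@oofStacked, m2@oofStacked)
  expect_identical(m1@cutoff, m2@cutoff)
  p1 <- predictEnsemble(m1, fs)
  p2 <- predictEnsemble(m2, fs)
  expect_identical(p1$score, p2$score)
})

test_that("stratification errors when a fold cannot contain both classes", {
  fs <- makeFeatureSet(n = 8L)
  expect_error(trainBaseModels(fs, k = 5L, seed = 1L), "stratification")
})

test_that("mean stacking is the arithmetic mean and is monotone", {
  sc <- matrix(c(0.8, 0.6, 1.0), 1)
  expect_equal(stackScores(sc, "mean")$score, 0.8)
  # consensus identity in both modes
  same <- matrix(0.7, 5, 3)
  expect_equal(stackScores(same, "mean")$score, rep(0.7, 5))
  # monotonicity: raising any base score never lowers the stack
  set.seed(4)
  base <- matrix(runif(60), 10, 6)
  s0 <- stackScores(base, "mean")$score
  for (j in 1:6) {
    up <- base
    up[, j] <- pmin(up[, j] + 0.2, 1)
    expect_true(all(stackScores(up, "mean")$score >= s0 - 1e-12))
  }
})

test_that("the logistic meta-layer separates separable OOF scores", {
  set.seed(5)
  lab <- rep(c("cancer", "healthy"), each = 20)
  oof <- matrix(runif(40 * 3), 40, 3)
  oof[lab == "cancer", 1] <- oof[lab == "cancer", 1] / 2 + 0.5
  oof[lab == "healthy", 1] <- oof[lab == "healthy", 1] / 2  # separable on col 1
  st <- suppressWarnings(stackScores(oof, "meta_glm", labels = lab))
  expect_equal(rocAuc(data.frame(label = lab, score = st$score))$auc, 1.0)
  # refit-free application at predict time
  st2 <- stackScores(oof, "meta_glm", meta = st$meta)
  expect_equal(st$score, st2$score)
})

test_that("cutoff selection follows the order-statistic enumeration", {
  # 10 healthy scores 0.1..1.0 at target 0.95: all must sit below the cutoff
  h <- seq(0.1, 1.0, by = 0.1)
  r <- fixCutoff(data.frame(label = "healthy", score = h), 0.95)
  expect_gt(r$cutoff, 1.0)
  expect_equal(r$achievedSpecificity, 1.0)
  # target 0.5 on {0.2, 0.8}: cutoff 0.8 (1 of 2 below)
  r2 <- fixCutoff(data.frame(label = "healthy", score = c(0.2, 0.8)), 0.5)
  expect_equal(r2$cutoff, 0.8)
  expect_equal(r2$achievedSpecificity, 0.5)
  # degenerate all-zero scores: smallest representable step above 0
  r3 <- fixCutoff(rep(0, 5), 0.95)
  expect_gt(r3$cutoff, 0)
  expect_lt(r3$cutoff, 1e-6)
  expect_equal(r3$achievedSpecificity, 1.0)
  expect_error(fixCutoff(h, 1.5), "targetSpecificity")
})

test_that("cutoffs anchored on large healthy arms reach the target specificity", {
  # order-statistic property across many synthetic healthy arms
  for (seed in 1:5) {
    set.seed(seed)
    h <- rbeta(112, 2, 5)
    r <- fixCutoff(h, 0.95)
    expect_gte(r$achievedSpecificity, 0.95)
    expect_gte(mean(h < r$cutoff), 0.95)
    # smallest admissible candidate: the next-lower candidate fails
    cand <- sort(unique(h))
    below <- cand[cand < r$cutoff]
    if (length(below))
      expect_lt(mean(h < max(below)), 0.95)
  }
})

test_that("validation samples leave no trace in the fitted model", {
  fs <- makeFeatureSet(n = 24L, signal = 1)
  m1 <- trainEnsemble(fs, families = c("GLM", "XRT"), seed = 2L)
  m2 <- trainEnsemble(fs, families = c("GLM", "XRT"), seed = 2L)
  # same training data, independent of anything else in the session
  f1 <- tempfile(); f2 <- tempfile()
  saveRDS(m1, f1, version = 2); saveRDS(m2, f2, version = 2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # scoring a different validation set does not alter predictions for a
  # fixed sample
  vs1 <- makeFeatureSet(n = 10L, seed = 7L, split = "validation")
  vs2 <- makeFeatureSet(n = 16L, seed = 8L, split = "validation")
  p1 <- predictEnsemble(m1, vs1)
  p12 <- predictEnsemble(m1, vs2)
  # re-score vs1 after vs2: identical
  p1b <- predictEnsemble(m1, vs1)
  expect_identical(p1$score, p1b$score)
})

test_that("block width mismatches are refused by name", {
  fs <- makeFeatureSet(n = 24L, signal = 1)
  m <- trainEnsemble(fs, families = "GLM", seed = 1L)
  bad <- makeFeatureSet(n = 6L, blocks = c(cnv = 10L, fsd = 48L, fragma = 21L))
  expect_error(predictEnsemble(m, bad), "cnv")
})
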