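## stratified k-fold assignment: within each class, shuffled round-robin
.stratifiedFolds <- function(labels, k, seed) {
  set.seed(as.integer(seed))
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    if (length(i) < k)
      .stopf("stratification error: class '%s' has %d samples for %d folds",
             cl, length(i), k)
    folds[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  folds
}

#' Train base models with out-of-fold scoring
#'
#' For every (feature block x learner family) pair: fits the learner on each
#' of k-1 folds and scores the held-out fold, assembling an out-of-fold
#' score matrix in which every training sample carries an unbiased score
#' from every base model; then refits each base model on the full training
#' set for deployment. Folds are stratified by class. With
#' \code{gridBudget > 1}, each family additionally evaluates randomly drawn
#' hyperparameter candidates by out-of-fold AUC and keeps the best.
#'
#' @param train \linkS4class{FragFeatureSet} (training samples).
#' @param blocks feature block names to use.
#' @param families learner families to use.
#' @param k folds (default 5).
#' @param seed integer seed controlling folds, grids and learner randomness.
#' @param gridBudget hyperparameter candidates per family (1 = defaults).
#' @return List: \code{models} (keyed "block.family"), \code{oof}
#'   (n x models matrix), \code{folds}, \code{labels}.
#' @export
trainBaseModels <- function(train, blocks = featureBlockNames(train),
                            families = learnerFamilies(), k = 5L, seed = 1L,
                            gridBudget = 1L) {
  labels <- as.character(SummarizedExperiment::colData(train)$label)
  folds <- .stratifiedFolds(labels, k, .childSeed(seed, "folds"))
  n <- length(labels)
  keys <- as.vector(outer(blocks, families, paste, sep = "."))
  oof <- matrix(NA_real_, n, length(keys),
                dimnames = list(colnames(train), keys))
  models <- setNames(vector("list", length(keys)), keys)
  for (b in blocks) {
    xb <- featureBlocks(train, b)
    for (fam in families) {
      key <- paste(b, fam, sep = ".")
      cands <- if (gridBudget > 1L)
        rbind(as.data.frame(.defaultParams(fam)),
              .paramGrid(fam, gridBudget - 1L, seed))
      else as.data.frame(.defaultParams(fam))
      best <- NULL
      for (ci in seq_len(nrow(cands))) {
        p <- as.list(cands[ci, , drop = FALSE])
        sc <- rep(NA_real_, n)
        for (f in seq_len(k)) {
          tr <- folds != f
          m <- fitBaseLearner(xb[tr, , drop = FALSE], labels[tr], fam,
                              params = p,
                              seed = .childSeed(seed, paste0(key, f, ci)))
          sc[!tr] <- predictBaseLearner(m, xb[!tr, , drop = FALSE])
        }
        a <- rocAuc(data.frame(label = labels, score = sc))$auc
        if (is.null(best) || a > best$auc) best <- list(p = p, sc = sc, auc = a)
      }
      oof[, key] <- best$sc
      models[[key]] <- fitBaseLearner(xb, labels, fam, params = best$p,
                                      seed = .childSeed(seed, paste0(key, "full")))
    }
  }
  list(models = models, oof = oof, folds = folds, labels = labels)
}

#' Combine base scores into the stacked cancer score
#'
#' \code{"mean"}: unweighted mean over base model scores. \code{"meta_glm"}:
#' a second-layer logistic regression fitted on the out-of-fold scores (fit
#' once during training, then applied). Outputs are clipped to [0, 1].
#'
#' @param scores samples x base-models score matrix.
#' @param combination \code{"mean"} or \code{"meta_glm"}.
#' @param meta fitted meta model (required for \code{"meta_glm"} at predict
#'   time; omit to fit one, which requires \code{labels}).
#' @param labels training labels when fitting the meta layer.
#' @return List: \code{score} (numeric), \code{meta} (the meta model or
#'   empty list).
#' @export
stackScores <- function(scores, combination = c("mean", "meta_glm"),
                        meta = NULL, labels = NULL) {
  combination <- match.arg(combination)
  scores <- as.matrix(scores)
  if (combination == "mean")
    return(list(score = pmin(pmax(rowMeans(scores), 0), 1), meta = list()))
  if (is.null(meta)) {
    if (is.null(labels)) .stopf("labels required to fit the meta layer")
    df <- data.frame(y = as.numeric(labels == "cancer"), scores,
                     check.names = TRUE)
    meta <- glm(y ~ ., data = df, family = binomial(),
                control = list(maxit = 100))
    meta <- list(coef = coef(meta))
  }
  X <- cbind(1, scores)
  cf <- meta$coef
  cf[is.na(cf)] <- 0
  eta <- as.numeric(X %*% cf)
  list(score = pmin(pmax(1 / (1 + exp(-eta)), 0), 1), meta = meta)
}

#' Fix the decision cutoff at a target training specificity
#'
#' Order-statistic rule on the healthy training scores: candidate thresholds
#' are the observed healthy scores plus one step above the maximum; the
#' cutoff is the smallest candidate t for which the fraction of healthy
#' samples with score < t reaches the target. Samples scoring >= cutoff are
#' called cancer, so the achieved specificity is that fraction.
#'
#' @param scores data.frame with columns \code{label} and \code{score} (the
#'   training cohort), or a numeric vector of healthy scores.
#' @param targetSpecificity target in (0, 1), default 0.95.
#' @return List: \code{cutoff}, \code{achievedSpecificity}.
#' @export
fixCutoff <- function(scores, targetSpecificity = 0.95) {
  .assertScalarNumber(targetSpecificity, "targetSpecificity", lower = 0,
                      upper = 1, lowerOpen = TRUE, upperOpen = TRUE)
  h <- if (is.data.frame(scores)) scores$score[scores$label == "healthy"]
       else as.numeric(scores)
  if (!length(h)) .stopf("no healthy samples to anchor the cutoff")
  step <- max(1e-9, diff(range(h)) * 1e-9)
  cand <- c(sort(unique(h)), max(h) + step)
  spec <- vapply(cand, function(t) mean(h < t), numeric(1))
  i <- which(spec >= targetSpecificity)[1L]
  if (is.na(i)) i <- length(cand)  # unreachable, but stay defined
  list(cutoff = cand[i], achievedSpecificity = spec[i])
}

#' Train the stacked ensemble
#'
#' Full training procedure: stratified k-fold out-of-fold scoring of every
#' (block x family) base model, exhaustive search over the non-empty block
#' subsets by out-of-fold stacked AUC (skippable), refit of all base models
#' on the full training cohort, and a decision cutoff anchored at the target
#' specificity on the out-of-fold stacked training scores. The feature
#' set's frozen FSD normalizer (and optionally a PoN) is bundled so new
#' samples can be featurized identically.
#'
#' @param train training-split \linkS4class{FragFeatureSet}.
#' @param families learner families (default all six).
#' @param blocks candidate feature blocks (default all present).
#' @param k folds.
#' @param combination score combination rule.
#' @param targetSpecificity cutoff anchor (default 0.95).
#' @param selectBlocks if TRUE (default) pick the block subset with the best
#'   out-of-fold stacked AUC; if FALSE use all blocks.
#' @param gridBudget hyperparameter candidates per family.
#' @param seed integer seed.
#' @param pon optional \linkS4class{PanelOfNormals} to bundle.
#' @return A \linkS4class{TrainedEnsemble}.
#' @export
trainEnsemble <- function(train, families = learnerFamilies(),
                          blocks = featureBlockNames(train), k = 5L,
                          combination = c("mean", "meta_glm"),
                          targetSpecificity = 0.95, selectBlocks = TRUE,
                          gridBudget = 1L, seed = 1L, pon = NULL) {
  combination <- match.arg(combination)
  base <- trainBaseModels(train, blocks = blocks, families = families,
                          k = k, seed = seed, gridBudget = gridBudget)
  ## larger subsets first so AUC ties resolve toward the fuller stack
  subsets <- if (selectBlocks)
    unlist(lapply(rev(seq_along(blocks)), function(m)
      utils::combn(blocks, m, simplify = FALSE)), recursive = FALSE)
  else list(blocks)
  bestSubset <- NULL
  for (sub in subsets) {
    cols <- as.vector(outer(sub, families, paste, sep = "."))
    st <- stackScores(base$oof[, cols, drop = FALSE], combination,
                      labels = base$labels)
    a <- rocAuc(data.frame(label = base$labels, score = st$score))$auc
    if (is.null(bestSubset) || a > bestSubset$auc)
      bestSubset <- list(blocks = sub, auc = a, stacked = st$score,
                         meta = st$meta)
  }
  cut <- fixCutoff(data.frame(label = base$labels, score = bestSubset$stacked),
                   targetSpecificity)
  new("TrainedEnsemble",
      baseModels = base$models,
      families = families, blocks = blocks,
      selectedBlocks = bestSubset$blocks,
      combination = combination,
      metaModel = bestSubset$meta,
      cutoff = cut$cutoff, cutoffSpecificity = cut$achievedSpecificity,
      oofScores = base$oof, oofStacked = bestSubset$stacked,
      folds = base$folds, trainLabels = base$labels,
      preprocess = list(
        fsdNormalizer = S4Vectors::metadata(train)$fsdNormalizer,
        pon = pon),
      seed = as.integer(seed))
}

#' Score samples with a trained ensemble
#'
#' Applies the deployed base models to the matching feature blocks, combines
#' them with the trained rule, and labels samples by the training-derived
#' cutoff (score >= cutoff is called cancer). No parameter is refit.
#'
#' @param model \linkS4class{TrainedEnsemble}.
#' @param features \linkS4class{FragFeatureSet} of the samples to score
#'   (must have been built with the model's frozen normalizer for honest
#'   validation).
#' @param perBlock if TRUE, also return per-block stacked scores.
#' @return Score table data.frame: sample, score, predicted, label.
#'   With \code{perBlock}, per-block score columns \code{score.<block>}.
#' @export
predictEnsemble <- function(model, features, perBlock = FALSE) {
  labels <- as.character(SummarizedExperiment::colData(features)$label)
  n <- ncol(features)
  keys <- names(model@baseModels)
  sc <- matrix(NA_real_, n, length(keys), dimnames = list(colnames(features), keys))
  for (b in model@blocks) {
    xb <- featureBlocks(features, b)
    expect <- model@baseModels[[paste(b, model@families[1L], sep = ".")]]$nFeatures
    if (ncol(xb) != expect)
      .stopf("block '%s' width mismatch: model expects %d features, got %d",
             b, expect, ncol(xb))
    for (fam in model@families) {
      key <- paste(b, fam, sep = ".")
      sc[, key] <- predictBaseLearner(model@baseModels[[key]], xb)
    }
  }
  cols <- as.vector(outer(model@selectedBlocks, model@families, paste, sep = "."))
  st <- stackScores(sc[, cols, drop = FALSE], model@combination,
                    meta = if (model@combination == "meta_glm") model@metaModel)
  out <- data.frame(sample = colnames(features), score = st$score,
                    predicted = ifelse(st$score >= model@cutoff,
                                       "cancer", "healthy"),
                    label = labels, stringsAsFactors = FALSE)
  if (perBlock) {
    for (b in model@blocks) {
      cb <- paste(b, model@families, sep = ".")
      out[[paste0("score.", b)]] <-
        stackScores(sc[, cb, drop = FALSE], "mean")$score
    }
  }
  rownames(out) <- NULL
  out
}
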