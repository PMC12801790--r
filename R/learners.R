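#' Base learner families
#' @return The six supported family names.
#' @export
learnerFamilies <- function() {
  c("GLM", "XRT", "DRF", "DeepLearning", "GBM", "XGBoost")
}

## Default hyperparameters per family: sensible mid-grid values.
## `gridBudget > 1` samples additional candidates from .paramGrid and keeps
## the best by out-of-fold AUC (the "small random grid search").
.defaultParams <- function(family) {
  switch(family,
    GLM = list(alpha = 0, nlambda = 30),
    XRT = list(num.trees = 300, min.node.size = 5, mtryFrac = NA),
    DRF = list(num.trees = 300, min.node.size = 5, mtryFrac = NA),
    DeepLearning = list(size = 8, decay = 0.1, maxit = 150),
    GBM = list(eta = 0.1, max_depth = 3, nrounds = 150, subsample = 0.8),
    XGBoost = list(eta = 0.1, max_depth = 4, nrounds = 150, subsample = 0.8,
                   colsample_bytree = 0.8, reg_lambda = 1, reg_alpha = 0),
    .stopf("unknown learner family '%s'", family))
}

.paramGrid <- function(family, n, seed) {
  set.seed(.childSeed(seed, paste0("grid", family)))
  draw <- function(x) sample(x, n, replace = TRUE)
  switch(family,
    GLM = data.frame(alpha = draw(c(0, 0.25, 0.5)), nlambda = 30),
    XRT = ,
    DRF = data.frame(num.trees = draw(c(200, 300, 500)),
                     min.node.size = draw(c(1, 5, 10)), mtryFrac = NA),
    DeepLearning = data.frame(size = draw(c(4, 8, 16)),
                              decay = draw(c(0.01, 0.1, 1)), maxit = 150),
    GBM = data.frame(eta = draw(c(0.05, 0.1, 0.2)),
                     max_depth = draw(2:4), nrounds = draw(c(100, 150, 200)),
                     subsample = draw(c(0.7, 0.8, 1))),
    XGBoost = data.frame(eta = draw(c(0.05, 0.1, 0.2)), max_depth = draw(3:5),
                         nrounds = draw(c(100, 150, 200)),
                         subsample = draw(c(0.7, 0.8, 1)),
                         colsample_bytree = draw(c(0.6, 0.8, 1)),
                         reg_lambda = draw(c(0.5, 1, 2)),
                         reg_alpha = draw(c(0, 0.1))))
}

## column-wise standardization stats on the training block; sd 0 -> 1
.scaleStats <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}
.applyScale <- function(x, st) sweep(sweep(x, 2L, st$mu), 2L, st$sd, "/")

#' Fit one base learner
#'
#' Fits a probabilistic binary classifier of the requested family on a
#' samples x features matrix. Labels are \code{"cancer"} (positive) /
#' \code{"healthy"}. All stochastic fits derive their randomness from
#' \code{seed}; single-threaded throughout so reruns are bit-identical.
#'
#' Realizations: GLM = elastic-net-regularized logistic regression (ridge by
#' default); XRT = extremely randomized trees; DRF = random forest;
#' DeepLearning = single-hidden-layer feedforward net with weight decay on
#' standardized inputs; GBM = gradient-boosted trees (exact greedy splits,
#' row subsampling); XGBoost = histogram-tree gradient boosting with column
#' sampling and explicit L1/L2 regularization.
#'
#' @param x numeric matrix, samples x features.
#' @param y character/factor labels ("cancer"/"healthy").
#' @param family one of \code{\link{learnerFamilies}()}.
#' @param params hyperparameter list (defaults per family).
#' @param seed integer seed.
#' @return Opaque fitted learner for \code{\link{predictBaseLearner}}.
#' @export
fitBaseLearner <- function(x, y, family, params = .defaultParams(family),
                           seed = 1L) {
  y <- factor(as.character(y), levels = c("healthy", "cancer"))
  if (nlevels(droplevels(y)) < 2L) .stopf("both classes required to fit")
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  p <- utils::modifyList(.defaultParams(family), as.list(params))
  set.seed(as.integer(seed))
  fit <- switch(family,
    GLM = {
      f <- glmnet::glmnet(x, y, family = "binomial", alpha = p$alpha,
                          nlambda = p$nlambda, standardize = TRUE)
      # mild fixed penalty from the interior of the path: regularized enough
      # for p >> n blocks, close to plain logistic for small blocks
      s <- f$lambda[max(1L, ceiling(length(f$lambda) * 0.7))]
      list(model = f, s = s)
    },
    XRT = ,
    DRF = {
      ranger::ranger(x = x, y = y, probability = TRUE,
                     num.trees = p$num.trees, min.node.size = p$min.node.size,
                     splitrule = if (family == "XRT") "extratrees" else "gini",
                     num.random.splits = 1L,
                     seed = as.integer(seed), num.threads = 1L)
    },
    DeepLearning = {
      st <- .scaleStats(x)
      xs <- .applyScale(x, st)
      nw <- (ncol(xs) + 1L) * p$size + (p$size + 1L)
      m <- nnet::nnet(xs, as.numeric(y == "cancer"), size = p$size,
                      decay = p$decay, maxit = p$maxit, entropy = TRUE,
                      MaxNWts = max(nw + 10L, 1000L), trace = FALSE)
      list(model = m, scale = st)
    },
    GBM = {
      d <- xgboost::xgb.DMatrix(x, label = as.numeric(y == "cancer"))
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       tree_method = "exact", eta = p$eta,
                                       max_depth = p$max_depth,
                                       subsample = p$subsample,
                                       colsample_bytree = 1,
                                       nthread = 1, seed = as.integer(seed)),
                         data = d, nrounds = p$nrounds, verbose = 0)
    },
    XGBoost = {
      d <- xgboost::xgb.DMatrix(x, label = as.numeric(y == "cancer"))
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       tree_method = "hist", eta = p$eta,
                                       max_depth = p$max_depth,
                                       subsample = p$subsample,
                                       colsample_bytree = p$colsample_bytree,
                                       lambda = p$reg_lambda, alpha = p$reg_alpha,
                                       nthread = 1, seed = as.integer(seed)),
                         data = d, nrounds = p$nrounds, verbose = 0)
    },
    .stopf("unknown learner family '%s'", family))
  structure(list(family = family, fit = fit, params = p,
                 nFeatures = ncol(x)), class = "fragstackLearner")
}

#' Predict cancer probabilities from a fitted base learner
#' @param object fitted learner from \code{\link{fitBaseLearner}}.
#' @param x samples x features matrix (same layout as at fit time).
#' @return Numeric scores in [0, 1], higher = more cancer-like.
#' @export
predictBaseLearner <- function(object, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != object$nFeatures)
    .stopf("feature width mismatch: model expects %d, got %d",
           object$nFeatures, ncol(x))
  s <- switch(object$family,
    GLM = as.numeric(predict(object$fit$model, x, s = object$fit$s,
                             type = "response")),
    XRT = ,
    DRF = {
      pr <- predict(object$fit, data = x, num.threads = 1L)$predictions
      as.numeric(pr[, "cancer"])
    },
    DeepLearning = as.numeric(predict(object$fit$model,
                                      .applyScale(x, object$fit$scale))),
    GBM = ,
    XGBoost = as.numeric(predict(object$fit, xgboost::xgb.DMatrix(x))))
  pmin(pmax(s, 0), 1)
}
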