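#' Extract features for a whole cohort
#'
#' Runs the three extractors over every sample, building the Panel of
#' Normals from the training-split healthy samples when none is supplied,
#' and assembles the \linkS4class{FragFeatureSet} (FSD normalizer fitted on
#' the training split unless a frozen one is given).
#'
#' @param samples named list of \linkS4class{SampleFragments} or BED paths.
#' @param sheet cohort sheet (sample/label/split + extras).
#' @param assets \linkS4class{GenomeAssets}.
#' @param pon optional frozen \linkS4class{PanelOfNormals}.
#' @param normalizer optional frozen \linkS4class{FsdNormalizer}.
#' @param scheme size-bin scheme.
#' @param endMode FRAGMA end mode.
#' @return List: \code{features} (\linkS4class{FragFeatureSet}), \code{pon}.
#' @export
extractCohortFeatures <- function(samples, sheet, assets, pon = NULL,
                                  normalizer = NULL, scheme = sizeBinScheme(),
                                  endMode = "both") {
  samples <- lapply(samples, function(s) {
    if (is.character(s)) readFragmentsBed(s, assets@reference, assets@seqinfo)
    else s
  })
  names(samples) <- vapply(samples, sampleId, character(1))
  if (is.null(pon)) {
    ph <- sheet$sample[sheet$label == "healthy" & sheet$split == "train"]
    if (length(ph) < 3L)
      .stopf("PoN construction needs >= 3 training healthy samples")
    counts <- lapply(samples[ph], countFragmentsPerBin, bins = assets@bins)
    pon <- suppressMessages(buildPanelOfNormals(counts, assets@bins))
  }
  extracts <- lapply(samples, extractSampleFeatures, assets = assets,
                     pon = pon, scheme = scheme, endMode = endMode)
  feats <- buildFeatureMatrix(extracts, sheet, assets, normalizer = normalizer)
  list(features = feats, pon = pon)
}

#' Simulate, train and validate end to end
#'
#' The whole desk-scale study in one call: build a toy genome, simulate a
#' training and a validation cohort, extract features (PoN and FSD
#' normalizer frozen on the training split), train the stacked ensemble,
#' score the untouched validation cohort, and evaluate. Everything derives
#' from \code{seed}.
#'
#' @param seed integer master seed.
#' @param cfg \code{\link{simulationConfig}}.
#' @param nTrain c(cancer, healthy) training sizes.
#' @param nVal c(cancer, healthy) validation sizes.
#' @param tfRange tumor-fraction range (c(0, 0) gives a null study).
#' @param families learner families.
#' @param combination stacking rule.
#' @param gridBudget hyperparameter candidates per family.
#' @param assets reuse an existing \linkS4class{GenomeAssets} (skips the
#'   genome build).
#' @return List: \code{model}, \code{valScores} (with per-block columns),
#'   \code{valAuc}, \code{blockAuc} (named per-block validation AUCs),
#'   \code{metrics} (confusion metrics at the trained cutoff),
#'   \code{trainSheet}, \code{valSheet}, \code{assets}.
#' @export
runEndToEnd <- function(seed = 1L, cfg = simulationConfig(),
                        nTrain = c(60L, 60L), nVal = c(30L, 30L),
                        tfRange = c(0.05, 0.3),
                        families = learnerFamilies(),
                        combination = "mean", gridBudget = 1L,
                        assets = NULL) {
  if (is.null(assets)) assets <- buildToyGenome(cfg, seed = .childSeed(seed, "g"))
  tr <- simulateCohort(assets, nTrain[1], nTrain[2], tfRange, "train",
                       seed = .childSeed(seed, "train"))
  va <- simulateCohort(assets, nVal[1], nVal[2], tfRange, "validation",
                       seed = .childSeed(seed, "val"))
  ext <- extractCohortFeatures(tr$samples, tr$sheet, assets)
  model <- trainEnsemble(ext$features, families = families,
                         combination = combination, gridBudget = gridBudget,
                         seed = .childSeed(seed, "fit"), pon = ext$pon)
  extV <- extractCohortFeatures(va$samples, va$sheet, assets, pon = ext$pon,
                                normalizer = model@preprocess$fsdNormalizer)
  valScores <- predictEnsemble(model, extV$features, perBlock = TRUE)
  valAuc <- rocAuc(valScores)$auc
  blockAuc <- vapply(model@blocks, function(b)
    rocAuc(data.frame(label = valScores$label,
                      score = valScores[[paste0("score.", b)]]))$auc,
    numeric(1))
  list(model = model, valScores = valScores, valAuc = valAuc,
       blockAuc = blockAuc,
       metrics = confusionMetrics(valScores, cutoff = model@cutoff),
       trainSheet = tr$sheet, valSheet = va$sheet, assets = assets)
}

.hashFile <- function(p) if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_

#' Run the pipeline from a YAML configuration
#'
#' Declarative front end over the simulate -> extract -> pon -> train ->
#' predict -> evaluate chain. The config carries the simulation settings,
#' cohort sizes, learner settings and seed; unknown keys are a validation
#' error. Every run writes a run manifest (package version, config hash,
#' seeds, stage output hashes) next to its outputs; when an up-to-date
#' manifest with identical config hash and seed exists, cached stage
#' outputs are reused instead of recomputed.
#'
#' @param configPath YAML file.
#' @param outDir output directory.
#' @param seed overrides the config's seed when non-NULL.
#' @return Invisibly, the run manifest list; outputs (score table TSV,
#'   metrics TSV, manifest JSON) are written under \code{outDir}.
#' @export
runPipeline <- function(configPath, outDir, seed = NULL) {
  known <- c("seed", "simulation", "cohort", "model", "evaluate")
  cfgY <- yaml::read_yaml(configPath)
  bad <- setdiff(names(cfgY), known)
  if (length(bad))
    .stopf("config validation error: unknown key(s): %s",
           paste(bad, collapse = ", "))
  seed <- as.integer(seed %||% cfgY$seed %||% 1L)
  simArgs <- cfgY$simulation %||% list()
  badSim <- setdiff(names(simArgs), names(formals(simulationConfig)))
  if (length(badSim))
    .stopf("config validation error: unknown simulation key(s): %s",
           paste(badSim, collapse = ", "))
  cfg <- do.call(simulationConfig, simArgs)
  co <- cfgY$cohort %||% list()
  mo <- cfgY$model %||% list()
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  cfgHash <- unname(tools::md5sum(configPath))
  manifestPath <- file.path(outDir, "run_manifest.json")
  scorePath <- file.path(outDir, "validation_scores.tsv")
  metricPath <- file.path(outDir, "metrics.tsv")
  if (file.exists(manifestPath)) {
    prev <- jsonlite::read_json(manifestPath)
    if (identical(prev$configHash, cfgHash) &&
        identical(as.integer(prev$seed), seed) &&
        file.exists(scorePath) && file.exists(metricPath) &&
        identical(prev$outputs$validation_scores, .hashFile(scorePath))) {
      message("cache hit: outputs up to date, nothing recomputed")
      return(invisible(prev))
    }
  }
  res <- runEndToEnd(seed = seed, cfg = cfg,
                     nTrain = c(co$train_cancer %||% 60L, co$train_healthy %||% 60L),
                     nVal = c(co$val_cancer %||% 30L, co$val_healthy %||% 30L),
                     tfRange = c(co$tf_min %||% 0.05, co$tf_max %||% 0.3),
                     families = mo$families %||% learnerFamilies(),
                     combination = mo$combination %||% "mean",
                     gridBudget = mo$grid_budget %||% 1L)
  write.table(res$valScores, scorePath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  mt <- cbind(metric = rownames(res$metrics$metrics), res$metrics$metrics)
  write.table(mt, metricPath, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    tool = "fragstack",
    version = as.character(utils::packageVersion("fragstack")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    configHash = cfgHash, seed = seed,
    valAuc = res$valAuc, cutoff = res$model@cutoff,
    outputs = list(validation_scores = .hashFile(scorePath),
                   metrics = .hashFile(metricPath)))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
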