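# End-to-end pipeline: images (or a feature CSV) -> segmentation ->
# features -> correlation filter -> component model -> thresholds ->
# pairwise classification, with every stage's artifact written to disk.

#' Pipeline configuration
#'
#' Bundles the stage parameters: segmentation settings, the correlation
#' filter threshold and priority, PCA flags, the threshold pairing plan,
#' the holdout fraction and the seed. Round-trips losslessly through JSON.
#'
#' @param segmentation a [segmentationConfig()].
#' @param selectionThreshold absolute-correlation cutoff of the filter.
#' @param priority feature priority order of the filter.
#' @param kaiserTolerance,rowNormalize PCA flags (see [fitSeedlingPCA()]).
#' @param plan `"auto"` or an explicit pairing plan (see
#'   [deriveThresholds()]).
#' @param splitFraction holdout test fraction.
#' @param confidence CI level for thresholds.
#' @param seed integer seed for the holdout split.
#' @return named list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(segmentation = segmentationConfig(),
                           selectionThreshold = 0.7,
                           priority = defaultPriority(),
                           kaiserTolerance = 0.05, rowNormalize = TRUE,
                           plan = "auto", splitFraction = 0.2,
                           confidence = 0.95, seed = 1L) {
  structure(list(segmentation = segmentation,
                 selectionThreshold = selectionThreshold,
                 priority = priority, kaiserTolerance = kaiserTolerance,
                 rowNormalize = rowNormalize, plan = plan,
                 splitFraction = splitFraction, confidence = confidence,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' @rdname pipelineConfig
#' @param path file path.
#' @param config a `pipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  obj <- unclass(config)
  obj$segmentation <- unclass(obj$segmentation)
  .writeAtomic(path, function(p)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA))
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- do.call(segmentationConfig, o$segmentation)
  pipelineConfig(segmentation = seg,
                 selectionThreshold = o$selectionThreshold,
                 priority = o$priority, kaiserTolerance = o$kaiserTolerance,
                 rowNormalize = o$rowNormalize,
                 plan = if (is.character(o$plan)) o$plan else as.data.frame(o$plan),
                 splitFraction = o$splitFraction, confidence = o$confidence,
                 seed = o$seed)
}

.log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[grassID] ", fmt), ...))
}

#' Run the full discrimination pipeline
#'
#' Input is either a directory of single-plant images with a
#' `manifest.csv` (columns `file`, `species`) or a feature table CSV (the
#' image stages are then skipped). The pipeline segments each image,
#' extracts the eleven features, filters them by correlation, splits into
#' training and holdout sets, fits the Varimax-rotated component model on
#' the training set, derives CI-midpoint thresholds, and classifies the
#' holdout. All artifacts (feature table, correlation matrix, selection
#' report, model JSON, scores, ANOVA/post-hoc/descriptives, thresholds,
#' per-plant predictions) are written atomically under `outDir`.
#'
#' @param input directory with images + manifest.csv, or a feature CSV
#'   path, or a feature table data.frame.
#' @param outDir output directory.
#' @param config a [pipelineConfig()].
#' @param verbose log stage progress and counts.
#' @return invisibly, a list with the feature table, model, thresholds,
#'   training/holdout reports and artifact paths.
#' @export
runPipeline <- function(input, outDir, config = pipelineConfig(),
                        verbose = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  ## stage 1-2: images -> features (skipped for CSV/data.frame input)
  if (is.data.frame(input)) {
    tab <- input
    .log(verbose, "using supplied feature table (%d plants)", nrow(tab))
  } else if (dir.exists(input)) {
    man <- utils::read.csv(file.path(input, "manifest.csv"),
                           stringsAsFactors = FALSE)
    .log(verbose, "segmenting %d images", nrow(man))
    regions <- lapply(file.path(input, man$file), function(f)
      segmentPlant(readRgbImage(f), config$segmentation))
    tab <- extractFeatureTable(regions, species = man$species,
                               ids = if ("id" %in% names(man)) man$id else NULL)
    .log(verbose, "extracted %d features for %d plants",
         length(featureNames()), nrow(tab))
  } else if (file.exists(input)) {
    tab <- readFeatureTable(input)
    .log(verbose, "read feature table (%d plants)", nrow(tab))
  } else {
    .gerr("badInput", paste("input not found:", input))
  }
  writeFeatureTable(tab, file.path(outDir, "features.csv"))

  ## stage 3: correlation filter
  corr <- correlationMatrix(tab)
  sel <- selectFeatures(corr, threshold = config$selectionThreshold,
                        priority = config$priority)
  writeCorrelationMatrix(corr, file.path(outDir, "correlation.csv"))
  writeSelection(sel, file.path(outDir, "selection.json"))
  .log(verbose, "correlation filter kept %d/%d features: %s",
       length(sel$kept), ncol(corr), paste(sel$kept, collapse = ", "))

  ## stage 4: holdout split + model fit
  split <- holdoutSplit(tab, fraction = config$splitFraction,
                        seed = config$seed)
  .log(verbose, "split: %d training / %d holdout plants",
       nrow(split$train), nrow(split$test))
  model <- fitSeedlingPCA(split$train, features = sel$kept,
                          kaiserTolerance = config$kaiserTolerance,
                          rowNormalize = config$rowNormalize)
  writeModel(model, file.path(outDir, "model.json"))
  .log(verbose, "model: %d retained components, %.1f%% variance explained",
       nComponents(model),
       sum(explainedVariance(model)[seq_len(nComponents(model))]))

  ## stage 5: scores, ANOVA, post-hoc, descriptives, thresholds
  trainScores <- scoreSamples(model, split$train)
  testScores <- scoreSamples(model, split$test)
  scoresOut <- cbind(split$train[, c("plant_id", "species")],
                     as.data.frame(trainScores))
  .writeAtomic(file.path(outDir, "scores_train.csv"), function(p)
    utils::write.csv(scoresOut, p, row.names = FALSE))
  stats <- lapply(seq_len(ncol(trainScores)), function(j) list(
    component = colnames(trainScores)[j],
    anova = oneWayAnova(trainScores[, j], split$train$species),
    posthoc = bonferroniPairwise(trainScores[, j], split$train$species),
    descriptives = groupDescriptives(trainScores[, j], split$train$species,
                                     config$confidence)))
  .writeAtomic(file.path(outDir, "score_statistics.json"), function(p)
    jsonlite::write_json(stats, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows"))
  thr <- deriveThresholds(trainScores, split$train$species,
                          plan = config$plan, confidence = config$confidence)
  .writeAtomic(file.path(outDir, "thresholds.json"), function(p)
    jsonlite::write_json(list(confidence = thr@confidence,
                              thresholds = thr@thresholds),
                         p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows"))

  ## stage 6: holdout classification
  report <- classifyPairwise(testScores, split$test$species, thr)
  .writeAtomic(file.path(outDir, "classification.csv"), function(p)
    utils::write.csv(report$predictions, p, row.names = FALSE))
  .writeAtomic(file.path(outDir, "classification_summary.json"), function(p)
    jsonlite::write_json(report$summary, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows"))
  for (i in seq_len(nrow(report$summary)))
    .log(verbose, "holdout %s vs %s on %s: %.1f%% (%d/%d)",
         report$summary$speciesHigh[i], report$summary$speciesLow[i],
         report$summary$component[i], report$summary$accuracyPct[i],
         report$summary$nCorrect[i], report$summary$nTotal[i])
  .log(verbose, "done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))

  invisible(list(features = tab, correlation = corr, selection = sel,
                 split = split, model = model, thresholds = thr,
                 trainScores = trainScores, testScores = testScores,
                 statistics = stats, report = report, outDir = outDir))
}
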