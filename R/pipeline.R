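#' @include AllClasses.R AllGenerics.R io.R features.R classification.R importance.R
NULL

#' Run the full classification framework end to end
#'
#' Chains simulate -> segment -> (register) -> subregion -> extract ->
#' classify -> importance -> report on a synthetic cohort, writing every
#' intermediate product plus a machine-readable provenance log into the
#' run directory. Deterministic given `config$seed`: every stage and
#' subject draws from a named sub-stream derived with [deriveSeed()].
#'
#' @param config a `PipelineConfig` from [pipelineConfig()] /
#'   [readConfig()].
#' @param outDir run directory (created).
#' @return invisibly, a list with the manifest, feature table, multiclass
#'   result, metrics, importance table and the provenance log.
#' @export
runPipeline <- function(config, outDir) {
  validatePipelineConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  prov <- list(package = as.character(utils::packageVersion("cftpet")),
               seed = seed, config = unclass(config), stages = list())
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  # simulate
  spec <- phantomSpec(gridShape = config$phantom$gridShape,
                      voxelSize = config$phantom$voxelSize,
                      noiseSd = config$phantom$noiseSd,
                      seed = deriveSeed(seed, "phantom-spec"))
  manifest <- generateCohort(spec, nPerGroup = config$cohort$nPerGroup,
                             esFractions = config$cohort$esFractions,
                             outDir = file.path(outDir, "data"),
                             seed = deriveSeed(seed, "cohort"))
  prov$stages$simulate <- list(n = nrow(manifest), seconds = tic() - t0)

  # segment backend
  t0 <- tic()
  segmenter <- switch(config$segmentation$backend,
    truth = NULL,
    atlas = {
      ref <- manifest[1, ]
      atlasSegmenter(readVolume(ref$mri_path), readLabelMap(ref$labels_path))
    },
    learned = {
      take <- manifest[seq_len(min(4L, nrow(manifest))), ]
      pairs <- lapply(seq_len(nrow(take)), function(i)
        list(mri = readVolume(take$mri_path[i]),
             labels = readLabelMap(take$labels_path[i])))
      trainSegmenter(pairs, segmenterConfig(seed = deriveSeed(seed, "segmenter")))
    })

  # features (segmentation + optional registration + subregions inside)
  features <- cohortFeatureTable(
    manifest, segmenter = segmenter,
    register = isTRUE(config$registration$enabled),
    featureSet = config$features$featureSet,
    includeAsymmetry = isTRUE(config$features$includeAsymmetry),
    formula = config$features$sorFormula,
    subregionSeed = deriveSeed(seed, "subregions"))
  if (length(attr(features, "failures")))
    stop(sprintf("feature extraction failed for: %s",
                 paste(attr(features, "failures"), collapse = "; ")),
         call. = FALSE)
  writeFeatureTable(features, file.path(outDir, "features.csv"))
  summary_ <- groupFeatureSummary(features)
  utils::write.csv(summary_, file.path(outDir, "group_summary.csv"),
                   row.names = FALSE)
  prov$stages$features <- list(n = nrow(features), seconds = tic() - t0)

  # classify (patients only, as in the diagnostic task)
  t0 <- tic()
  patients <- features[features$group != "NC", , drop = FALSE]
  ccfg <- classifierConfig(costGrid = config$classifier$costGrid,
                           innerFolds = config$classifier$innerFolds,
                           seed = deriveSeed(seed, "classifier"))
  multi <- loocv(patients, patients$group, ccfg, ids = patients$subject_id)
  cm <- resultConfusion(multi)
  metrics <- metricsFromMatrix(cm)
  binary <- binaryTasks(featureMatrix(patients), patients$group, ccfg,
                        ids = patients$subject_id)
  strat <- lapply(config$strategies, function(s)
    runStrategy(patients, s, ccfg, seed = deriveSeed(seed, "strategy", s)))
  names(strat) <- as.character(config$strategies)
  resultsCsv <- data.frame(subject_id = multi$ids, true = multi$true,
                           predicted = multi$predicted)
  utils::write.csv(resultsCsv, file.path(outDir, "multiclass_predictions.csv"),
                   row.names = FALSE)
  report <- list(
    multiclass = list(accuracy = metrics$accuracy,
                      confusion = counts(cm), perClass = metrics$perClass),
    binary = lapply(binary, function(b) list(accuracy = b$accuracy,
                                             auc = b$auc)),
    strategies = lapply(strat, function(r)
      list(accuracy = mean(r$predicted == r$true), n = length(r$ids))))
  prov$stages$classify <- list(n = nrow(patients), seconds = tic() - t0)

  # importance
  t0 <- tic()
  icfg <- importanceConfig(nTrees = config$importance$nTrees,
                           nRep = config$importance$nRep,
                           seed = deriveSeed(seed, "importance"))
  X14 <- featureMatrix(patients)[, featureColumns("striatum"), drop = FALSE]
  imp <- featureContributions(X14, patients$group, icfg)
  utils::write.csv(data.frame(feature = names(imp$perFeature),
                              contribution = imp$perFeature),
                   file.path(outDir, "importance.csv"), row.names = FALSE)
  truth <- phantomTruth(spec)
  writeVolume(contributionMap(truth$submap, imp),
              file.path(outDir, "contribution_map.nii.gz"))
  prov$stages$importance <- list(seconds = tic() - t0)

  report$importance <- list(bilateralPercent = imp$bilateralPercent,
                            nucleusPercent = imp$nucleusPercent)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, features = features, multiclass = multi,
                 metrics = metrics, importance = imp, report = report,
                 provenance = prov))
}
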