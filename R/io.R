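#' @include AllClasses.R AllGenerics.R
NULL

# ---- NIfTI volumes -------------------------------------------------------

# build the RAS affine of a volume; NIfTI origin is the center of voxel
# (0,0,0), i.e. our corner origin + spacing/2
#' @keywords internal
volumeAffine <- function(vol) {
  m <- diag(4)
  m[1, 1] <- vol@spacing[1]; m[2, 2] <- vol@spacing[2]
  m[3, 3] <- vol@spacing[3]
  m[1:3, 4] <- vol@origin + vol@spacing / 2
  m
}

#' Write a volume as NIfTI-1
#'
#' @param vol a [VolumeImage-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@data)
  # pixdim and the xform must agree: the writer normalizes the rotation
  # columns to pixdim scale
  img <- RNifti::`pixdim<-`(img, vol@spacing)
  aff <- structure(volumeAffine(vol), code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Requires an axis-aligned RAS affine (diagonal, positive); anything else
#' errors rather than silently reorienting.
#'
#' @param path NIfTI file path.
#' @return a [VolumeImage-class].
#' @export
readVolume <- function(path) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-6) || any(diag(rot) <= 0))
    stop(sprintf("%s: affine is not axis-aligned RAS; refusing to reorient",
                 path), call. = FALSE)
  spacing <- diag(rot)
  origin <- aff[1:3, 4] - spacing / 2
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))  # strip niftiImage attributes
  volumeImage(a, spacing, origin)
}

#' Write a label map (NIfTI + JSON code-table sidecar)
#'
#' @param labels a [LabelMap-class].
#' @param path output NIfTI path; the sidecar replaces the extension with
#'   `.json`.
#' @return the path, invisibly.
#' @export
writeLabelMap <- function(labels, path) {
  writeVolume(labels, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(codeTable(labels), side, digits = NA)
  invisible(path)
}

#' Read a label map written by [writeLabelMap()]
#'
#' @param path NIfTI path; the JSON sidecar is read when present, else the
#'   canonical code table matching the codes found is used.
#' @return a [LabelMap-class].
#' @export
readLabelMap <- function(path) {
  vol <- readVolume(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  codes <- setdiff(unique(as.vector(vol@data)), 0)
  ct <- if (file.exists(side)) {
    as.data.frame(jsonlite::read_json(side, simplifyVector = TRUE))
  } else if (all(codes %in% regionCodeTable()$code)) {
    regionCodeTable()
  } else {
    subregionCodeTable()
  }
  grid <- vol@data
  storage.mode(grid) <- "integer"
  if ("subregion" %in% names(ct))
    new("SubregionMap", data = grid, spacing = vol@spacing,
        origin = vol@origin, codeTable = ct)
  else
    labelMap(grid, vol@spacing, vol@origin, codeTable = ct)
}

#' Check that paired volumes share a grid
#'
#' @param a,b two [VolumeImage-class] objects.
#' @param nameA,nameB names used in the error message.
#' @param tol tolerance in mm on spacing and origin.
#' @return invisibly TRUE; errors naming both inputs on mismatch.
#' @export
checkPairedGrids <- function(a, b, nameA = "first", nameB = "second",
                             tol = 1e-3) {
  ok <- identical(dim(a), dim(b)) &&
    all(abs(voxelSpacing(a) - voxelSpacing(b)) <= tol) &&
    all(abs(volOrigin(a) - volOrigin(b)) <= tol)
  if (!ok)
    stop(sprintf("grid mismatch between %s and %s (dims/spacing/origin differ beyond %g mm)",
                 nameA, nameB, tol), call. = FALSE)
  invisible(TRUE)
}

# ---- transforms ----------------------------------------------------------

#' Write a rigid transform as JSON
#'
#' @param transform a [RigidTransform-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTransform <- function(transform, path) {
  jsonlite::write_json(
    list(angles_rad = transform@angles, translation_mm = transform@translation,
         center_mm = transform@center,
         convention = "fixed<-moving; world mm RAS; R = Rz(az) Ry(ay) Rx(ax) about center"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rigid transform written by [writeTransform()]
#'
#' @param path JSON path.
#' @return a [RigidTransform-class].
#' @export
readTransform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigidTransform(angles = j$angles_rad, translation = j$translation_mm,
                 center = j$center_mm)
}

# ---- feature tables ------------------------------------------------------

#' Write a feature table as CSV
#'
#' @param features feature data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table CSV
#'
#' Recognized columns are the metadata fields (`subject_id`, `group`,
#' `stage`, `seed`, `occipital_mean`) and the `sor_` / `ai_` features;
#' unknown columns are dropped with a warning.
#'
#' @param path CSV path.
#' @return feature data.frame.
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  known <- names(df) %in% c("subject_id", "group", "stage", "seed",
                            "occipital_mean") |
    grepl("^(sor|ai)_", names(df))
  if (any(!known)) {
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(names(df)[!known], collapse = ", ")), call. = FALSE)
    df <- df[, known, drop = FALSE]
  }
  df
}

# ---- configuration -------------------------------------------------------

#' Default end-to-end pipeline configuration
#'
#' One document holding every stage's settings; validated by
#' [validatePipelineConfig()] before any stage runs.
#'
#' @param nPerGroup,esFractions cohort composition.
#' @param gridShape,voxelSize,noiseSd phantom geometry and noise.
#' @param segmentationBackend "truth" (use supplied label volumes),
#'   "atlas" or "learned".
#' @param register rigidly register MRI to PET before subregioning.
#' @param featureSet,includeAsymmetry,sorFormula feature settings.
#' @param costGrid,innerFolds classifier settings.
#' @param nTrees,nRep importance settings.
#' @param strategies which training strategies to run (integer ids,
#'   possibly empty).
#' @param seed global seed; all stage/subject seeds derive from it.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(nPerGroup = c(PD = 8L, MSA = 8L, PSP = 8L, NC = 8L),
                           esFractions = defaultESFractions(),
                           gridShape = c(64L, 64L, 64L), voxelSize = 2,
                           noiseSd = 0.05,
                           segmentationBackend = "truth", register = FALSE,
                           featureSet = "striatum+midbrain",
                           includeAsymmetry = TRUE, sorFormula = "sbr",
                           costGrid = 10^seq(-3, 3), innerFolds = 5L,
                           nTrees = 500L, nRep = 10L,
                           strategies = integer(), seed = 1L) {
  cfg <- list(
    cohort = list(nPerGroup = nPerGroup, esFractions = esFractions),
    phantom = list(gridShape = gridShape, voxelSize = voxelSize,
                   noiseSd = noiseSd),
    segmentation = list(backend = segmentationBackend),
    registration = list(enabled = register),
    features = list(featureSet = featureSet,
                    includeAsymmetry = includeAsymmetry,
                    sorFormula = sorFormula),
    classifier = list(costGrid = costGrid, innerFolds = innerFolds),
    importance = list(nTrees = nTrees, nRep = nRep),
    strategies = strategies,
    seed = seed)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema check: every stage block and required field must be present and
#' well-typed; the first missing field is named in the error.
#'
#' @param config a `PipelineConfig` (or plain list, e.g. from YAML).
#' @return invisibly TRUE.
#' @export
validatePipelineConfig <- function(config) {
  need <- list(
    "cohort" = c("nPerGroup", "esFractions"),
    "phantom" = c("gridShape", "voxelSize", "noiseSd"),
    "segmentation" = "backend",
    "registration" = "enabled",
    "features" = c("featureSet", "includeAsymmetry", "sorFormula"),
    "classifier" = c("costGrid", "innerFolds"),
    "importance" = c("nTrees", "nRep"))
  for (blk in names(need)) {
    stopIfNot(!is.null(config[[blk]]),
              sprintf("config is missing required block '%s'", blk))
    for (f in need[[blk]])
      stopIfNot(!is.null(config[[blk]][[f]]),
                sprintf("config is missing required field '%s.%s'", blk, f))
  }
  stopIfNot(!is.null(config$seed), "config is missing required field 'seed'")
  stopIfNot(config$segmentation$backend %in% c("truth", "atlas", "learned"),
            "segmentation.backend must be truth, atlas or learned")
  stopIfNot(config$features$featureSet %in%
              c("striatum", "midbrain", "striatum+midbrain"),
            "features.featureSet invalid")
  invisible(TRUE)
}

#' Read/write a pipeline configuration as YAML
#'
#' @param config a `PipelineConfig`.
#' @param path YAML path.
#' @return `writeConfig`: the path, invisibly. `readConfig`: a validated
#'   `PipelineConfig`.
#' @name configIO
#' @export
writeConfig <- function(config, path) {
  cfg <- unclass(config)
  # named atomic vectors lose their names as YAML sequences; store as maps
  cfg$cohort$nPerGroup <- as.list(cfg$cohort$nPerGroup)
  cfg$cohort$esFractions <- as.list(cfg$cohort$esFractions)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname configIO
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$cohort$nPerGroup)) cfg$cohort$nPerGroup <-
    unlist(cfg$cohort$nPerGroup)
  if (!is.null(cfg$cohort$esFractions)) cfg$cohort$esFractions <-
    unlist(cfg$cohort$esFractions)
  class(cfg) <- "PipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}
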