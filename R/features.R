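#' @include AllClasses.R AllGenerics.R phantom.R
NULL

#' Striatal-to-occipital ratio of one subregion
#'
#' The specific-binding-ratio convention standard for dopamine-transporter
#' PET: `SOR = (mean uptake in subregion - mean occipital uptake) / mean
#' occipital uptake`, with the occipital reference pooling left and right
#' occipital voxels. The plain-ratio alternative
#' (`mean subregion / mean occipital`) is available via `formula`.
#'
#' @param pet a [VolumeImage-class] on the subregion grid.
#' @param submap a [SubregionMap-class] (or [LabelMap-class]) containing
#'   the subregion and both occipital regions.
#' @param subregionCode integer code of the subregion.
#' @param formula "sbr" (default) or "plain_ratio".
#' @return the SOR value.
#' @export
computeSOR <- function(pet, submap, subregionCode,
                       formula = c("sbr", "plain_ratio")) {
  formula <- match.arg(formula)
  grid <- volData(submap)
  petArr <- volData(pet)
  ct <- codeTable(submap)
  occ <- ct$code[ct$region == "occipital"]
  occVox <- grid %in% occ
  subVox <- grid == subregionCode
  stopIfNot(any(subVox), sprintf("subregion code %d is empty", subregionCode))
  stopIfNot(any(occVox), "occipital reference regions are empty")
  occMean <- mean(petArr[occVox])
  if (occMean <= 0)
    stop("invalid occipital reference: mean uptake <= 0", call. = FALSE)
  subMean <- mean(petArr[subVox])
  if (formula == "sbr") (subMean - occMean) / occMean else subMean / occMean
}

#' Bilateral asymmetry index
#'
#' `AI = (higher-side SOR - lower-side SOR) / mean(both sides)`; zero for
#' equal sides, 2 at the boundary where the lower side reaches zero. When
#' the two-side mean is not positive the index is undefined and returned as
#' `NA` (flagged via the `undefined` attribute) rather than raising.
#'
#' @param sorLeft,sorRight finite per-side SOR values.
#' @return the asymmetry index (NA when undefined).
#' @export
computeAsymmetry <- function(sorLeft, sorRight) {
  stopIfNot(is.finite(sorLeft) && is.finite(sorRight),
            "side SORs must be finite")
  m <- (sorLeft + sorRight) / 2
  if (m <= 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  (max(sorLeft, sorRight) - min(sorLeft, sorRight)) / m
}

#' Canonical feature column names
#'
#' SOR columns come in fixed order: for each subregion key (caudate
#' anterior/middle/posterior, putamen anterior/middle/posterior, pallidum,
#' then midbrain when included), right side before left. Asymmetry columns
#' follow for the six split subregions.
#'
#' @param featureSet "striatum" (14), "midbrain" (2) or
#'   "striatum+midbrain" (16).
#' @param includeAsymmetry append the six `ai_` columns.
#' @return character vector of column names.
#' @export
featureColumns <- function(featureSet = "striatum", includeAsymmetry = FALSE) {
  keys <- featureSetKeys(featureSet)
  cols <- as.vector(t(outer(keys, c("R", "L"),
                            function(k, s) paste0("sor_", k, "_", s))))
  if (includeAsymmetry)
    cols <- c(cols, paste0("ai_", splitSubregionKeys()))
  cols
}

#' Extract one subject's feature vector
#'
#' Computes the SOR of every subregion in the requested feature set plus
#' the six bilateral asymmetry indexes and the pooled occipital reference
#' mean.
#'
#' @param pet a [VolumeImage-class] (native PET grid).
#' @param submap a [SubregionMap-class] on the same grid.
#' @param metadata list or one-row data.frame with `subject_id`, `group`,
#'   `stage` (missing entries become NA).
#' @param featureSet "striatum+midbrain" (16 SOR columns, default),
#'   "striatum" (14) or "midbrain" (2).
#' @param includeAsymmetry include the `ai_` columns (default TRUE).
#' @param formula SOR convention, see [computeSOR()].
#' @return one-row data.frame in canonical column order, with
#'   `occipital_mean` appended.
#' @export
extractSubject <- function(pet, submap, metadata = list(),
                           featureSet = "striatum+midbrain",
                           includeAsymmetry = TRUE,
                           formula = c("sbr", "plain_ratio")) {
  formula <- match.arg(formula)
  ct <- codeTable(submap)
  keys <- featureSetKeys(featureSet)
  grid <- volData(submap)
  codeFor <- function(key, side) {
    if (key %in% c("pallidum", "midbrain")) {
      ct$code[ct$region == key & ct$side == side]
    } else {
      parts <- strsplit(key, "_")[[1]]
      ct$code[ct$region == parts[1] & ct$subregion == parts[2] & ct$side == side]
    }
  }
  vals <- list()
  for (k in keys) for (s in c("R", "L")) {
    code <- codeFor(k, s)
    stopIfNot(length(code) == 1L && any(grid == code),
              sprintf("subregion %s (%s) missing from map", k, s))
    vals[[paste0("sor_", k, "_", s)]] <- computeSOR(pet, submap, code, formula)
  }
  meta <- function(f) if (!is.null(metadata[[f]])) metadata[[f]] else NA
  row <- data.frame(subject_id = as.character(meta("subject_id")),
                    group = as.character(meta("group")),
                    stage = as.character(meta("stage")),
                    stringsAsFactors = FALSE)
  row <- cbind(row, as.data.frame(vals))
  if (includeAsymmetry) {
    ai <- list()
    for (k in splitSubregionKeys()) {
      l <- vals[[paste0("sor_", k, "_L")]]
      r <- vals[[paste0("sor_", k, "_R")]]
      ai[[paste0("ai_", k)]] <-
        if (is.null(l) || is.null(r)) NA_real_ else
          as.numeric(computeAsymmetry(l, r))
    }
    row <- cbind(row, as.data.frame(ai))
  }
  occ <- ct$code[ct$region == "occipital"]
  row$occipital_mean <- mean(volData(pet)[grid %in% occ])
  row
}

#' Feature table for a whole cohort
#'
#' Runs the per-subject pipeline (load volumes, obtain labels, optional
#' rigid MRI-to-PET registration, subregion split, feature extraction) over
#' a manifest. Labels come from the manifest's `labels_path` when
#' `segmenter` is NULL (supplied ground truth, mirroring manually
#' delineated inputs); otherwise the given [SegmenterModel-class] is
#' applied to each MRI. Per-subject failures are logged, the subject is
#' excluded, and a summary attribute `failures` reports them.
#'
#' @param manifest data.frame as written by [generateCohort()].
#' @param segmenter optional [SegmenterModel-class].
#' @param register logical: rigidly register MRI to PET and carry labels
#'   onto the PET grid. With FALSE the label grid is trusted to be the PET
#'   grid (exact for phantoms generated on a shared grid).
#' @param featureSet,includeAsymmetry,formula as in [extractSubject()].
#' @param subregionSeed seed for the subregion stage.
#' @param regConfig registration settings when `register = TRUE`.
#' @return data.frame with one row per successfully processed subject.
#' @export
cohortFeatureTable <- function(manifest, segmenter = NULL, register = FALSE,
                               featureSet = "striatum+midbrain",
                               includeAsymmetry = TRUE,
                               formula = "sbr", subregionSeed = 1L,
                               regConfig = registrationConfig()) {
  rows <- list(); failures <- character()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$subject_id[i]
    res <- tryCatch({
      pet <- readVolume(manifest$pet_path[i])
      if (is.null(segmenter)) {
        labels <- readLabelMap(manifest$labels_path[i])
      } else {
        mri <- readVolume(manifest$mri_path[i])
        labels <- segment(segmenter, mri)
      }
      if (register) {
        mri <- readVolume(manifest$mri_path[i])
        tr <- registerRigid(mri, pet, regConfig)
        labels <- resampleLabels(labels, tr, pet)
      }
      submap <- buildSubregionMap(labels, seed = deriveSeed(subregionSeed,
                                                            "subregions", id))
      extractSubject(pet, submap,
                     metadata = manifest[i, c("subject_id", "group", "stage")],
                     featureSet = featureSet,
                     includeAsymmetry = includeAsymmetry, formula = formula)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", id, conditionMessage(res)))
      message(sprintf("subject %s failed: %s", id, conditionMessage(res)))
    } else rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows))
    stop(sprintf("no subject processed successfully; failures: %s",
                 paste(failures, collapse = "; ")), call. = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  out
}

#' Group-level feature summary
#'
#' Per-group mean and SD of the bilateral-average SOR and of the asymmetry
#' index for every subregion, in the layout of a cohort characteristics
#' table.
#'
#' @param features feature table from [cohortFeatureTable()] or
#'   [sampleCohortFeatures()].
#' @return data.frame with columns group, measure (sor/ai), subregion,
#'   mean, sd, n.
#' @export
groupFeatureSummary <- function(features) {
  sorKeys <- unique(sub("_[RL]$", "", sub("^sor_", "",
                    grep("^sor_", names(features), value = TRUE))))
  out <- list()
  for (g in unique(features$group)) {
    f <- features[features$group == g, ]
    for (k in sorKeys) {
      r <- f[[paste0("sor_", k, "_R")]]; l <- f[[paste0("sor_", k, "_L")]]
      bil <- (r + l) / 2
      out[[length(out) + 1L]] <- data.frame(group = g, measure = "sor",
                                            subregion = k, mean = mean(bil),
                                            sd = stats::sd(bil), n = length(bil))
    }
    for (k in intersect(paste0("ai_", splitSubregionKeys()), names(f))) {
      v <- f[[k]]
      out[[length(out) + 1L]] <- data.frame(group = g, measure = "ai",
                                            subregion = sub("^ai_", "", k),
                                            mean = mean(v, na.rm = TRUE),
                                            sd = stats::sd(v, na.rm = TRUE),
                                            n = sum(!is.na(v)))
    }
  }
  do.call(rbind, out)
}
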