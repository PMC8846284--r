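#' @include AllClasses.R AllGenerics.R
NULL

# ---- region coding -------------------------------------------------------

#' Canonical parent-region code table
#'
#' Ten regions: caudate, putamen, pallidum, midbrain and occipital cortex,
#' right/left. Code 0 is background.
#'
#' @return data.frame with columns code, region, side.
#' @export
regionCodeTable <- function() {
  data.frame(
    code = 1:10,
    region = rep(c("caudate", "putamen", "pallidum", "midbrain", "occipital"),
                 each = 2),
    side = rep(c("R", "L"), 5),
    stringsAsFactors = FALSE)
}

#' Subregion code table
#'
#' Each caudate and putamen is split into anterior/middle/posterior thirds
#' (codes 11-16 caudate, 21-26 putamen); pallidum (5, 6), midbrain (7, 8)
#' and the occipital reference (9, 10) keep their parent codes.
#'
#' @return data.frame with columns code, region, side, subregion.
#' @export
subregionCodeTable <- function() {
  thirds <- c("anterior", "middle", "posterior")
  rbind(
    data.frame(code = c(11:13, 14:16), region = "caudate",
               side = rep(c("R", "L"), each = 3), subregion = rep(thirds, 2),
               stringsAsFactors = FALSE),
    data.frame(code = c(21:23, 24:26), region = "putamen",
               side = rep(c("R", "L"), each = 3), subregion = rep(thirds, 2),
               stringsAsFactors = FALSE),
    data.frame(code = c(5L, 6L, 7L, 8L, 9L, 10L),
               region = rep(c("pallidum", "midbrain", "occipital"), each = 2),
               side = rep(c("R", "L"), 3), subregion = "whole",
               stringsAsFactors = FALSE))
}

# subregion keys in canonical feature order
#' @keywords internal
splitSubregionKeys <- function() {
  as.vector(outer(c("anterior", "middle", "posterior"),
                  c("caudate", "putamen"),
                  function(a, b) paste(b, a, sep = "_")))
}

# ---- phantom specification ----------------------------------------------

#' Default striatal ROI geometry
#'
#' Ellipsoid centers and semi-axes (world mm, for a reference field of view
#' of 128 mm per axis; the generator rescales per axis for other grids).
#' Left/right pairs are mirror images about the mid-sagittal plane and the
#' ten ellipsoids are pairwise disjoint on the default grid. Caudate and
#' putamen are elongated along +y (anterior), so anatomical thirds are well
#' defined.
#'
#' @return data.frame with columns region, side, cx, cy, cz, ax, ay, az.
#' @export
defaultRoiGeometry <- function() {
  base <- data.frame(
    region = c("caudate", "putamen", "pallidum", "midbrain", "occipital"),
    dx = c(12, 23, 12, 4, 18),
    cy = c(76, 62, 56, 52, 22),
    cz = c(72, 63, 58, 46, 60),
    ax = c(4.5, 6, 3.5, 3.5, 10),
    ay = c(13, 15, 5, 6, 9),
    az = c(6, 7, 4.5, 7, 11),
    stringsAsFactors = FALSE)
  mid <- 64
  out <- do.call(rbind, lapply(seq_len(nrow(base)), function(i) {
    b <- base[i, ]
    data.frame(region = b$region, side = c("R", "L"),
               cx = c(mid + b$dx, mid - b$dx), cy = b$cy, cz = b$cz,
               ax = b$ax, ay = b$ay, az = b$az, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Specify a synthetic MRI/PET phantom
#'
#' @param gridShape integer(3), voxels per axis.
#' @param voxelSize isotropic voxel edge in mm.
#' @param roiGeometry ellipsoid table as from [defaultRoiGeometry()].
#' @param backgroundUptake nonnegative background PET level.
#' @param occipitalUptake positive reference-region PET level.
#' @param noiseSd additive Gaussian noise SD on the PET volume.
#' @param mriContrastStep MRI intensity step between consecutive region
#'   codes (region intensity = code x step).
#' @param mriNoiseSd additive Gaussian noise SD on the MRI volume.
#' @param seed RNG seed for spec-level determinism (subregion plateaus).
#' @return a validated `PhantomSpec` (list).
#' @export
phantomSpec <- function(gridShape = c(64L, 64L, 64L), voxelSize = 2,
                        roiGeometry = defaultRoiGeometry(),
                        backgroundUptake = 0.2, occipitalUptake = 1,
                        noiseSd = 0.05, mriContrastStep = 100,
                        mriNoiseSd = 5, seed = 1L) {
  spec <- list(gridShape = as.integer(gridShape), voxelSize = voxelSize,
               roiGeometry = roiGeometry, backgroundUptake = backgroundUptake,
               occipitalUptake = occipitalUptake, noiseSd = noiseSd,
               mriContrastStep = mriContrastStep, mriNoiseSd = mriNoiseSd,
               seed = as.integer(seed))
  class(spec) <- "PhantomSpec"
  validatePhantomSpec(spec)
  spec
}

#' Validate a PhantomSpec
#'
#' Checks grid/uptake sanity, that all ellipsoids (rescaled to the grid's
#' field of view) lie inside the grid, and that left/right ellipsoids are
#' mirror-symmetric about the mid-sagittal plane.
#'
#' @param spec a `PhantomSpec`.
#' @return invisibly TRUE; errors otherwise.
#' @export
validatePhantomSpec <- function(spec) {
  stopIfNot(length(spec$gridShape) == 3L && all(spec$gridShape >= 8L),
            "gridShape must be 3 integers >= 8")
  stopIfNot(spec$voxelSize > 0, "voxelSize must be positive")
  stopIfNot(spec$occipitalUptake > 0, "occipitalUptake must be positive")
  stopIfNot(spec$backgroundUptake >= 0, "backgroundUptake must be nonnegative")
  stopIfNot(spec$noiseSd >= 0, "noiseSd must be nonnegative")
  g <- scaledGeometry(spec)
  fov <- spec$gridShape * spec$voxelSize
  inside <- g$cx - g$ax >= 0 & g$cx + g$ax <= fov[1] &
    g$cy - g$ay >= 0 & g$cy + g$ay <= fov[2] &
    g$cz - g$az >= 0 & g$cz + g$az <= fov[3]
  stopIfNot(all(inside), "roi_geometry: some ellipsoids extend outside the grid")
  for (rg in unique(g$region)) {
    r <- g[g$region == rg & g$side == "R", ]
    l <- g[g$region == rg & g$side == "L", ]
    mirrored <- isTRUE(all.equal(r$cx - fov[1] / 2, fov[1] / 2 - l$cx)) &&
      isTRUE(all.equal(c(r$cy, r$cz, r$ax, r$ay, r$az),
                       c(l$cy, l$cz, l$ax, l$ay, l$az)))
    stopIfNot(mirrored, sprintf("roi_geometry: %s L/R not mirror-symmetric", rg))
  }
  invisible(TRUE)
}

# rescale the reference-FOV geometry to this spec's field of view
#' @keywords internal
scaledGeometry <- function(spec) {
  g <- spec$roiGeometry
  fov <- spec$gridShape * spec$voxelSize
  s <- fov / 128
  g$cx <- g$cx * s[1]; g$ax <- g$ax * s[1]
  g$cy <- g$cy * s[2]; g$ay <- g$ay * s[2]
  g$cz <- g$cz * s[3]; g$az <- g$az * s[3]
  g
}

# ---- group profiles ------------------------------------------------------

#' Define a diagnostic group's uptake profile
#'
#' Per-subregion mean/SD of the bilateral-average striatal-to-occipital
#' ratio (SOR) plus mean/SD of the bilateral asymmetry index for the six
#' split subregions. Pallidum and midbrain carry a SOR level but no
#' asymmetry (they are generated symmetric).
#'
#' @param group one of "PD", "MSA", "PSP", "NC".
#' @param sorMean,sorSd named numeric(8): caudate_anterior/middle/posterior,
#'   putamen_anterior/middle/posterior, pallidum, midbrain.
#' @param asymMean,asymSd named numeric(6) for the split subregions;
#'   means must lie in \[0, 2\].
#' @return a `GroupProfile` (list).
#' @export
groupProfile <- function(group, sorMean, sorSd, asymMean, asymSd) {
  keys <- c(splitSubregionKeys(), "pallidum", "midbrain")
  stopIfNot(group %in% c("PD", "MSA", "PSP", "NC"),
            "group must be PD, MSA, PSP or NC")
  stopIfNot(all(keys %in% names(sorMean)) && all(keys %in% names(sorSd)),
            "sorMean/sorSd must be named with the 8 subregion keys")
  stopIfNot(all(splitSubregionKeys() %in% names(asymMean)) &&
              all(splitSubregionKeys() %in% names(asymSd)),
            "asymMean/asymSd must be named with the 6 split subregion keys")
  stopIfNot(all(sorMean > -1), "sorMean entries must exceed -1")
  stopIfNot(all(asymMean >= 0 & asymMean <= 2), "asymMean must lie in [0, 2]")
  structure(list(group = group, sorMean = sorMean[keys], sorSd = sorSd[keys],
                 asymMean = asymMean[splitSubregionKeys()],
                 asymSd = asymSd[splitSubregionKeys()]),
            class = "GroupProfile")
}

#' Default group profiles
#'
#' SOR and asymmetry-index means/SDs for the six caudate/putamen subregions
#' in each diagnostic group, reflecting the characteristic patterns of the
#' disorders (rostrocaudal denervation gradient in PD with marked putaminal
#' asymmetry; diffuse loss in MSA/PSP; preserved uptake in controls).
#' Pallidum and midbrain levels are not tabulated group-wise in the
#' literature source for the striatal values and use fixed plausible
#' defaults (see the methods vignette).
#'
#' @return named list of `GroupProfile` objects (PD, MSA, PSP, NC).
#' @export
defaultGroupProfiles <- function() {
  k <- c(splitSubregionKeys(), "pallidum", "midbrain")
  a <- splitSubregionKeys()
  mk <- function(group, sm, ss, am, as_) {
    groupProfile(group,
                 sorMean = stats::setNames(sm, k), sorSd = stats::setNames(ss, k),
                 asymMean = stats::setNames(am, a), asymSd = stats::setNames(as_, a))
  }
  list(
    # order within vectors: caudate ant/mid/post, putamen ant/mid/post,
    # pallidum, midbrain
    PD = mk("PD",
            c(0.90, 0.52, 0.25, 1.13, 0.65, 0.46, 0.45, 0.30),
            c(0.53, 0.44, 0.25, 0.48, 0.34, 0.30, 0.30, 0.15),
            c(1.06, 1.28, 1.41, 0.63, 0.76, 0.67),
            c(0.84, 0.90, 0.72, 0.38, 0.50, 0.55)),
    MSA = mk("MSA",
             c(1.02, 0.62, 0.32, 1.26, 1.06, 0.77, 0.50, 0.28),
             c(0.83, 0.59, 0.36, 0.88, 0.93, 0.86, 0.35, 0.15),
             c(1.00, 1.50, 1.78, 0.40, 0.45, 0.59),
             c(0.71, 0.91, 0.86, 0.41, 0.47, 0.44)),
    PSP = mk("PSP",
             c(0.58, 0.25, 0.14, 1.03, 0.67, 0.55, 0.40, 0.20),
             c(0.40, 0.22, 0.13, 0.37, 0.29, 0.29, 0.25, 0.12),
             c(0.97, 1.57, 1.54, 0.31, 0.39, 0.52),
             c(0.71, 0.83, 0.71, 0.22, 0.40, 0.56)),
    NC = mk("NC",
            c(1.65, 1.26, 0.70, 2.25, 1.98, 1.50, 1.00, 0.50),
            c(0.65, 0.77, 0.55, 0.74, 0.91, 0.88, 0.40, 0.20),
            c(0.74, 0.89, 1.24, 0.25, 0.29, 0.45),
            c(0.66, 0.82, 0.84, 0.23, 0.28, 0.36)))
}

# ---- subject generation --------------------------------------------------

# truncated draws: SOR level redrawn while <= -1 + eps (physical
# nonnegativity of uptake), asymmetry redrawn into [0, 2]
#' @keywords internal
drawTruncated <- function(mean, sd, lower, upper = Inf, what = "value",
                          lowerOpen = TRUE) {
  inBounds <- function(x)
    (if (lowerOpen) x > lower else x >= lower) && x <= upper
  if (sd <= 0) {
    if (inBounds(mean)) return(mean)
    warning(sprintf("%s fixed value outside bounds; clamping", what),
            call. = FALSE)
    return(max(min(mean, upper), lower + if (lowerOpen) 1e-6 else 0))
  }
  for (i in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (inBounds(x)) return(x)
    if (i == 1L)
      warning(sprintf("%s draw outside bounds [%g, %g]; redrawing (truncation)",
                      what, lower, upper), call. = FALSE)
  }
  max(min(mean, upper), lower + if (lowerOpen) 1e-6 else 0)
}

#' Draw a subject's subregional SOR values from a group profile
#'
#' For each split subregion a bilateral level `s` and an asymmetry index
#' `a` are drawn; side SORs are `s (1 + a/2)` and `s (1 - a/2)` with the
#' higher side assigned left or right by a fair coin. Pallidum and midbrain
#' draw one symmetric level. Levels are truncated above -0.99 and
#' asymmetries into \[0, 2\] by redrawing.
#'
#' @param profile a `GroupProfile`.
#' @param seed integer seed for this subject's draws.
#' @return data.frame with columns key, side R/L SOR values, level, asym.
#' @export
drawSubjectSOR <- function(profile, seed) {
  set.seed(seed)
  keys <- splitSubregionKeys()
  out <- data.frame(key = c(keys, "pallidum", "midbrain"),
                    sorR = NA_real_, sorL = NA_real_,
                    level = NA_real_, asym = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(keys)) {
    k <- keys[i]
    s <- drawTruncated(profile$sorMean[[k]], profile$sorSd[[k]], -0.99,
                       what = paste("SOR", k))
    a <- drawTruncated(profile$asymMean[[k]], profile$asymSd[[k]], 0, 2,
                       what = paste("asymmetry", k), lowerOpen = FALSE)
    hi <- s * (1 + a / 2); lo <- s * (1 - a / 2)
    if (s < 0) { tmp <- hi; hi <- lo; lo <- tmp }  # keep |hi| >= |lo| ordering by value
    rightHigher <- stats::runif(1) < 0.5
    out$sorR[i] <- if (rightHigher) hi else lo
    out$sorL[i] <- if (rightHigher) lo else hi
    out$level[i] <- s; out$asym[i] <- a
  }
  for (k in c("pallidum", "midbrain")) {
    s <- drawTruncated(profile$sorMean[[k]], profile$sorSd[[k]], -0.99,
                       what = paste("SOR", k))
    j <- match(k, out$key)
    out$sorR[j] <- out$sorL[j] <- out$level[j] <- s
    out$asym[j] <- 0
  }
  out
}

#' Ground-truth label map of a phantom spec
#'
#' Paints the ten ROI ellipsoids onto the grid; errors if any two ellipsoids
#' overlap.
#'
#' @param spec a `PhantomSpec`.
#' @return a [LabelMap-class] with the canonical 10-region code table.
#' @export
phantomTruthLabels <- function(spec) {
  d <- spec$gridShape
  vs <- rep(spec$voxelSize, 3)
  cx <- (seq_len(d[1]) - 0.5) * vs[1]
  cy <- (seq_len(d[2]) - 0.5) * vs[2]
  cz <- (seq_len(d[3]) - 0.5) * vs[3]
  g <- scaledGeometry(spec)
  ct <- regionCodeTable()
  lab <- array(0L, d)
  for (i in seq_len(nrow(g))) {
    code <- ct$code[ct$region == g$region[i] & ct$side == g$side[i]]
    ex <- ((cx - g$cx[i]) / g$ax[i])^2
    ey <- ((cy - g$cy[i]) / g$ay[i])^2
    ez <- ((cz - g$cz[i]) / g$az[i])^2
    inside <- outer(outer(ex, ey, `+`), ez, `+`) <= 1
    if (any(lab[inside] != 0L))
      stop("roi_geometry: ellipsoids overlap on this grid", call. = FALSE)
    lab[inside] <- code
  }
  labelMap(lab, spacing = vs, origin = c(0, 0, 0), codeTable = ct)
}

#' Generate one synthetic subject (paired MRI + PET + truth labels)
#'
#' The PET volume plants, for every subregion, a mean uptake of
#' `occipitalUptake * (1 + SOR)` with the subregional SORs drawn from the
#' group profile (see [drawSubjectSOR()]); the anatomical thirds of caudate
#' and putamen are piecewise-constant plateaus. The occipital reference is
#' planted at `occipitalUptake` and the background at `backgroundUptake`;
#' Gaussian noise of SD `noiseSd` is added. The MRI volume encodes each
#' region as `code * mriContrastStep` plus noise, a simple learnable
#' contrast. Fully deterministic given `subjectSeed` (draws, noise) and
#' `spec$seed` (subregion plateaus).
#'
#' @param spec a `PhantomSpec`.
#' @param profile a `GroupProfile`.
#' @param subjectSeed integer seed for this subject.
#' @param truth optional precomputed list(labels, submap) shared across a
#'   cohort (computed from `spec` when NULL).
#' @return list with elements `mri`, `pet` ([VolumeImage-class]), `labels`
#'   ([LabelMap-class]) and `draws` (the drawn SOR/asymmetry table).
#' @export
generateSubject <- function(spec, profile, subjectSeed, truth = NULL) {
  validatePhantomSpec(spec)
  if (is.null(truth)) truth <- phantomTruth(spec)
  draws <- drawSubjectSOR(profile, deriveSeed(subjectSeed, "draws"))
  sub <- truth$submap
  ct <- codeTable(sub)
  pet <- array(spec$backgroundUptake, spec$gridShape)
  grid <- volData(sub)
  for (i in seq_len(nrow(ct))) {
    code <- ct$code[i]
    vox <- grid == code
    if (ct$region[i] == "occipital") {
      pet[vox] <- spec$occipitalUptake
      next
    }
    key <- if (ct$subregion[i] == "whole") ct$region[i] else
      paste(ct$region[i], ct$subregion[i], sep = "_")
    j <- match(key, draws$key)
    sor <- if (ct$side[i] == "R") draws$sorR[j] else draws$sorL[j]
    pet[vox] <- spec$occipitalUptake * (1 + sor)
  }
  mri <- volData(truth$labels) * spec$mriContrastStep
  set.seed(deriveSeed(subjectSeed, "noise"))
  if (spec$noiseSd > 0)
    pet <- pet + array(stats::rnorm(length(pet), 0, spec$noiseSd), dim(pet))
  if (spec$mriNoiseSd > 0)
    mri <- mri + array(stats::rnorm(length(mri), 0, spec$mriNoiseSd), dim(mri))
  vs <- rep(spec$voxelSize, 3)
  list(mri = volumeImage(mri, vs), pet = volumeImage(pet, vs),
       labels = truth$labels, draws = draws)
}

#' Shared truth geometry of a phantom spec
#'
#' Truth labels plus their subregion refinement; identical for every
#' subject generated from the same spec, so cohorts compute it once.
#'
#' @param spec a `PhantomSpec`.
#' @return list(labels, submap).
#' @export
phantomTruth <- function(spec) {
  labels <- phantomTruthLabels(spec)
  submap <- buildSubregionMap(labels, seed = deriveSeed(spec$seed, "subregions"))
  list(labels = labels, submap = submap)
}

# ---- cohort generation ---------------------------------------------------

#' Default cohort composition
#'
#' 50 PD, 37 MSA, 20 PSP patients and 22 normal controls; early-stage
#' fractions 22.0%, 45.9% and 40.0% for the patient groups (11 + 17 + 8 =
#' 36 early-stage of 107 patients).
#'
#' @name cohortDefaults
#' @export
defaultNPerGroup <- function() c(PD = 50L, MSA = 37L, PSP = 20L, NC = 22L)

#' @rdname cohortDefaults
#' @export
defaultESFractions <- function() c(PD = 0.22, MSA = 0.459, PSP = 0.40)

# early-stage assignment with exact per-group counts: round(n * fraction)
# subjects drawn at random as ES, the rest AS; NC carries no stage
#' @keywords internal
assignStages <- function(groups, esFractions, seed) {
  stage <- rep(NA_character_, length(groups))
  for (g in intersect(unique(groups), names(esFractions))) {
    idx <- which(groups == g)
    nES <- round(length(idx) * esFractions[[g]])
    set.seed(deriveSeed(seed, "stage", g))
    es <- sample(idx, nES)
    stage[idx] <- "AS"
    stage[es] <- "ES"
  }
  stage
}

#' Generate a synthetic cohort on disk
#'
#' Writes per-subject MRI/PET/label NIfTI volumes plus a manifest CSV with
#' columns `subject_id,group,stage,mri_path,pet_path,labels_path,seed`.
#' Per-subject seeds are derived from the cohort seed and the subject id,
#' so adding or removing one subject never changes another's volumes.
#'
#' @param spec a `PhantomSpec`.
#' @param profiles named list of `GroupProfile`s (as
#'   [defaultGroupProfiles()]).
#' @param nPerGroup named integer vector of subjects per group.
#' @param esFractions named early-stage fractions for patient groups.
#' @param outDir output directory (created if needed).
#' @param seed cohort master seed.
#' @param writeVolumes if FALSE, only the manifest is constructed (paths
#'   empty) -- useful for planning and bookkeeping tests.
#' @return the manifest data.frame (also written to
#'   `file.path(outDir, "manifest.csv")` when volumes are written).
#' @export
generateCohort <- function(spec, profiles = defaultGroupProfiles(),
                           nPerGroup = defaultNPerGroup(),
                           esFractions = defaultESFractions(),
                           outDir = NULL, seed = 1L, writeVolumes = TRUE) {
  stopIfNot(all(nPerGroup > 0), "nPerGroup entries must be positive")
  stopIfNot(all(names(nPerGroup) %in% names(profiles)),
            "every group needs a profile")
  groups <- rep(names(nPerGroup), nPerGroup)
  ids <- unlist(lapply(names(nPerGroup), function(g)
    sprintf("%s%03d", g, seq_len(nPerGroup[[g]]))))
  stage <- assignStages(groups, esFractions, seed)
  subjSeed <- vapply(ids, function(id) deriveSeed(seed, "subject", id), 1L)
  manifest <- data.frame(subject_id = ids, group = groups, stage = stage,
                         mri_path = "", pet_path = "", labels_path = "",
                         seed = subjSeed, stringsAsFactors = FALSE)
  if (writeVolumes) {
    stopIfNot(!is.null(outDir), "outDir required when writing volumes")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(outDir) || file.access(outDir, 2) != 0)
      stop(sprintf("output directory '%s' is not writable", outDir), call. = FALSE)
    truth <- phantomTruth(spec)
    for (i in seq_len(nrow(manifest))) {
      id <- manifest$subject_id[i]
      subj <- generateSubject(spec, profiles[[manifest$group[i]]],
                              manifest$seed[i], truth = truth)
      manifest$mri_path[i] <- file.path(outDir, paste0(id, "_mri.nii.gz"))
      manifest$pet_path[i] <- file.path(outDir, paste0(id, "_pet.nii.gz"))
      manifest$labels_path[i] <- file.path(outDir, paste0(id, "_labels.nii.gz"))
      writeVolume(subj$mri, manifest$mri_path[i])
      writeVolume(subj$pet, manifest$pet_path[i])
      writeLabelMap(subj$labels, manifest$labels_path[i])
    }
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
  }
  manifest
}

#' Sample subject features directly from group profiles
#'
#' A statistical (voxel-free) phantom mode: draws each subject's subregional
#' SOR/asymmetry values with [drawSubjectSOR()] and assembles the feature
#' row exactly as [extractSubject()] would, skipping volume rendering.
#' Used for classifier and importance experiments where only the feature
#' distribution matters; the voxel path is exercised by the round-trip
#' checks.
#'
#' @inheritParams generateCohort
#' @param featureSet "striatum" (14 SOR columns), "midbrain" (2) or
#'   "striatum+midbrain" (16).
#' @param includeAsymmetry include the six asymmetry-index columns.
#' @return feature data.frame, one row per subject.
#' @export
sampleCohortFeatures <- function(profiles = defaultGroupProfiles(),
                                 nPerGroup = defaultNPerGroup(),
                                 esFractions = defaultESFractions(),
                                 seed = 1L, featureSet = "striatum",
                                 includeAsymmetry = FALSE) {
  stopIfNot(all(nPerGroup > 0), "nPerGroup entries must be positive")
  groups <- rep(names(nPerGroup), nPerGroup)
  ids <- unlist(lapply(names(nPerGroup), function(g)
    sprintf("%s%03d", g, seq_len(nPerGroup[[g]]))))
  stage <- assignStages(groups, esFractions, seed)
  rows <- lapply(seq_along(ids), function(i) {
    draws <- drawSubjectSOR(profiles[[groups[i]]],
                            deriveSeed(seed, "subject", ids[i], "draws"))
    featureRowFromDraws(draws, ids[i], groups[i], stage[i], featureSet,
                        includeAsymmetry)
  })
  do.call(rbind, rows)
}

# assemble one canonical feature row from a draw table (shared by the
# statistical sampler and tests)
#' @keywords internal
featureRowFromDraws <- function(draws, id, group, stage, featureSet,
                                includeAsymmetry) {
  keys <- featureSetKeys(featureSet)
  sor <- list()
  for (k in keys) {
    j <- match(k, draws$key)
    sor[[paste0("sor_", k, "_R")]] <- draws$sorR[j]
    sor[[paste0("sor_", k, "_L")]] <- draws$sorL[j]
  }
  row <- data.frame(subject_id = id, group = group, stage = stage,
                    stringsAsFactors = FALSE)
  row <- cbind(row, as.data.frame(sor))
  if (includeAsymmetry) {
    ai <- list()
    for (k in splitSubregionKeys()) {
      j <- match(k, draws$key)
      ai[[paste0("ai_", k)]] <- computeAsymmetry(draws$sorL[j], draws$sorR[j])
    }
    row <- cbind(row, as.data.frame(ai))
  }
  row
}

#' @keywords internal
featureSetKeys <- function(featureSet) {
  switch(featureSet,
         "striatum" = c(splitSubregionKeys(), "pallidum"),
         "midbrain" = "midbrain",
         "striatum+midbrain" = c(splitSubregionKeys(), "pallidum", "midbrain"),
         stop(sprintf("unknown feature_set '%s'", featureSet), call. = FALSE))
}
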