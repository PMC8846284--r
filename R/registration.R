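#' @include AllClasses.R AllGenerics.R
NULL

# ---- transform algebra ---------------------------------------------------

#' @keywords internal
rotationMatrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to world points
#'
#' @param transform a [RigidTransform-class].
#' @param xyz n x 3 matrix of world mm coordinates (moving space).
#' @return n x 3 matrix of transformed coordinates (fixed space).
#' @export
applyTransform <- function(transform, xyz) {
  R <- rotationMatrix(transform@angles)
  xyz <- as.matrix(xyz)
  sweep(sweep(xyz, 2, transform@center, `-`) %*% t(R), 2,
        transform@center + transform@translation, `+`)
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return the inverse transform, expressed as a 4 x 4 homogeneous matrix
#'   applicator (see Details) wrapped back into angles where possible.
#' @details The inverse of `p -> R (p - c) + c + t` is
#'   `q -> R' (q - c - t) + c` with `R' = R^T`; it is returned as a
#'   [RigidTransform-class] with the same center, angles recovered from
#'   `R^T` and translation `-R^T t`.
#' @export
invertTransform <- function(transform) {
  R <- rotationMatrix(transform@angles)
  Rt <- t(R)
  # recover ZYX Euler angles from Rt
  ay <- asin(-Rt[3, 1])
  if (abs(cos(ay)) > 1e-9) {
    ax <- atan2(Rt[3, 2], Rt[3, 3])
    az <- atan2(Rt[2, 1], Rt[1, 1])
  } else {  # gimbal lock
    ax <- atan2(-Rt[2, 3], Rt[2, 2]); az <- 0
  }
  rigidTransform(angles = c(ax, ay, az),
                 translation = as.vector(-Rt %*% transform@translation),
                 center = transform@center)
}

#' Homogeneous 4 x 4 matrix of a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return 4 x 4 matrix mapping homogeneous moving-world to fixed-world.
#' @export
transformMatrix <- function(transform) {
  R <- rotationMatrix(transform@angles)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- transform@center + transform@translation -
    R %*% transform@center
  m
}

# ---- resampling ----------------------------------------------------------

# trilinear sample of array `a` at continuous 1-based voxel coordinates;
# outside voxels return `fill`
#' @keywords internal
trilinearSample <- function(a, ijk, fill = NA_real_) {
  d <- dim(a)
  i <- ijk[, 1]; j <- ijk[, 2]; k <- ijk[, 3]
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- rep(fill, nrow(ijk))
  if (!any(ok)) return(out)
  i <- pmin(pmax(i[ok], 1), d[1]); j <- pmin(pmax(j[ok], 1), d[2])
  k <- pmin(pmax(k[ok], 1), d[3])
  i0 <- pmin(floor(i), d[1] - 1L); j0 <- pmin(floor(j), d[2] - 1L)
  k0 <- pmin(floor(k), d[3] - 1L)
  i0 <- pmax(i0, 1); j0 <- pmax(j0, 1); k0 <- pmax(k0, 1)
  fi <- i - i0; fj <- j - j0; fk <- k - k0
  at <- function(ii, jj, kk) a[cbind(ii, jj, kk)]
  v <- at(i0, j0, k0) * (1 - fi) * (1 - fj) * (1 - fk) +
    at(i0 + 1, j0, k0) * fi * (1 - fj) * (1 - fk) +
    at(i0, j0 + 1, k0) * (1 - fi) * fj * (1 - fk) +
    at(i0, j0, k0 + 1) * (1 - fi) * (1 - fj) * fk +
    at(i0 + 1, j0 + 1, k0) * fi * fj * (1 - fk) +
    at(i0 + 1, j0, k0 + 1) * fi * (1 - fj) * fk +
    at(i0, j0 + 1, k0 + 1) * (1 - fi) * fj * fk +
    at(i0 + 1, j0 + 1, k0 + 1) * fi * fj * fk
  out[ok] <- v
  out
}

#' Resample a volume through a rigid transform
#'
#' Pulls the moving volume onto the target grid by trilinear interpolation:
#' each target voxel center is mapped through the inverse transform into
#' moving space.
#'
#' @param moving a [VolumeImage-class].
#' @param transform a [RigidTransform-class] mapping moving-world to
#'   fixed-world.
#' @param targetGrid a [VolumeImage-class] defining the output grid.
#' @param fill value for voxels mapping outside the moving volume.
#' @return a [VolumeImage-class] on the target grid.
#' @export
resampleVolume <- function(moving, transform, targetGrid, fill = 0) {
  xyz <- voxelToWorld(targetGrid)
  src <- applyTransform(invertTransform(transform), xyz)
  ijk <- worldToVoxel(moving, src)
  vals <- trilinearSample(volData(moving), ijk, fill = fill)
  volumeImage(array(vals, dim(targetGrid)), voxelSpacing(targetGrid),
              volOrigin(targetGrid))
}

#' Carry a label map onto a target grid through a rigid transform
#'
#' Nearest-neighbor interpolation (labels are categorical); the code table
#' is preserved and no code absent from the input can appear in the output.
#' A region that vanishes entirely after resampling triggers a warning and
#' is listed in the `missingRegions` attribute.
#'
#' @param labels a [LabelMap-class] on the moving grid.
#' @param transform a [RigidTransform-class] (moving-world to fixed-world).
#' @param targetGrid a [VolumeImage-class] defining the output grid.
#' @return a [LabelMap-class] on the target grid.
#' @export
resampleLabels <- function(labels, transform, targetGrid) {
  identity <- all(abs(transform@angles) < 1e-12) &&
    all(abs(transform@translation) < 1e-12)
  sameGrid <- identical(dim(labels), dim(targetGrid)) &&
    isTRUE(all.equal(voxelSpacing(labels), voxelSpacing(targetGrid))) &&
    isTRUE(all.equal(volOrigin(labels), volOrigin(targetGrid)))
  if (identity && sameGrid) {
    out <- labels
  } else {
    xyz <- voxelToWorld(targetGrid)
    src <- applyTransform(invertTransform(transform), xyz)
    ijk <- round(worldToVoxel(labels, src))
    d <- dim(labels)
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
      ijk[, 3] >= 1 & ijk[, 3] <= d[3]
    vals <- integer(nrow(ijk))
    vals[ok] <- volData(labels)[ijk[ok, , drop = FALSE]]
    out <- labelMap(array(vals, dim(targetGrid)), voxelSpacing(targetGrid),
                    volOrigin(targetGrid), codeTable = codeTable(labels))
  }
  inCodes <- setdiff(unique(as.vector(volData(labels))), 0L)
  outCodes <- setdiff(unique(as.vector(volData(out))), 0L)
  lost <- setdiff(inCodes, outCodes)
  if (length(lost)) {
    ct <- codeTable(labels)
    nm <- paste(ct$region[match(lost, ct$code)], ct$side[match(lost, ct$code)])
    warning(sprintf("region(s) vanished after resampling: %s",
                    paste(nm, collapse = ", ")), call. = FALSE)
  }
  attr(out, "missingRegions") <- lost
  out
}

# ---- mutual-information metric ------------------------------------------

# negative mutual information between fixed values and the transformed
# moving volume, from a 32x32 joint histogram over in-bounds voxels
#' @keywords internal
negMutualInformation <- function(par, movingArr, movingVol, fixedVol,
                                 fixedVals, xyzFixed, center,
                                 fixedBin, nBins = 32L) {
  tr <- rigidTransform(angles = par[4:6] * pi / 180, translation = par[1:3],
                       center = center)
  src <- applyTransform(invertTransform(tr), xyzFixed)
  ijk <- worldToVoxel(movingVol, src)
  mv <- trilinearSample(movingArr, ijk, fill = NA_real_)
  ok <- !is.na(mv)
  if (sum(ok) < 100) return(0)
  mv <- mv[ok]
  rng <- range(mv)
  if (rng[2] <= rng[1]) return(0)
  mb <- pmin(floor((mv - rng[1]) / (rng[2] - rng[1]) * nBins) + 1L, nBins)
  fb <- fixedBin[ok]
  joint <- tabulate(fb + nBins * (mb - 1L), nbins = nBins * nBins)
  p <- joint / sum(joint)
  pj <- matrix(p, nBins, nBins)
  px <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  -sum(pj[nz] * log(pj[nz] / (px[row(pj)[nz]] * py[col(pj)[nz]])))
}

#' @keywords internal
binValues <- function(v, nBins = 32L) {
  rng <- range(v)
  if (rng[2] <= rng[1]) stop("constant volume", call. = FALSE)
  pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * nBins) + 1L, nBins)
}

# monotone compass search: try +/- step along each parameter, accept any
# improvement, halve the step when a full sweep stalls
#' @keywords internal
patternSearch <- function(par, obj, stepInit, stepMin, maxEval = 1000L) {
  val <- obj(par)
  evals <- 1L
  step <- stepInit
  while (step >= stepMin * (1 - 1e-12)) {
    improved <- FALSE
    for (d in seq_along(par)) {
      for (s in c(1, -1)) {
        cand <- par
        cand[d] <- cand[d] + s * step
        v <- obj(cand)
        evals <- evals + 1L
        if (v < val - 1e-12) {
          par <- cand; val <- v; improved <- TRUE
          break
        }
        if (evals >= maxEval)
          return(list(par = par, value = val, converged = FALSE))
      }
    }
    if (!improved) step <- step / 2
  }
  list(par = par, value = val, converged = TRUE)
}

#' Registration settings
#'
#' @param levels integer pooling factors of the multiresolution pyramid,
#'   coarse to fine; the last entry must be 1 (native resolution).
#' @param maxit evaluation budget unit per pyramid level (each level's
#'   pattern search may spend up to `4 * maxit` metric evaluations).
#' @param nBins joint-histogram bins for the mutual-information metric.
#' @param captureTrans,captureRot half-ranges (mm, degrees) of the
#'   exhaustive capture grids evaluated at the coarsest level before any
#'   local optimization.
#' @param edgeQuantile at native resolution the metric uses a deterministic
#'   informative subsample: every voxel whose local intensity gradient
#'   exceeds this quantile, plus a regular stride through the flat
#'   remainder.
#' @param flatStride stride through the low-gradient voxels.
#' @return a list of settings.
#' @export
registrationConfig <- function(levels = c(4L, 2L, 1L), maxit = 250L,
                               nBins = 32L, captureTrans = 6, captureRot = 5,
                               edgeQuantile = 0.9, flatStride = 12L) {
  list(levels = levels, maxit = maxit, nBins = nBins,
       captureTrans = captureTrans, captureRot = captureRot,
       edgeQuantile = edgeQuantile, flatStride = flatStride)
}

#' Rigidly register a moving volume to a fixed volume
#'
#' Multimodal rigid alignment maximizing histogram mutual information.
#' Two stages: (1) capture -- exhaustive translation and rotation grids
#' evaluated at the coarsest pyramid level, which makes the optimization
#' robust to the local optima the piecewise-smooth metric has far from
#' alignment; (2) monotone compass (pattern) search down a mean-pooling
#' pyramid, with step sizes halving from 2 mm/deg at the coarsest level to
#' 1/32 mm/deg at native resolution. Pattern search only ever accepts
#' improvements, which makes it reliable on the locally rough, quantized
#' surface of a histogram metric where simplex methods stall. At native
#' resolution the metric uses a deterministic edge-preferring voxel
#' subsample (flat voxels carry almost no alignment information, so
#' sampling is concentrated where the gradient is). The identity is kept
#' as a candidate and the best final metric wins, so registering a volume
#' to itself returns the exact identity. If a search level exhausts its
#' evaluation budget the best parameters so far are returned with
#' `converged = FALSE` and a warning.
#'
#' @param moving,fixed non-constant [VolumeImage-class] volumes.
#' @param config settings from [registrationConfig()].
#' @return a [RigidTransform-class] mapping moving-world to fixed-world,
#'   with the achieved and initial metric in attributes `metric` and
#'   `initialMetric`.
#' @export
registerRigid <- function(moving, fixed, config = registrationConfig()) {
  fArr <- volData(fixed); mArr <- volData(moving)
  if (diff(range(fArr)) == 0 || diff(range(mArr)) == 0)
    stop("registration requires non-constant volumes", call. = FALSE)
  center <- volOrigin(fixed) + dim(fixed) * voxelSpacing(fixed) / 2
  mkObjective <- function(lev, edgeSample = FALSE) {
    fPool <- poolVolume(fArr, lev)
    mPool <- poolVolume(mArr, lev)
    fVol <- volumeImage(fPool, voxelSpacing(fixed) * lev, volOrigin(fixed))
    mVol <- volumeImage(mPool, voxelSpacing(moving) * lev, volOrigin(moving))
    xyz <- voxelToWorld(fVol)
    fVals <- as.vector(fPool)
    if (edgeSample) {
      grad <- abs(as.vector(fPool - boxBlur3(fPool, 1)))
      edge <- which(grad > stats::quantile(grad, config$edgeQuantile))
      flat <- setdiff(seq_along(fVals), edge)
      keep <- sort(c(edge, flat[seq(1, length(flat), by = config$flatStride)]))
      xyz <- xyz[keep, , drop = FALSE]; fVals <- fVals[keep]
    }
    fBin <- binValues(fVals, config$nBins)
    function(p) negMutualInformation(p, mPool, mVol, fVol, fVals, xyz,
                                     center, fBin, config$nBins)
  }
  convergedAll <- TRUE
  levels <- config$levels
  coarse <- levels[1]
  objCoarse <- mkObjective(coarse)
  # capture grids: translation first (rotation zero), then rotation at the
  # best translation
  tGrid <- as.matrix(expand.grid(
    x = seq(-config$captureTrans, config$captureTrans, by = 2),
    y = seq(-config$captureTrans, config$captureTrans, by = 2),
    z = seq(-config$captureTrans, config$captureTrans, by = 2)))
  tVals <- apply(tGrid, 1, function(t_) objCoarse(c(t_, 0, 0, 0)))
  tBest <- tGrid[which.min(tVals), ]
  rGrid <- as.matrix(expand.grid(
    ax = seq(-config$captureRot, config$captureRot, by = 2.5),
    ay = seq(-config$captureRot, config$captureRot, by = 2.5),
    az = seq(-config$captureRot, config$captureRot, by = 2.5)))
  rVals <- apply(rGrid, 1, function(r_) objCoarse(c(tBest, r_)))
  par <- c(tBest, rGrid[which.min(rVals), ])
  # pyramid refinement by monotone compass (pattern) search: robust on the
  # quantized, locally rough surface the histogram metric has, where a 6-D
  # simplex stalls
  schedule <- list(c(2, 0.5), c(1, 0.25), c(0.5, 1 / 32))
  objFine <- NULL
  for (li in seq_along(levels)) {
    lev <- levels[li]
    obj <- if (lev == coarse) objCoarse else
      mkObjective(lev, edgeSample = lev == 1L)
    if (lev == 1L) objFine <- obj
    st <- patternSearch(par, obj, stepInit = schedule[[min(li, 3)]][1],
                        stepMin = schedule[[min(li, 3)]][2],
                        maxEval = config$maxit * 4L)
    if (!st$converged) convergedAll <- FALSE
    par <- st$par
  }
  if (is.null(objFine)) objFine <- mkObjective(1L, edgeSample = TRUE)
  init <- objFine(rep(0, 6))
  cand <- list(list(par = rep(0, 6), val = init),
               list(par = par, val = objFine(par)))
  best <- cand[[which.min(vapply(cand, `[[`, 0, "val"))]]
  if (!convergedAll)
    warning("registration optimizer did not fully converge; returning best so far",
            call. = FALSE)
  out <- rigidTransform(angles = best$par[4:6] * pi / 180,
                        translation = best$par[1:3], center = center)
  out@converged <- convergedAll
  attr(out, "metric") <- best$val
  attr(out, "initialMetric") <- init
  out
}
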