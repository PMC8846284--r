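#' @include AllClasses.R AllGenerics.R
NULL

#' Split a nucleus into three equal-volume subregions
#'
#' Implements the equal-volume anterior/middle/posterior tripartition of a
#' caudate or putamen: k-means (k = 3) on voxel world coordinates locates
#' three centroids, then voxels are assigned to centroids by a balanced
#' greedy rule so the three parts differ by at most one voxel. Plain
#' k-means cannot guarantee equal volumes, so the balancing step is part of
#' the contract, not an implementation detail.
#'
#' Balancing rule: clusters are ordered anterior-to-posterior by centroid
#' +y; capacities are `floor(V/3)` with one extra voxel for the first
#' `V mod 3` clusters in that order. Voxels are processed in decreasing
#' margin between their best and second-best centroid distance and assigned
#' to the nearest centroid with free capacity. Finally the three parts are
#' (re)named anterior/middle/posterior by decreasing mean +y of their
#' voxels (ties by mean +z).
#'
#' @param labels a [LabelMap-class].
#' @param regionCode integer code of the nucleus to split (>= 3 voxels).
#' @param seed RNG seed for the k-means restarts.
#' @return list of three integer vectors of linear voxel indices, ordered
#'   anterior, middle, posterior.
#' @export
tripartitionNucleus <- function(labels, regionCode, seed = 1L) {
  vox <- which(volData(labels) == regionCode)
  V <- length(vox)
  if (V < 3L) {
    nm <- codeTable(labels)
    nm <- nm[nm$code == regionCode, ]
    stop(sprintf("region %s (code %d) has %d voxel(s); >= 3 required",
                 if (nrow(nm)) paste(nm$region, nm$side) else "?",
                 regionCode, V), call. = FALSE)
  }
  idx <- arrayInd(vox, dim(labels))
  xyz <- voxelToWorld(labels, idx)
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(xyz, centers = 3, nstart = 10,
                                       iter.max = 100))
  centers <- km$centers
  # anterior-to-posterior centroid order fixes which clusters get the
  # remainder voxels
  ord <- order(-centers[, 2], -centers[, 3])
  centers <- centers[ord, , drop = FALSE]
  cap <- rep(V %/% 3L, 3L)
  extra <- V %% 3L
  if (extra > 0L) cap[seq_len(extra)] <- cap[seq_len(extra)] + 1L
  d2 <- sapply(1:3, function(c_) colSums((t(xyz) - centers[c_, ])^2))
  pref <- t(apply(d2, 1, order))
  sorted <- apply(d2, 1, sort)
  margin <- sorted[2, ] - sorted[1, ]
  assign <- integer(V)
  left <- cap
  for (i in order(-margin)) {
    for (c_ in pref[i, ]) {
      if (left[c_] > 0L) { assign[i] <- c_; left[c_] <- left[c_] - 1L; break }
    }
  }
  parts <- split(vox, assign)
  # name parts by realized mean anterior coordinate
  my <- vapply(parts, function(v) {
    ii <- arrayInd(v, dim(labels)); w <- voxelToWorld(labels, ii)
    mean(w[, 2]) + 1e-9 * mean(w[, 3])
  }, 0)
  parts <- parts[order(-my)]
  names(parts) <- c("anterior", "middle", "posterior")
  parts
}

#' Refine a label map into the 16-subregion parcellation
#'
#' Applies [tripartitionNucleus()] to both caudates and both putamens
#' (12 subregions) and passes pallidum, midbrain and the occipital
#' reference through unsplit, yielding the full feature parcellation on the
#' same grid.
#'
#' @param labels a [LabelMap-class] containing at least both caudates and
#'   both putamens.
#' @param seed RNG seed (per-nucleus seeds are derived from it).
#' @return a [SubregionMap-class].
#' @export
buildSubregionMap <- function(labels, seed = 1L) {
  ct <- codeTable(labels)
  grid <- volData(labels)
  need <- ct[ct$region %in% c("caudate", "putamen"), ]
  missing <- need$code[!need$code %in% unique(as.vector(grid))]
  if (length(missing))
    stop(sprintf("missing nuclei: codes %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  sct <- subregionCodeTable()
  out <- grid
  out[grid == 1L | grid == 2L | grid == 3L | grid == 4L] <- 0L
  for (i in seq_len(nrow(need))) {
    code <- need$code[i]
    parts <- tripartitionNucleus(labels, code,
                                 seed = deriveSeed(seed, "nucleus", code))
    for (third in names(parts)) {
      newCode <- sct$code[sct$region == need$region[i] &
                            sct$side == need$side[i] & sct$subregion == third]
      out[parts[[third]]] <- newCode
    }
  }
  storage.mode(out) <- "integer"
  new("SubregionMap", data = out, spacing = voxelSpacing(labels),
      origin = volOrigin(labels), codeTable = sct)
}
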