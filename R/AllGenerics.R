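#' @include AllClasses.R
NULL

#' Voxel data of a volume
#' @param x a [VolumeImage-class].
#' @return the underlying 3D array.
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname volData
#' @export
setMethod("volData", "VolumeImage", function(x) x@data)

#' Voxel spacing (mm)
#' @param x a [VolumeImage-class].
#' @return numeric(3).
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "VolumeImage", function(x) x@spacing)

#' World origin (mm)
#' @param x a [VolumeImage-class].
#' @return numeric(3).
#' @export
setGeneric("volOrigin", function(x) standardGeneric("volOrigin"))
#' @rdname volOrigin
#' @export
setMethod("volOrigin", "VolumeImage", function(x) x@origin)

#' Region code table of a label map
#' @param x a [LabelMap-class].
#' @return data.frame with columns code, region, side (and subregion for
#'   [SubregionMap-class]).
#' @export
setGeneric("codeTable", function(x) standardGeneric("codeTable"))
#' @rdname codeTable
#' @export
setMethod("codeTable", "LabelMap", function(x) x@codeTable)

#' @export
setMethod("dim", "VolumeImage", function(x) dim(x@data))

#' Confusion-matrix counts
#' @param x a [ConfusionMatrix-class].
#' @return integer matrix, rows = predicted, columns = true.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname counts
#' @export
setMethod("counts", "ConfusionMatrix", function(x) x@counts)

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s %dx%dx%d, spacing %s mm, origin (%s) mm\n",
              class(object), d[1], d[2], d[3],
              paste(format(object@spacing), collapse = "x"),
              paste(format(object@origin), collapse = ", ")))
  rng <- range(object@data)
  cat(sprintf("  values in [%.4g, %.4g]\n", rng[1], rng[2]))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@data)
  codes <- sort(unique(as.vector(object@data)))
  cat(sprintf("%s %dx%dx%d, %d labelled region(s) of %d coded\n",
              class(object), d[1], d[2], d[3],
              sum(codes != 0), nrow(object@codeTable)))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: rot (%.3f, %.3f, %.3f) deg, t (%.3f, %.3f, %.3f) mm\n",
              object@angles[1] * 180 / pi, object@angles[2] * 180 / pi,
              object@angles[3] * 180 / pi, object@translation[1],
              object@translation[2], object@translation[3]))
  cat(sprintf("  center (%s) mm%s\n", paste(format(object@center), collapse = ", "),
              if (object@converged) "" else "  [not converged]"))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = predicted, columns = true)\n")
  print(object@counts)
})

setMethod("show", "SegmenterModel", function(object) {
  cat(sprintf("SegmenterModel, backend = %s\n", object@backend))
  if (object@backend == "learned" && !is.null(object@fit$lossHistory))
    cat(sprintf("  trained %d epochs, loss %.4f -> %.4f\n",
                length(object@fit$lossHistory),
                object@fit$lossHistory[1],
                object@fit$lossHistory[length(object@fit$lossHistory)]))
})

# --- shared coordinate helpers -------------------------------------------

#' World coordinates of voxel centers
#'
#' @param vol a [VolumeImage-class].
#' @param idx integer matrix of 1-based voxel indices (n x 3); default all
#'   voxels in array order.
#' @return n x 3 matrix of world mm coordinates (RAS).
#' @export
voxelToWorld <- function(vol, idx = NULL) {
  if (is.null(idx)) {
    d <- dim(vol@data)
    idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                                 k = seq_len(d[3])))
  }
  sweep(sweep(idx - 0.5, 2, vol@spacing, `*`), 2, vol@origin, `+`)
}

#' Continuous voxel indices of world points
#'
#' @param vol a [VolumeImage-class].
#' @param xyz n x 3 matrix of world mm coordinates.
#' @return n x 3 matrix of continuous 1-based voxel indices.
#' @export
worldToVoxel <- function(vol, xyz) {
  sweep(sweep(xyz, 2, vol@origin, `-`), 2, vol@spacing, `/`) + 0.5
}
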