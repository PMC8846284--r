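#' @import methods
NULL

#' VolumeImage: a 3D scalar grid with world geometry
#'
#' The elementary container shared by all stages: a 3D array of voxel values
#' with isotropic-or-not spacing (mm) and a world origin (mm), in RAS
#' orientation (+x right, +y anterior, +z superior). Voxel (i, j, k)
#' (1-based) has world center `origin + (c(i, j, k) - 0.5) * spacing`.
#'
#' @slot data 3D numeric array of voxel values.
#' @slot spacing numeric(3), voxel edge lengths in mm, all > 0.
#' @slot origin numeric(3), world coordinate (mm) of the corner of voxel
#'   (1,1,1).
#' @export
setClass("VolumeImage",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("VolumeImage", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) return("spacing must be 3 positive numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite numbers")
  TRUE
})

#' Construct a VolumeImage
#'
#' @param data 3D numeric array.
#' @param spacing voxel spacing in mm (length 1 or 3).
#' @param origin world origin in mm (length 3).
#' @return a [VolumeImage-class] object.
#' @export
volumeImage <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VolumeImage", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' LabelMap: integer-coded regions of interest on a volume grid
#'
#' A [VolumeImage-class] whose voxel values are integer region codes
#' (0 = background), together with a code table naming each region and its
#' side. The canonical parent-region codes are 1..10 covering
#' caudate/putamen/pallidum/midbrain/occipital x right/left (see
#' [regionCodeTable()]).
#'
#' @slot codeTable data.frame with columns `code`, `region`, `side` and
#'   (for subregion maps) `subregion`.
#' @export
setClass("LabelMap", contains = "VolumeImage",
  representation(codeTable = "data.frame"))

setValidity("LabelMap", function(object) {
  codes <- unique(as.vector(object@data))
  codes <- codes[codes != 0]
  if (any(codes != as.integer(codes))) return("label values must be integers")
  if (!all(c("code", "region", "side") %in% names(object@codeTable)))
    return("codeTable needs columns code, region, side")
  if (!all(codes %in% object@codeTable$code))
    return("grid contains codes missing from codeTable")
  TRUE
})

# warn (not error) about one-sided L/R pairs: a degraded segmentation may
# legitimately lose one side, and such maps must remain representable
#' @keywords internal
warnUnpairedSides <- function(grid, ct) {
  codes <- unique(as.vector(grid))
  sided <- ct[ct$side %in% c("R", "L"), ]
  for (rg in unique(sided$region)) {
    pair <- sided[sided$region == rg, ]
    srs <- if ("subregion" %in% names(pair)) unique(pair$subregion) else NA
    for (sr in srs) {
      pp <- if (is.na(sr[1])) pair else pair[pair$subregion == sr, ]
      got <- pp$code %in% codes
      if (length(unique(got)) > 1L)
        warning(sprintf("region %s present on one side only", rg),
                call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Construct a LabelMap
#'
#' @param data 3D integer array of region codes (0 = background).
#' @param spacing,origin grid geometry as in [volumeImage()].
#' @param codeTable data.frame mapping codes to region names and sides;
#'   defaults to the canonical 10-region table.
#' @return a [LabelMap-class].
#' @export
labelMap <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     codeTable = regionCodeTable()) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(data) <- "integer"
  warnUnpairedSides(data, codeTable)
  new("LabelMap", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), codeTable = codeTable)
}

#' SubregionMap: label map refined into striatal subregions
#'
#' A [LabelMap-class] in which each caudate and putamen has been split into
#' anterior/middle/posterior thirds of equal volume; pallidum, midbrain and
#' occipital pass through unsplit. See [subregionCodeTable()] for codes.
#'
#' @export
setClass("SubregionMap", contains = "LabelMap")

#' RigidTransform: a 6-parameter world-space rigid transform
#'
#' Maps moving-world coordinates to fixed-world coordinates as
#' `R (p - center) + center + translation`, with `R = Rz(az) Ry(ay) Rx(ax)`.
#'
#' @slot angles numeric(3), rotations about x, y, z in radians.
#' @slot translation numeric(3), offsets in mm.
#' @slot center numeric(3), rotation center in world mm.
#' @slot converged logical flag set by [registerRigid()].
#' @export
setClass("RigidTransform",
  representation(angles = "numeric", translation = "numeric",
                 center = "numeric", converged = "logical"),
  prototype(angles = c(0, 0, 0), translation = c(0, 0, 0),
            center = c(0, 0, 0), converged = TRUE))

setValidity("RigidTransform", function(object) {
  if (length(object@angles) != 3L || length(object@translation) != 3L ||
      length(object@center) != 3L) return("angles/translation/center must have length 3")
  if (any(!is.finite(c(object@angles, object@translation, object@center))))
    return("transform parameters must be finite")
  TRUE
})

#' Construct a RigidTransform
#'
#' @param angles rotations (x, y, z) in radians.
#' @param translation offsets in mm.
#' @param center rotation center in world mm.
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  new("RigidTransform", angles = as.numeric(angles),
      translation = as.numeric(translation), center = as.numeric(center))
}

#' ConfusionMatrix: predicted-by-true classification counts
#'
#' Rows index the predicted class, columns the true (standard-of-truth)
#' class, in a fixed class order.
#'
#' @slot counts integer matrix with identical row/column dimnames.
#' @export
setClass("ConfusionMatrix", representation(counts = "matrix"))

setValidity("ConfusionMatrix", function(object) {
  cm <- object@counts
  if (nrow(cm) != ncol(cm)) return("counts must be square")
  if (any(cm < 0) || any(cm != round(cm))) return("counts must be nonnegative integers")
  if (is.null(rownames(cm)) || !identical(rownames(cm), colnames(cm)))
    return("row and column names must match (class order)")
  TRUE
})

#' Construct a ConfusionMatrix
#'
#' Either from a square count matrix, or from paired true/predicted label
#' vectors.
#'
#' @param counts square matrix (rows = predicted, columns = true), or NULL.
#' @param true,predicted label vectors (used when `counts` is NULL).
#' @param classes class order; defaults to `c("PD", "MSA", "PSP")` for a
#'   bare matrix, or the union of observed labels.
#' @return a [ConfusionMatrix-class].
#' @export
confusionMatrix <- function(counts = NULL, true = NULL, predicted = NULL,
                            classes = NULL) {
  if (is.null(counts)) {
    if (is.null(classes)) classes <- union(levels(factor(true)), levels(factor(predicted)))
    counts <- table(factor(predicted, classes), factor(true, classes))
    counts <- matrix(as.integer(counts), length(classes), length(classes),
                     dimnames = list(classes, classes))
  } else {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts))) {
      if (is.null(classes)) classes <- c("PD", "MSA", "PSP")[seq_len(nrow(counts))]
      dimnames(counts) <- list(classes, classes)
    }
    storage.mode(counts) <- "integer"
  }
  new("ConfusionMatrix", counts = counts)
}

#' SegmenterModel: a fitted ROI segmentation backend
#'
#' @slot backend `"atlas"` or `"learned"`.
#' @slot fit backend-specific fitted state (reference volumes for the atlas
#'   backend; network weights, feature scaling and the training loss history
#'   for the learned backend).
#' @export
setClass("SegmenterModel",
  representation(backend = "character", fit = "list"))

setValidity("SegmenterModel", function(object) {
  if (!object@backend %in% c("atlas", "learned"))
    return("backend must be 'atlas' or 'learned'")
  TRUE
})
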