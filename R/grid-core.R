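.defaultAffine <- function(spacing, origin = c(0, 0, 0)) {
  A <- diag(4)
  A[1:3, 1:3] <- diag(spacing, nrow = 3L)
  A[1:3, 4L] <- origin
  A
}

#' Construct a VolumeGrid
#'
#' @param data 3D numeric array of intensities.
#' @param spacing Numeric voxel size in mm; scalar values are recycled to
#'   all three axes.
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   RAS affine built from `spacing` with origin at voxel (0,0,0).
#' @param phase `"preop"`, `"postop"` or `"unknown"`.
#' @return A [VolumeGrid-class] object.
#' @export
#' @examples
#' v <- VolumeGrid(array(rnorm(8^3), c(8, 8, 8)), spacing = 2)
#' v
VolumeGrid <- function(data, spacing = c(1, 1, 1), affine = NULL,
                       phase = "unknown") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(affine)) affine <- .defaultAffine(spacing)
  new("VolumeGrid", data = data, spacing = as.numeric(spacing),
      affine = affine, phase = phase)
}

#' Construct a MaskGrid
#'
#' @param data 3D array of 0/1 values (logical arrays are coerced).
#' @inheritParams VolumeGrid
#' @return A [MaskGrid-class] object.
#' @export
MaskGrid <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(affine)) affine <- .defaultAffine(spacing)
  storage.mode(data) <- "double"
  new("MaskGrid", data = data, spacing = as.numeric(spacing),
      affine = affine)
}

#' Construct a ProbabilityGrid
#'
#' @param data 3D array of values in \[0, 1\].
#' @inheritParams VolumeGrid
#' @return A [ProbabilityGrid-class] object.
#' @export
ProbabilityGrid <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(affine)) affine <- .defaultAffine(spacing)
  new("ProbabilityGrid", data = data, spacing = as.numeric(spacing),
      affine = affine)
}

#' Construct a GridSpec
#'
#' @param shape Target lattice shape; a scalar is used for all three axes.
#' @param spacing Target isotropic spacing in mm.
#' @param orientation Axis convention; only `"RAS"` is supported.
#' @return A [GridSpec-class] object.
#' @export
#' @examples
#' GridSpec(64)            # desk-scale grid
#' GridSpec()              # clinical 256^3 at 1 mm
GridSpec <- function(shape = 256L, spacing = 1.0, orientation = "RAS") {
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  new("GridSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      orientation = orientation)
}

#' Construct a Slice2D
#'
#' @param data Numeric matrix.
#' @param index 0-based coronal position.
#' @param parentShape Integer length-3 shape of the parent volume.
#' @return A [Slice2D-class] object.
#' @export
Slice2D <- function(data, index, parentShape) {
  new("Slice2D", data = data, index = as.integer(index),
      parentShape = as.integer(parentShape))
}

#' @rdname grid-accessors
#' @export
setMethod("gridData", "ImageGrid", function(x) x@data)

#' @rdname grid-accessors
#' @export
setMethod("voxelSpacing", "ImageGrid", function(x) x@spacing)

#' @rdname grid-accessors
#' @export
setMethod("affine", "ImageGrid", function(x) x@affine)

#' @rdname grid-accessors
#' @export
setMethod("gridShape", "ImageGrid", function(x) dim(x@data))

#' @rdname grid-accessors
#' @export
setMethod("phase", "VolumeGrid", function(x) x@phase)

.showGrid <- function(object, what) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %s mm\n", what,
              d[1L], d[2L], d[3L],
              paste(format(object@spacing, digits = 4), collapse = " x ")))
  cat(sprintf("  orientation: %s\n", .orientationCode(object@affine)))
  rng <- range(object@data)
  cat(sprintf("  value range: [%.4g, %.4g]\n", rng[1L], rng[2L]))
  invisible(NULL)
}

setMethod("show", "VolumeGrid", function(object) {
  .showGrid(object, sprintf("VolumeGrid (%s)", object@phase))
})

setMethod("show", "MaskGrid", function(object) {
  .showGrid(object, "MaskGrid")
  cat(sprintf("  foreground: %d voxels (%.1f mm^3)\n",
              as.integer(sum(object@data)), maskVolume(object)))
})

setMethod("show", "ProbabilityGrid", function(object) {
  .showGrid(object, "ProbabilityGrid")
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %s voxels at %.3g mm (%s)\n",
              paste(object@shape, collapse = " x "), object@spacing,
              object@orientation))
})

setMethod("show", "StudyPair", function(object) {
  cat(sprintf("StudyPair %s\n", object@patientId))
  cat(sprintf("  preop tumor:  %.1f mm^3\n", maskVolume(object@preopMask)))
  cat(sprintf("  postop tumor: %.1f mm^3\n", maskVolume(object@postopMask)))
  if (length(object@truth))
    cat(sprintf("  truth: analytic %.1f mm^3, residual fraction %.3f\n",
                object@truth$analyticVolumeMm3,
                object@truth$residualFraction))
})

setMethod("show", "TrainedModel", function(object) {
  np <- sum(vapply(object@parameters, length, integer(1)))
  cat(sprintf("TrainedModel (%s, fold %d): %d parameters, %d epochs\n",
              object@phase, object@fold, np, nrow(object@history)))
  if (nrow(object@history))
    cat(sprintf("  final training loss: %.5f\n",
                object@history$trainLoss[nrow(object@history)]))
})

setMethod("show", "FoldSplit", function(object) {
  cat(sprintf("FoldSplit: %d patients in %d folds (sizes: %s)\n",
              length(object@assignments), object@k,
              paste(tabulate(object@assignments + 1L, object@k),
                    collapse = ", ")))
})

setMethod("show", "ConfusionReport", function(object) {
  cat("GTR confusion report (positive class: gross total resection)\n")
  cat(sprintf("  counts: TP %d  FN %d  FP %d  TN %d\n",
              object@tp, object@fn, object@fp, object@tn))
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              object@accuracy, object@sensitivity, object@specificity))
  cat(sprintf("  PPV %.2f%%  NPV %.2f%%\n", object@ppv, object@npv))
})
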