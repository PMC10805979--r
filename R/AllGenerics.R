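#' Accessors for voxel-lattice objects
#'
#' `gridData()` returns the raw 3D array, `voxelSpacing()` the per-axis
#' voxel size in mm, `affine()` the 4x4 voxel-to-world matrix,
#' `gridShape()` the lattice dimensions and `phase()` the study phase of a
#' [VolumeGrid].
#'
#' @param x An [ImageGrid] derivative.
#' @return `gridData`: array; `voxelSpacing`: numeric(3); `affine`: 4x4
#'   matrix; `gridShape`: integer(3); `phase`: character scalar.
#' @name grid-accessors
#' @examples
#' v <- VolumeGrid(array(0, c(8, 8, 8)))
#' gridShape(v)
#' voxelSpacing(v)
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridData", function(x) standardGeneric("gridData"))

#' @rdname grid-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname grid-accessors
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))

#' @rdname grid-accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname grid-accessors
#' @export
setGeneric("phase", function(x) standardGeneric("phase"))

#' @rdname reorientRAS
#' @export
setGeneric("reorientRAS", function(x, tol = 1e-4) standardGeneric("reorientRAS"))

#' @rdname resampleIsotropic
#' @export
setGeneric("resampleIsotropic",
  function(x, targetSpacing = 1.0) standardGeneric("resampleIsotropic"))

#' @rdname conformGrid
#' @export
setGeneric("conformGrid", function(x, spec) standardGeneric("conformGrid"))

#' @rdname normalizeIntensity
#' @export
setGeneric("normalizeIntensity", function(x) standardGeneric("normalizeIntensity"))

#' @rdname sliceCoronal
#' @export
setGeneric("sliceCoronal", function(x) standardGeneric("sliceCoronal"))

#' @rdname maskVolume
#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))
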