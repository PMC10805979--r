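#' Read and write NIfTI volumes
#'
#' Thin wrappers around \pkg{RNifti} that move between NIfTI-1 files
#' (`.nii` / `.nii.gz`) and the package's grid classes. Orientation is taken
#' from the file's (s/q-form) affine; conformed volumes are written with
#' their affine stored as both forms.
#'
#' @param path File path.
#' @param phase Study phase tag attached to the returned [VolumeGrid].
#' @return `readVolume`: a [VolumeGrid]; `readMask`: a [MaskGrid] (values
#'   are binarized at 0.5 to absorb interpolation dust in upstream files).
#' @export
readVolume <- function(path, phase = "unknown") {
  img <- RNifti::readNifti(path)
  A <- unclass(RNifti::xform(img))
  attributes(A) <- list(dim = c(4L, 4L))
  data <- array(as.vector(as.array(img)), dim = dim(img))
  if (length(dim(data)) != 3L)
    stop(sprintf("expected a 3D volume, got rank %d", length(dim(data))))
  sp <- RNifti::pixdim(img)[1:3]
  VolumeGrid(data, spacing = sp, affine = A, phase = phase)
}

#' @rdname readVolume
#' @export
readMask <- function(path) {
  v <- readVolume(path)
  MaskGrid((v@data > 0.5) * 1, spacing = v@spacing, affine = v@affine)
}

#' @rdname readVolume
#' @param x A [VolumeGrid], [MaskGrid] or [ProbabilityGrid].
#' @export
writeVolume <- function(x, path) {
  img <- RNifti::asNifti(x@data)
  RNifti::pixdim(img) <- x@spacing
  RNifti::`qform<-`(img, structure(x@affine, code = 2L)) -> img
  RNifti::`sform<-`(img, structure(x@affine, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}
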