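# Postoperative mask cleanup: small residual specks below a size floor are
# discarded, enclosed holes are filled, and a final dilation smooths
# corners towards more natural tumor shapes.

#' Postprocessing configuration constructor
#'
#' @param minComponentVoxels Components smaller than this many voxels are
#'   removed (default 50; one voxel is 1 mm^3 on the canonical grid).
#' @param structuringElement Binary 3D array with odd extents used for
#'   dilation; default a 3x3x3 cube.
#' @param iterations Number of dilation passes (default 1).
#' @return A [PostprocConfig-class].
#' @export
PostprocConfig <- function(minComponentVoxels = 50L,
                           structuringElement = array(1, c(3L, 3L, 3L)),
                           iterations = 1L) {
  new("PostprocConfig", minComponentVoxels = as.integer(minComponentVoxels),
      structuringElement = structuringElement,
      iterations = as.integer(iterations))
}

#' Remove small connected components
#'
#' Deletes every 26-connected foreground component with fewer than
#' `minSize` voxels; components of exactly `minSize` voxels survive.
#'
#' @param mask A [MaskGrid].
#' @param minSize Minimum surviving component size in voxels.
#' @return A [MaskGrid].
#' @export
removeSmallComponents <- function(mask, minSize = 50L) {
  lab <- cpp_label_components(mask@data, 26L)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minSize)
  data <- array(as.numeric(lab %in% keep & lab > 0L), dim(mask@data))
  initialize(mask, data = data)
}

#' Fill enclosed holes
#'
#' Background regions with no 6-connected path to the lattice boundary
#' become foreground; cavities opening onto the boundary are untouched.
#'
#' @param mask A [MaskGrid].
#' @return A [MaskGrid].
#' @export
fillHoles <- function(mask) {
  initialize(mask, data = cpp_fill_holes(mask@data))
}

#' Morphological dilation
#'
#' Dilates the mask by the configured structuring element; the input is
#' always a subset of the output.
#'
#' @param mask A [MaskGrid].
#' @param cfg A [PostprocConfig-class] providing the structuring element
#'   and iteration count.
#' @return A [MaskGrid].
#' @export
dilateMask <- function(mask, cfg = PostprocConfig()) {
  initialize(mask,
             data = cpp_dilate(mask@data, cfg@structuringElement,
                               cfg@iterations))
}

#' Postoperative postprocessing chain
#'
#' Applies, in order: small-component removal, hole filling, dilation.
#' Note that after the final dilation, components may again grow or merge,
#' so a component-size floor is only guaranteed before dilation.
#'
#' @param mask A [MaskGrid].
#' @param cfg A [PostprocConfig-class].
#' @return A [MaskGrid].
#' @export
postprocessPostop <- function(mask, cfg = PostprocConfig()) {
  mask <- removeSmallComponents(mask, cfg@minComponentVoxels)
  mask <- fillHoles(mask)
  dilateMask(mask, cfg)
}
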