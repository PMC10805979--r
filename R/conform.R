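# Axis-dominance decomposition of the 3x3 direction part of an affine:
# for each voxel axis, the world axis it mostly points along and the sign.
# Rejects oblique acquisitions whose off-dominant components exceed tol
# relative to the dominant one.
.axisDominance <- function(A, tol = 1e-4) {
  D <- A[1:3, 1:3, drop = FALSE]
  if (abs(det(D)) < 1e-12)
    stop("orientation matrix is not invertible")
  m <- integer(3L)
  s <- numeric(3L)
  for (j in 1:3) {
    col <- D[, j]
    m[j] <- which.max(abs(col))
    s[j] <- sign(col[m[j]])
    if (any(abs(col[-m[j]]) > tol * abs(col[m[j]])))
      stop(sprintf(
        "oblique orientation: voxel axis %d deviates from world axis %d beyond tolerance %g",
        j, m[j], tol))
  }
  if (!setequal(m, 1:3))
    stop("orientation is not axis-dominant: two voxel axes map to one world axis")
  list(m = m, s = s)
}

.orientationCode <- function(A) {
  ax <- tryCatch(.axisDominance(A, tol = Inf), error = function(e) NULL)
  if (is.null(ax)) return("??")
  pos <- c("R", "A", "S")
  neg <- c("L", "P", "I")
  paste(vapply(1:3, function(j)
    if (ax$s[j] > 0) pos[ax$m[j]] else neg[ax$m[j]], character(1)),
    collapse = "")
}

.flipAxis <- function(data, j) {
  idx <- list(TRUE, TRUE, TRUE)
  idx[[j]] <- rev(seq_len(dim(data)[j]))
  do.call(`[`, c(list(data), idx, list(drop = FALSE)))
}

.reorientCore <- function(x, tol) {
  A <- x@affine
  ax <- .axisDominance(A, tol)
  data <- x@data
  d <- dim(data)
  for (j in 1:3) {
    if (ax$s[j] < 0) {
      data <- .flipAxis(data, j)
      A[1:3, 4L] <- A[1:3, 4L] + A[1:3, j] * (d[j] - 1L)
      A[1:3, j] <- -A[1:3, j]
    }
  }
  perm <- order(ax$m)
  if (!identical(perm, 1:3)) {
    data <- aperm(data, perm)
    A[1:3, 1:3] <- A[1:3, perm, drop = FALSE]
  }
  list(data = data, affine = A, spacing = x@spacing[perm])
}

#' Reorient a volume or mask to RAS
#'
#' Permutes and flips the voxel axes so that they increase towards the
#' Right, Anterior and Superior world directions, updating the affine so
#' that the world coordinate of every voxel is unchanged. Only
#' axis-dominant (non-oblique) orientations are accepted.
#'
#' @param x A [VolumeGrid] or [MaskGrid].
#' @param tol Relative tolerance on off-dominant direction components
#'   before an orientation is rejected as oblique.
#' @return An object of the same class in RAS orientation.
#' @export
#' @name reorientRAS
#' @examples
#' v <- VolumeGrid(array(rnorm(8^3), c(8, 8, 8)))
#' identical(gridData(reorientRAS(v)), gridData(v))  # already RAS
setMethod("reorientRAS", "VolumeGrid", function(x, tol = 1e-4) {
  r <- .reorientCore(x, tol)
  new("VolumeGrid", data = r$data, spacing = r$spacing, affine = r$affine,
      phase = x@phase)
})

#' @rdname reorientRAS
#' @export
setMethod("reorientRAS", "MaskGrid", function(x, tol = 1e-4) {
  r <- .reorientCore(x, tol)
  new("MaskGrid", data = r$data, spacing = r$spacing, affine = r$affine)
})

.resampleCore <- function(x, targetSpacing, linear) {
  stopifnot(targetSpacing > 0)
  d <- dim(x@data)
  if (any(d < 2L))
    stop("cannot resample a degenerate volume (an axis has fewer than 2 voxels)")
  newShape <- pmax(2L, as.integer(round(d * x@spacing / targetSpacing)))
  # voxel 0 stays put; new index i samples old coordinate i * t / s
  scale <- targetSpacing / x@spacing
  data <- cpp_resample3d(x@data, newShape, scale, linear)
  A <- x@affine
  for (j in 1:3) A[1:3, j] <- A[1:3, j] * scale[j]
  list(data = data, affine = A, spacing = rep(targetSpacing, 3L))
}

#' Resample to isotropic voxel spacing
#'
#' Resamples onto an isotropic lattice of the requested spacing, preserving
#' the physical field of view to within one voxel per axis. Images are
#' interpolated trilinearly; masks use nearest-neighbour interpolation so
#' labels stay binary.
#'
#' @param x A [VolumeGrid] or [MaskGrid].
#' @param targetSpacing Target isotropic voxel size in mm (default 1.0).
#' @return An object of the same class with spacing
#'   `c(targetSpacing, targetSpacing, targetSpacing)`.
#' @export
#' @name resampleIsotropic
setMethod("resampleIsotropic", "VolumeGrid", function(x, targetSpacing = 1.0) {
  r <- .resampleCore(x, targetSpacing, linear = TRUE)
  new("VolumeGrid", data = r$data, spacing = r$spacing, affine = r$affine,
      phase = x@phase)
})

#' @rdname resampleIsotropic
#' @export
setMethod("resampleIsotropic", "MaskGrid", function(x, targetSpacing = 1.0) {
  r <- .resampleCore(x, targetSpacing, linear = FALSE)
  new("MaskGrid", data = r$data, spacing = r$spacing, affine = r$affine)
})

.conformCore <- function(x, spec, padValue) {
  if (any(abs(x@spacing - spec@spacing) > 1e-6))
    stop("volume must be isotropic at the target spacing before conforming; run resampleIsotropic() first")
  d <- dim(x@data)
  N <- spec@shape
  # per-axis source window and destination offset; the odd extra voxel goes
  # to the high-index side for padding and is removed from the high side
  # when cropping
  srcStart <- integer(3L); take <- integer(3L); dstStart <- integer(3L)
  for (j in 1:3) {
    if (d[j] >= N[j]) {
      srcStart[j] <- (d[j] - N[j]) %/% 2L
      take[j] <- N[j]
      dstStart[j] <- 0L
    } else {
      srcStart[j] <- 0L
      take[j] <- d[j]
      dstStart[j] <- (N[j] - d[j]) %/% 2L
    }
  }
  out <- array(padValue, dim = N)
  out[dstStart[1L] + seq_len(take[1L]),
      dstStart[2L] + seq_len(take[2L]),
      dstStart[3L] + seq_len(take[3L])] <-
    x@data[srcStart[1L] + seq_len(take[1L]),
           srcStart[2L] + seq_len(take[2L]),
           srcStart[3L] + seq_len(take[3L]), drop = FALSE]
  A <- x@affine
  A[1:3, 4L] <- A[1:3, 4L] + A[1:3, 1:3] %*% (srcStart - dstStart)
  list(data = out, affine = A)
}

#' Conform a volume to a canonical grid shape
#'
#' Center-crops and/or symmetrically pads an (already isotropic) volume to
#' the shape of a [GridSpec]. Images are padded with their minimum
#' intensity, masks with 0. An odd leftover voxel is placed at the
#' high-index side.
#'
#' @param x A [VolumeGrid] or [MaskGrid], isotropic at `spec@spacing`.
#' @param spec A [GridSpec].
#' @return An object of the same class with shape `spec@shape`.
#' @export
#' @name conformGrid
setMethod("conformGrid", signature("VolumeGrid", "GridSpec"),
  function(x, spec) {
    r <- .conformCore(x, spec, padValue = min(x@data))
    new("VolumeGrid", data = r$data, spacing = x@spacing, affine = r$affine,
        phase = x@phase)
  })

#' @rdname conformGrid
#' @export
setMethod("conformGrid", signature("MaskGrid", "GridSpec"),
  function(x, spec) {
    r <- .conformCore(x, spec, padValue = 0)
    new("MaskGrid", data = r$data, spacing = x@spacing, affine = r$affine)
  })

#' Per-study intensity normalization
#'
#' Z-scores the whole volume (mean 0, unit standard deviation), the
#' standard per-study normalization for CNN inputs; it is invariant to
#' positive affine intensity rescaling. Constant volumes map to all zeros.
#'
#' @param x A [VolumeGrid].
#' @return A [VolumeGrid] with normalized intensities.
#' @export
#' @name normalizeIntensity
setMethod("normalizeIntensity", "VolumeGrid", function(x) {
  mu <- mean(x@data)
  sdv <- sd(as.vector(x@data))
  data <- if (!is.finite(sdv) || sdv < 1e-12) {
    array(0, dim(x@data))
  } else {
    (x@data - mu) / sdv
  }
  new("VolumeGrid", data = data, spacing = x@spacing, affine = x@affine,
      phase = x@phase)
})

.assertRAS <- function(x) {
  code <- .orientationCode(x@affine)
  if (!identical(code, "RAS"))
    stop(sprintf("volume must be in RAS orientation (found %s); run reorientRAS() first", code))
  invisible(TRUE)
}

#' Split a RAS volume into coronal slices
#'
#' Extracts one [Slice2D] per position along the anterior-posterior (second
#' RAS) axis, in ascending order. `stackCoronal()` inverts the operation
#' voxel-exactly.
#'
#' @param x A [VolumeGrid] or [MaskGrid] in RAS orientation.
#' @return A list of [Slice2D] objects of length `gridShape(x)[2]`.
#' @export
#' @name sliceCoronal
setMethod("sliceCoronal", "ImageGrid", function(x) {
  .assertRAS(x)
  d <- dim(x@data)
  lapply(seq_len(d[2L]), function(k)
    Slice2D(x@data[, k, , drop = TRUE], index = k - 1L, parentShape = d))
})

#' Rebuild a volume from coronal slices
#'
#' @param slices List of [Slice2D] covering every coronal index of one
#'   parent shape exactly once.
#' @param template Optional [VolumeGrid]/[MaskGrid] supplying spacing,
#'   affine and phase for the result; defaults to unit spacing.
#' @return A [VolumeGrid] (or an object of `class(template)`).
#' @export
stackCoronal <- function(slices, template = NULL) {
  stopifnot(length(slices) > 0L)
  ps <- slices[[1L]]@parentShape
  idx <- vapply(slices, function(s) s@index, integer(1))
  if (!setequal(idx, 0:(ps[2L] - 1L)) || length(idx) != ps[2L])
    stop("slices must cover every coronal index exactly once")
  data <- array(0, dim = ps)
  for (s in slices) data[, s@index + 1L, ] <- s@data
  if (is.null(template))
    return(VolumeGrid(data))
  if (is(template, "MaskGrid"))
    new("MaskGrid", data = data, spacing = template@spacing,
        affine = template@affine)
  else
    new("VolumeGrid", data = data, spacing = template@spacing,
        affine = template@affine, phase = template@phase)
}

#' Full preprocessing chain to the canonical grid
#'
#' Applies, in order: RAS reorientation, isotropic resampling, grid
#' conformation and (for images) per-study z-score normalization. The
#' chain is deterministic: identical inputs give identical outputs.
#'
#' @param x A [VolumeGrid] or [MaskGrid].
#' @param spec Target [GridSpec] (default: clinical 256^3 at 1 mm).
#' @param normalize Normalize intensities (ignored for masks).
#' @return The conformed object.
#' @export
preprocessVolume <- function(x, spec = GridSpec(), normalize = TRUE) {
  x <- reorientRAS(x)
  x <- resampleIsotropic(x, spec@spacing)
  x <- conformGrid(x, spec)
  if (normalize && is(x, "VolumeGrid")) x <- normalizeIntensity(x)
  x
}
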