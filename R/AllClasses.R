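#' @import methods
#' @importFrom stats sd quantile rnorm runif cor median IQR setNames
#' @importFrom utils read.csv write.csv
#' @useDynLib AdenoVol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.PHASES <- c("preop", "postop", "unknown")

#' Virtual parent of all voxel-lattice classes
#'
#' An `ImageGrid` couples a rank-3 voxel lattice with its geometry: per-axis
#' voxel spacing in millimetres and a 4x4 affine mapping 0-based voxel
#' indices to world coordinates (mm).
#'
#' @slot data 3D numeric array of voxel values.
#' @slot spacing Numeric length-3, voxel edge lengths in mm (all > 0).
#' @slot affine 4x4 voxel-index-to-world matrix (invertible).
#' @name ImageGrid-class
#' @aliases ImageGrid
#' @exportClass ImageGrid
setClass("ImageGrid",
  representation("VIRTUAL", data = "array", spacing = "numeric",
                 affine = "matrix"))

setValidity("ImageGrid", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a rank-3 array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  else if (abs(det(object@affine[1:3, 1:3])) < 1e-12)
    msg <- c(msg, "affine orientation matrix must be invertible")
  if (length(msg)) msg else TRUE
})

#' Scalar MRI volume on a voxel lattice
#'
#' The canonical intermediate of every pipeline stage: a T1-weighted
#' (typically contrast-enhanced) intensity volume with voxel geometry and a
#' study phase tag (`"preop"`, `"postop"` or `"unknown"`).
#'
#' @slot phase Character scalar, one of `"preop"`, `"postop"`, `"unknown"`.
#' @seealso [MaskGrid], [reorientRAS], [resampleIsotropic], [conformGrid]
#' @name VolumeGrid-class
#' @aliases VolumeGrid-class
#' @exportClass VolumeGrid
setClass("VolumeGrid", contains = "ImageGrid",
  representation(phase = "character"),
  prototype(phase = "unknown"))

setValidity("VolumeGrid", function(object) {
  if (length(object@phase) != 1L || !object@phase %in% .PHASES)
    sprintf("phase must be one of %s", paste(.PHASES, collapse = ", "))
  else TRUE
})

#' Binary segmentation mask on a voxel lattice
#'
#' Values are restricted to 0/1; the carrier of all volumetry.
#'
#' @seealso [maskVolume], [diceScore], [postprocessPostop]
#' @name MaskGrid-class
#' @aliases MaskGrid-class
#' @exportClass MaskGrid
setClass("MaskGrid", contains = "ImageGrid")

setValidity("MaskGrid", function(object) {
  if (!all(object@data %in% c(0, 1)))
    "mask values must all be 0 or 1"
  else TRUE
})

#' Per-voxel foreground probability grid
#'
#' The unthresholded output of (ensemble) network inference; every value
#' lies in \[0, 1\].
#'
#' @seealso [predictVolume], [ensembleAverage], [binarize]
#' @name ProbabilityGrid-class
#' @aliases ProbabilityGrid-class
#' @exportClass ProbabilityGrid
setClass("ProbabilityGrid", contains = "ImageGrid")

setValidity("ProbabilityGrid", function(object) {
  if (any(object@data < 0 | object@data > 1, na.rm = TRUE))
    "probabilities must lie in [0, 1]"
  else TRUE
})

#' A single coronal slice
#'
#' One 2D plane extracted perpendicular to the anterior-posterior axis of a
#' RAS-oriented volume, retaining its (0-based) coronal position and the
#' shape of the parent lattice so stacks can be rebuilt losslessly.
#'
#' @slot data Numeric matrix (right-left by superior-inferior extent).
#' @slot index Integer 0-based coronal position in the parent volume.
#' @slot parentShape Integer length-3 shape of the parent lattice.
#' @name Slice2D-class
#' @aliases Slice2D-class
#' @exportClass Slice2D
setClass("Slice2D",
  representation(data = "matrix", index = "integer",
                 parentShape = "integer"))

setValidity("Slice2D", function(object) {
  msg <- character()
  if (length(object@parentShape) != 3L)
    msg <- c(msg, "parentShape must have length 3")
  else {
    if (object@index < 0L || object@index >= object@parentShape[2L])
      msg <- c(msg, "index must satisfy 0 <= index < coronal extent")
    if (!all(dim(object@data) == object@parentShape[c(1L, 3L)]))
      msg <- c(msg, "slice shape must match parent right/superior extents")
  }
  if (length(msg)) msg else TRUE
})

#' Canonical grid specification
#'
#' Target lattice for grid conformation: shape, isotropic spacing and axis
#' convention. The clinical default is 256^3 voxels at 1.0 mm in RAS
#' orientation; smaller grids (e.g. 64^3) run the identical code paths at
#' desk scale.
#'
#' @slot shape Integer length-3 target shape (each entry >= 8).
#' @slot spacing Numeric scalar, target isotropic spacing in mm (> 0).
#' @slot orientation Character axis convention; only `"RAS"` is supported.
#' @name GridSpec-class
#' @aliases GridSpec-class
#' @exportClass GridSpec
setClass("GridSpec",
  representation(shape = "integer", spacing = "numeric",
                 orientation = "character"),
  prototype(shape = rep(256L, 3L), spacing = 1.0, orientation = "RAS"))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 8L))
    msg <- c(msg, "shape must be 3 integers, each >= 8")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive value")
  if (!identical(object@orientation, "RAS"))
    msg <- c(msg, "only RAS orientation is supported")
  if (length(msg)) msg else TRUE
})

#' One patient's pre/postoperative study bundle
#'
#' Links the preoperative and (3-month) postoperative image+mask pairs of a
#' patient, plus ground-truth bookkeeping for synthetic phantoms (analytic
#' preoperative volume in mm^3 and the simulated residual fraction).
#'
#' @slot patientId Character identifier.
#' @slot preopImage,postopImage [VolumeGrid] intensity volumes.
#' @slot preopMask,postopMask [MaskGrid] tumor masks on the same lattices.
#' @slot truth Named list; for phantoms holds `analyticVolumeMm3`,
#'   `residualFraction` and generator metadata (empty for clinical data).
#' @name StudyPair-class
#' @aliases StudyPair-class
#' @exportClass StudyPair
setClass("StudyPair",
  representation(patientId = "character",
                 preopImage = "VolumeGrid", preopMask = "MaskGrid",
                 postopImage = "VolumeGrid", postopMask = "MaskGrid",
                 truth = "list"))

setValidity("StudyPair", function(object) {
  msg <- character()
  if (length(object@patientId) != 1L || !nzchar(object@patientId))
    msg <- c(msg, "patientId must be a nonempty string")
  dpre <- dim(object@preopImage@data)
  if (!identical(dpre, dim(object@preopMask@data)) ||
      !identical(dpre, dim(object@postopImage@data)) ||
      !identical(dpre, dim(object@postopMask@data)))
    msg <- c(msg, "all four lattices must share one shape")
  if (sum(object@preopMask@data) < 1)
    msg <- c(msg, "preoperative mask must be nonempty")
  if (any(object@postopMask@data > object@preopMask@data))
    msg <- c(msg, "postoperative mask must be a subset of the preoperative mask")
  if (length(msg)) msg else TRUE
})

#' Phantom generator configuration
#'
#' Study conditions for the synthetic sellar phantom cohort: a noisy
#' low-frequency background carrying a contrast-enhancing tumor built from
#' 1-3 overlapping ellipsoids, and a simulated resection leaving a connected
#' residual of a prescribed volume fraction.
#'
#' @slot grid [GridSpec] lattice on which phantoms are generated.
#' @slot tumorRadiiRange Numeric length-2, ellipsoid semi-axis range in mm.
#' @slot lobeRange Integer length-2, range of the number of ellipsoid lobes.
#' @slot centerJitter Numeric, mm of uniform jitter of lobe centers.
#' @slot tumorContrast Numeric, mean intensity offset of tumor vs background.
#' @slot noiseSd Numeric, standard deviation of additive Gaussian noise.
#' @slot residualFractionRange Numeric length-2 in \[0,1\]: residual tumor
#'   volume fraction drawn for non-GTR cases.
#' @slot seed Integer master seed; all phantom randomness derives from it.
#' @name PhantomConfig-class
#' @aliases PhantomConfig-class
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(grid = "GridSpec", tumorRadiiRange = "numeric",
                 lobeRange = "integer", centerJitter = "numeric",
                 tumorContrast = "numeric", noiseSd = "numeric",
                 residualFractionRange = "numeric", seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@tumorRadiiRange) != 2L ||
      any(object@tumorRadiiRange <= 0) ||
      diff(object@tumorRadiiRange) < 0)
    msg <- c(msg, "tumorRadiiRange must be an increasing positive pair")
  fov <- min(object@grid@shape) * object@grid@spacing
  if (2 * max(object@tumorRadiiRange) > fov)
    msg <- c(msg, "largest tumor diameter exceeds the grid field of view")
  if (length(object@lobeRange) != 2L || object@lobeRange[1L] < 1L ||
      diff(object@lobeRange) < 0)
    msg <- c(msg, "lobeRange must be an increasing pair with min >= 1")
  if (length(object@residualFractionRange) != 2L ||
      any(object@residualFractionRange < 0) ||
      any(object@residualFractionRange > 1) ||
      diff(object@residualFractionRange) < 0)
    msg <- c(msg, "residualFractionRange must be increasing within [0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@centerJitter < 0) msg <- c(msg, "centerJitter must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Training configuration for the slice-wise U-Net
#'
#' The loss is binary cross-entropy, the optimizer Adam and the final
#' activation a sigmoid; those are fixed. Architecture size and optimization
#' schedule are configurable with desk-scale defaults.
#'
#' @slot folds Integer k for k-fold cross-validation (>= 2).
#' @slot epochs Integer >= 1.
#' @slot batchSize Integer >= 1.
#' @slot learningRate Numeric Adam step size.
#' @slot baseFilters Integer channels of the first encoder level.
#' @slot depth Integer number of resolution levels (>= 2); each level beyond
#'   the first halves the slice resolution, so slices must be divisible by
#'   2^(depth-1).
#' @slot seed Integer master seed fanned out to fold split, weight
#'   initialization, shuffling and augmentation.
#' @name TrainConfig-class
#' @aliases TrainConfig-class
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(folds = "integer", epochs = "integer",
                 batchSize = "integer", learningRate = "numeric",
                 baseFilters = "integer", depth = "integer",
                 seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@folds < 2L) msg <- c(msg, "folds must be >= 2")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@depth < 2L) msg <- c(msg, "depth must be >= 2")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@baseFilters < 1L) msg <- c(msg, "baseFilters must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Augmentation configuration
#'
#' A random rotation in \[0, 90\] degrees combined with a zoom-in of 0-30%
#' is applied to a `samplingRatio` fraction of training slices (image
#' bilinear, mask nearest-neighbour, identical transform for both).
#'
#' @slot rotationRange Numeric length-2 degrees within \[0, 90\].
#' @slot zoomRange Numeric length-2 zoom fractions within \[0, 0.30\].
#' @slot samplingRatio Numeric in (0, 1\]: fraction of slices augmented.
#' @slot enabled Logical switch.
#' @name AugmentConfig-class
#' @aliases AugmentConfig-class
#' @exportClass AugmentConfig
setClass("AugmentConfig",
  representation(rotationRange = "numeric", zoomRange = "numeric",
                 samplingRatio = "numeric", enabled = "logical"))

setValidity("AugmentConfig", function(object) {
  msg <- character()
  if (length(object@rotationRange) != 2L ||
      any(object@rotationRange < 0) || any(object@rotationRange > 90) ||
      diff(object@rotationRange) < 0)
    msg <- c(msg, "rotationRange must be increasing within [0, 90] degrees")
  if (length(object@zoomRange) != 2L || any(object@zoomRange < 0) ||
      any(object@zoomRange > 0.30) || diff(object@zoomRange) < 0)
    msg <- c(msg, "zoomRange must be increasing within [0, 0.30]")
  if (object@samplingRatio <= 0 || object@samplingRatio > 1)
    msg <- c(msg, "samplingRatio must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Patient-level fold assignment
#'
#' Maps each patient id to one fold index in `0:(k-1)`; both scans of a
#' patient always share a fold. Fold sizes differ by at most one.
#'
#' @slot assignments Named integer vector, names = patient ids, values in
#'   `0:(k-1)`.
#' @slot k Integer number of folds.
#' @name FoldSplit-class
#' @aliases FoldSplit-class
#' @exportClass FoldSplit
setClass("FoldSplit",
  representation(assignments = "integer", k = "integer"))

setValidity("FoldSplit", function(object) {
  msg <- character()
  if (is.null(names(object@assignments)) ||
      anyDuplicated(names(object@assignments)))
    msg <- c(msg, "assignments must be uniquely named by patient id")
  if (any(object@assignments < 0L) || any(object@assignments >= object@k))
    msg <- c(msg, "fold indices must lie in 0:(k-1)")
  sizes <- tabulate(object@assignments + 1L, nbins = object@k)
  if (length(sizes) && diff(range(sizes)) > 1L)
    msg <- c(msg, "fold sizes must differ by at most one")
  if (length(msg)) msg else TRUE
})

#' A trained slice-wise segmentation network
#'
#' Opaque learned parameters plus provenance: study phase, fold index and
#' per-epoch loss history. Predictions pass through a final sigmoid and so
#' lie in \[0, 1\].
#'
#' @slot parameters Named list of weight arrays.
#' @slot phase `"preop"` or `"postop"`.
#' @slot fold Integer fold index (0-based; -1 when trained outside CV).
#' @slot history data.frame with one row per epoch (`epoch`, `trainLoss`,
#'   `valLoss`).
#' @slot config The [TrainConfig] used.
#' @name TrainedModel-class
#' @aliases TrainedModel-class
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(parameters = "list", phase = "character",
                 fold = "integer", history = "data.frame",
                 config = "TrainConfig"))

#' Ensemble inference configuration
#'
#' Probability cutoffs used to binarize ensemble-averaged predictions:
#' 0.6 for preoperative and 0.44 for postoperative scans.
#'
#' @slot thresholdPreop,thresholdPostop Numeric cutoffs in (0, 1).
#' @name EnsembleConfig-class
#' @aliases EnsembleConfig-class
#' @exportClass EnsembleConfig
setClass("EnsembleConfig",
  representation(thresholdPreop = "numeric", thresholdPostop = "numeric"),
  prototype(thresholdPreop = 0.6, thresholdPostop = 0.44))

setValidity("EnsembleConfig", function(object) {
  ok <- function(t) length(t) == 1L && t > 0 && t < 1
  if (!ok(object@thresholdPreop) || !ok(object@thresholdPostop))
    "thresholds must be single values strictly inside (0, 1)"
  else TRUE
})

#' Postoperative mask postprocessing configuration
#'
#' Connected components (26-neighbourhood) smaller than
#' `minComponentVoxels` are removed, enclosed holes (background regions with
#' no 6-connected path to the lattice boundary) are filled, and the mask is
#' dilated by the structuring element to smooth corners.
#'
#' @slot minComponentVoxels Integer >= 1 (default 50).
#' @slot structuringElement Binary 3D array, odd-sized; default 3x3x3 cube.
#' @slot iterations Integer number of dilation passes (default 1).
#' @name PostprocConfig-class
#' @aliases PostprocConfig-class
#' @exportClass PostprocConfig
setClass("PostprocConfig",
  representation(minComponentVoxels = "integer",
                 structuringElement = "array", iterations = "integer"))

setValidity("PostprocConfig", function(object) {
  msg <- character()
  if (object@minComponentVoxels < 1L)
    msg <- c(msg, "minComponentVoxels must be >= 1")
  d <- dim(object@structuringElement)
  if (length(d) != 3L || any(d %% 2L == 0L))
    msg <- c(msg, "structuringElement must be a 3D array with odd extents")
  if (!all(object@structuringElement %in% c(0, 1)))
    msg <- c(msg, "structuringElement must be binary")
  if (object@iterations < 1L) msg <- c(msg, "iterations must be >= 1")
  if (length(msg)) msg else TRUE
})

#' GTR confusion statistics
#'
#' Counts of a 2x2 confusion matrix for gross-total-resection detection
#' (positive class: GTR present) and the derived rates in percent.
#' Rates with zero denominators are `NaN`.
#'
#' @slot tp,fn,fp,tn Integer counts.
#' @slot accuracy,sensitivity,specificity,ppv,npv Numeric percent.
#' @name ConfusionReport-class
#' @aliases ConfusionReport-class
#' @exportClass ConfusionReport
setClass("ConfusionReport",
  representation(tp = "integer", fn = "integer", fp = "integer",
                 tn = "integer", accuracy = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 ppv = "numeric", npv = "numeric"))
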