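#' Ensemble inference configuration constructor
#'
#' @param thresholdPreop Probability cutoff for preoperative scans
#'   (default 0.6).
#' @param thresholdPostop Probability cutoff for postoperative scans
#'   (default 0.44).
#' @return An [EnsembleConfig-class].
#' @export
EnsembleConfig <- function(thresholdPreop = 0.6, thresholdPostop = 0.44) {
  new("EnsembleConfig", thresholdPreop = thresholdPreop,
      thresholdPostop = thresholdPostop)
}

#' Slice-wise prediction of a full volume
#'
#' Runs the model over every coronal slice of a conformed, normalized
#' volume and restacks the per-slice sigmoid outputs into a
#' [ProbabilityGrid] of the same shape.
#'
#' @param model A [TrainedModel-class].
#' @param vol A [VolumeGrid] on the canonical grid (RAS, normalized).
#' @return A [ProbabilityGrid].
#' @export
predictVolume <- function(model, vol) {
  .assertRAS(vol)
  d <- dim(vol@data)
  .checkSliceShape(array(0, c(d[1L], d[3L], 1L)), model@config@depth)
  # coronal slices are [R, S] planes indexed along A
  x <- aperm(vol@data, c(1L, 3L, 2L))
  probs <- .predictArray(model@parameters, x, model@config@depth)
  ProbabilityGrid(aperm(probs, c(1L, 3L, 2L)), spacing = vol@spacing,
                  affine = vol@affine)
}

#' Average fold predictions into an ensemble probability grid
#'
#' Voxel-wise unweighted arithmetic mean of two or more probability grids
#' on one lattice.
#'
#' @param probs List of [ProbabilityGrid] objects of identical shape.
#' @return A [ProbabilityGrid].
#' @export
ensembleAverage <- function(probs) {
  stopifnot(length(probs) >= 1L)
  d <- dim(probs[[1L]]@data)
  acc <- array(0, d)
  for (p in probs) {
    if (!identical(dim(p@data), d))
      stop("probability grids must share one shape")
    acc <- acc + p@data
  }
  ProbabilityGrid(acc / length(probs), spacing = probs[[1L]]@spacing,
                  affine = probs[[1L]]@affine)
}

#' Threshold a probability grid into a binary mask
#'
#' A voxel becomes foreground iff its probability is greater than or equal
#' to the threshold (ties count as foreground).
#'
#' @param prob A [ProbabilityGrid].
#' @param threshold Cutoff strictly inside (0, 1).
#' @return A [MaskGrid].
#' @export
binarize <- function(prob, threshold) {
  stopifnot(length(threshold) == 1L, threshold > 0, threshold < 1)
  MaskGrid((prob@data >= threshold) * 1, spacing = prob@spacing,
           affine = prob@affine)
}

#' End-to-end segmentation of one study phase
#'
#' Slice-wise prediction with every fold model, ensemble averaging, and
#' phase-appropriate thresholding (0.6 preop / 0.44 postop by default).
#' Postoperative masks additionally pass through
#' [postprocessPostop()]; preoperative masks do not.
#'
#' @param models List of [TrainedModel-class] fold models.
#' @param vol Conformed, normalized [VolumeGrid].
#' @param phase `"preop"` or `"postop"`; defaults to `phase(vol)`.
#' @param ensembleCfg An [EnsembleConfig-class].
#' @param postprocCfg A [PostprocConfig-class] (postop only).
#' @return `list(mask = MaskGrid, probability = ProbabilityGrid)`.
#' @export
segmentStudy <- function(models, vol, phase = NULL,
                         ensembleCfg = EnsembleConfig(),
                         postprocCfg = PostprocConfig()) {
  if (is.null(phase)) phase <- vol@phase
  if (!phase %in% c("preop", "postop"))
    stop("phase must be preop or postop")
  prob <- ensembleAverage(lapply(models, predictVolume, vol = vol))
  thr <- if (phase == "preop") ensembleCfg@thresholdPreop
         else ensembleCfg@thresholdPostop
  mask <- binarize(prob, thr)
  if (phase == "postop") mask <- postprocessPostop(mask, postprocCfg)
  list(mask = mask, probability = prob)
}
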