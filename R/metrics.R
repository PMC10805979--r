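# Segmentation similarity metrics with explicit empty-mask conventions.
#
# Empty-mask policy: when both masks are empty, dice = jaccard = 1 and
# hd95 = 0 by default (perfect agreement); `bothEmpty = 0` scores such
# pairs 0 instead, for compatibility with scoring schemes that treat empty
# predictions as failures. When exactly one mask is empty, dice = jaccard
# = 0 and hd95 is NaN (the distance to an empty surface is undefined).

.checkSameShape <- function(a, b) {
  if (!identical(dim(a@data), dim(b@data)))
    stop("masks must share one shape")
  invisible(TRUE)
}

#' Dice overlap score
#'
#' `2|A n B| / (|A| + |B|)`: 1 for perfect congruence, 0 for no overlap.
#'
#' @param a,b [MaskGrid] objects of identical shape.
#' @param bothEmpty Score assigned when both masks are empty (default 1).
#' @return Numeric in \[0, 1\].
#' @export
#' @examples
#' m <- array(0, c(4, 4, 4)); m[1:2, 1, 1] <- 1
#' diceScore(MaskGrid(m), MaskGrid(m))
diceScore <- function(a, b, bothEmpty = 1) {
  .checkSameShape(a, b)
  na <- sum(a@data)
  nb <- sum(b@data)
  if (na == 0 && nb == 0) return(bothEmpty)
  2 * sum(a@data * b@data) / (na + nb)
}

#' Jaccard overlap score
#'
#' `|A n B| / |A u B|`; related to Dice by `J = D / (2 - D)`.
#'
#' @inheritParams diceScore
#' @return Numeric in \[0, 1\].
#' @export
jaccardScore <- function(a, b, bothEmpty = 1) {
  .checkSameShape(a, b)
  inter <- sum(a@data * b@data)
  uni <- sum(pmax(a@data, b@data))
  if (uni == 0) return(bothEmpty)
  inter / uni
}

#' 95th percentile Hausdorff distance
#'
#' The maximum of the two directed 95th-percentile surface distances, in
#' mm. Surfaces are foreground voxels with at least one background
#' 6-neighbour (the lattice border counts as background); distances are
#' Euclidean in world units and percentiles use the linear-interpolation
#' quantile. Identical masks give 0; exactly one empty mask gives NaN;
#' two empty masks give 0.
#'
#' @param a,b [MaskGrid] objects of identical shape and spacing.
#' @param probs Percentile as a fraction (default 0.95).
#' @return Distance in mm (>= 0), or NaN.
#' @export
hd95 <- function(a, b, probs = 0.95) {
  .checkSameShape(a, b)
  if (any(abs(a@spacing - b@spacing) > 1e-9))
    stop("masks must share voxel spacing")
  na <- sum(a@data)
  nb <- sum(b@data)
  if (na == 0 && nb == 0) return(0)
  if (na == 0 || nb == 0) return(NaN)
  sa <- cpp_surface_voxels(a@data)
  sb <- cpp_surface_voxels(b@data)
  dab <- cpp_min_distances(sa, sb, a@spacing)
  dba <- cpp_min_distances(sb, sa, a@spacing)
  max(quantile(dab, probs, names = FALSE, type = 7),
      quantile(dba, probs, names = FALSE, type = 7))
}

#' Per-case segmentation metric report
#'
#' @param pred,truth [MaskGrid] objects on one lattice.
#' @param bothEmpty Both-empty convention passed to the overlap scores
#'   (hd95 scores both-empty pairs 0 regardless).
#' @return One-row `data.frame` with columns `dice`, `jaccard`, `hd95_mm`.
#' @export
evaluateSegmentation <- function(pred, truth, bothEmpty = 1) {
  data.frame(dice = diceScore(pred, truth, bothEmpty),
             jaccard = jaccardScore(pred, truth, bothEmpty),
             hd95_mm = hd95(pred, truth))
}

#' Aggregate metric summaries
#'
#' Mean +/- SD and median (IQR) per metric column. `naRm = FALSE`
#' propagates NaN (an all-empty-prediction cohort then reports NaN), while
#' `naRm = TRUE` summarizes the defined cases only; both modes are
#' exposed because aggregate tables differ between the two readings.
#'
#' @param metrics data.frame of rows from [evaluateSegmentation()].
#' @param naRm Drop undefined (NaN) values before summarizing.
#' @return data.frame with one row per metric: mean, sd, median, iqr, nNA.
#' @export
summarizeMetrics <- function(metrics, naRm = FALSE) {
  cols <- intersect(c("dice", "jaccard", "hd95_mm"), names(metrics))
  do.call(rbind, lapply(cols, function(cn) {
    v <- metrics[[cn]]
    blocked <- !naRm && anyNA(v)  # stats::quantile refuses NaN otherwise
    data.frame(metric = cn,
               mean = mean(v, na.rm = naRm), sd = sd(v, na.rm = naRm),
               median = if (blocked) NaN else median(v, na.rm = naRm),
               iqr = if (blocked) NaN else IQR(v, na.rm = naRm),
               nNA = sum(is.na(v)))
  }))
}
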