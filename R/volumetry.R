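# Volume, extent-of-resection and gross-total-resection assessment.

#' Mask volume in cubic millimetres
#'
#' Foreground voxel count times the voxel volume (product of spacings).
#'
#' @param x A [MaskGrid].
#' @return Volume in mm^3.
#' @export
#' @name maskVolume
#' @examples
#' m <- array(0, c(8, 8, 8)); m[1:5, 1:5, 1:4] <- 1
#' maskVolume(MaskGrid(m, spacing = c(0.5, 0.5, 2)))
setMethod("maskVolume", "MaskGrid", function(x) {
  sum(x@data) * prod(x@spacing)
})

#' Extent of resection
#'
#' `100 * (pre - post) / pre` percent. The value is not clamped: a
#' postoperative volume larger than the preoperative one yields a negative
#' EOR. A zero preoperative volume is undefined and rejected.
#'
#' @param preMm3,postMm3 Volumes in mm^3 (vectors are paired).
#' @return EOR in percent.
#' @export
#' @examples
#' extentOfResection(10000, 0)     # 100
#' extentOfResection(10000, 5000)  # 50
extentOfResection <- function(preMm3, postMm3) {
  if (any(preMm3 <= 0))
    stop("extent of resection is undefined for a zero preoperative volume")
  100 * (preMm3 - postMm3) / preMm3
}

#' Build a per-patient resection report
#'
#' @param patientId Identifier.
#' @param preMask,postMask [MaskGrid] pre/postoperative tumor masks.
#' @return One-row data.frame: `patientId`, `preopVolumeMm3`,
#'   `postopVolumeMm3`, `eor` (percent), `gtr` (logical).
#' @export
resectionReport <- function(patientId, preMask, postMask) {
  pre <- maskVolume(preMask)
  post <- maskVolume(postMask)
  data.frame(patientId = patientId, preopVolumeMm3 = pre,
             postopVolumeMm3 = post, eor = extentOfResection(pre, post),
             gtr = post == 0)
}

#' Classify gross total resection
#'
#' GTR is an EOR of exactly 100%, i.e. zero postoperative volume. The
#' definition is strict: any positive residual, however small, is not GTR.
#'
#' @param report data.frame from [resectionReport()] (rows are vectorized).
#' @return Logical vector.
#' @export
classifyGTR <- function(report) {
  stopifnot(all(c("postopVolumeMm3", "preopVolumeMm3") %in% names(report)))
  if (any(report$preopVolumeMm3 <= 0))
    stop("GTR is undefined for a zero preoperative volume")
  report$postopVolumeMm3 == 0
}

.pct <- function(num, den) if (den == 0) NaN else 100 * num / den

#' GTR confusion statistics
#'
#' Counts and rates of gross-total-resection detection, with the true GTR
#' flags as ground truth and GTR-present as the positive class (so
#' sensitivity is the GTR detection rate). Rates are percentages; zero
#' denominators give NaN.
#'
#' @param predictedGtr,trueGtr Equal-length logical vectors.
#' @return A [ConfusionReport-class].
#' @export
#' @examples
#' confusionStats(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
confusionStats <- function(predictedGtr, trueGtr) {
  if (length(predictedGtr) != length(trueGtr))
    stop("flag vectors must have equal length")
  predictedGtr <- as.logical(predictedGtr)
  trueGtr <- as.logical(trueGtr)
  tp <- sum(predictedGtr & trueGtr)
  fn <- sum(!predictedGtr & trueGtr)
  fp <- sum(predictedGtr & !trueGtr)
  tn <- sum(!predictedGtr & !trueGtr)
  new("ConfusionReport", tp = tp, fn = fn, fp = fp, tn = tn,
      accuracy = .pct(tp + tn, tp + fn + fp + tn),
      sensitivity = .pct(tp, tp + fn),
      specificity = .pct(tn, tn + fp),
      ppv = .pct(tp, tp + fp),
      npv = .pct(tn, tn + fn))
}

#' @rdname confusionStats
#' @param x A `ConfusionReport`.
#' @export
confusionCounts <- function(x) {
  c(tp = x@tp, fn = x@fn, fp = x@fp, tn = x@tn)
}

#' @rdname confusionStats
#' @export
confusionRates <- function(x) {
  c(accuracy = x@accuracy, sensitivity = x@sensitivity,
    specificity = x@specificity, ppv = x@ppv, npv = x@npv)
}

#' Pearson product-moment correlation
#'
#' Standard correlation via [stats::cor()]; zero variance in either
#' argument gives NaN with a warning.
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @return Correlation in \[-1, 1\], or NaN.
#' @export
pearsonR <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NaN)
  }
  cor(x, y, method = "pearson")
}

#' Summarize automated-vs-manual EOR differences
#'
#' Per-patient absolute EOR differences with mean +/- SD and median (IQR).
#'
#' @param auto,manual data.frames with columns `patientId` and `eor`
#'   covering the same patients.
#' @return `list(differences, mean, sd, median, iqr)`.
#' @export
eorErrorSummary <- function(auto, manual) {
  if (!setequal(auto$patientId, manual$patientId) ||
      nrow(auto) != nrow(manual))
    stop("auto and manual reports must cover the same patients")
  m <- manual[match(auto$patientId, manual$patientId), ]
  d <- abs(auto$eor - m$eor)
  list(differences = setNames(d, auto$patientId),
       mean = mean(d), sd = sd(d), median = median(d), iqr = IQR(d))
}

#' Cohort-level resection assessment
#'
#' Joins automated and manual per-patient reports and computes the Table-4
#' style summary: Pearson correlations of pre/postoperative volumes and
#' EOR, the EOR-difference summary, and the GTR confusion report.
#'
#' @param auto,manual data.frames of [resectionReport()] rows for the same
#'   patients (manual = ground truth).
#' @return `list(table, volumeCorrelationPreop, volumeCorrelationPostop,
#'   eorCorrelation, eorDifference, confusion)`.
#' @export
assessResection <- function(auto, manual) {
  if (!setequal(auto$patientId, manual$patientId) ||
      nrow(auto) != nrow(manual))
    stop("auto and manual reports must cover the same patients")
  m <- manual[match(auto$patientId, manual$patientId), ]
  table <- data.frame(
    patientId = auto$patientId,
    preMm3Auto = auto$preopVolumeMm3, preMm3Manual = m$preopVolumeMm3,
    postMm3Auto = auto$postopVolumeMm3, postMm3Manual = m$postopVolumeMm3,
    eorAuto = auto$eor, eorManual = m$eor,
    gtrAuto = auto$gtr, gtrManual = m$gtr)
  corSafe <- function(x, y) {
    if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) NaN else pearsonR(x, y)
  }
  list(table = table,
       volumeCorrelationPreop = corSafe(table$preMm3Auto,
                                        table$preMm3Manual),
       volumeCorrelationPostop = corSafe(table$postMm3Auto,
                                         table$postMm3Manual),
       eorCorrelation = corSafe(table$eorAuto, table$eorManual),
       eorDifference = eorErrorSummary(auto, m),
       confusion = confusionStats(auto$gtr, m$gtr))
}
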