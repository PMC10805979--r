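# End-to-end orchestration: simulate -> preprocess -> train -> predict ->
# postprocess -> evaluate -> assess, with one master seed and artifacts
# written to a run directory.

.coronalArray <- function(x) aperm(x@data, c(1L, 3L, 2L))

# stack the coronal slices of several grids into [H, W, nSlices]
.stackSlices <- function(grids) {
  stopifnot(length(grids) >= 1L)
  d <- dim(grids[[1L]]@data)
  nA <- d[2L]
  out <- array(0, c(d[1L], d[3L], nA * length(grids)))
  for (i in seq_along(grids))
    out[, , (i - 1L) * nA + seq_len(nA)] <- .coronalArray(grids[[i]])
  out
}

.trainPhaseModels <- function(studies, foldSplit, cfg, phase,
                              augment = NULL, donors = NULL,
                              verbose = TRUE) {
  imgOf <- function(s) if (phase == "preop") s@preopImage else s@postopImage
  mskOf <- function(s) if (phase == "preop") s@preopMask else s@postopMask
  asg <- foldSplit@assignments
  models <- vector("list", foldSplit@k)
  for (j in seq_len(foldSplit@k) - 1L) {
    trIds <- names(asg)[asg != j]
    vaIds <- names(asg)[asg == j]
    trX <- .stackSlices(lapply(studies[trIds], function(s)
      normalizeIntensity(imgOf(s))))
    trY <- .stackSlices(lapply(studies[trIds], mskOf))
    vaX <- .stackSlices(lapply(studies[vaIds], function(s)
      normalizeIntensity(imgOf(s))))
    vaY <- .stackSlices(lapply(studies[vaIds], mskOf))
    if (verbose)
      message(sprintf("[%s] training fold %d on %d slices", phase, j,
                      dim(trX)[3L]))
    models[[j + 1L]] <- trainFold(
      trX, trY, cfg, valImages = vaX, valMasks = vaY, phase = phase,
      fold = j, augment = augment,
      initFrom = if (is.null(donors)) NULL else donors[[j + 1L]])
  }
  models
}

#' Run the full automated volumetry pipeline on a phantom cohort
#'
#' Simulates a seeded cohort, excludes the holdout patients, trains
#' per-phase fold models on the remainder, ensemble-segments the holdout
#' studies (preoperative threshold then postoperative threshold plus
#' morphological postprocessing), and assesses segmentation quality and
#' resection volumetry against the ground-truth masks. All stages derive
#' their randomness from `seed`; deterministic stages reproduce bit-exactly
#' under an identical configuration.
#'
#' @param nPatients Cohort size.
#' @param nHoldout Patients excluded from fold training and used for
#'   assessment.
#' @param phantomCfg [PhantomConfig-class]; its seed is overridden by
#'   `seed`.
#' @param trainCfg [TrainConfig-class].
#' @param ensembleCfg [EnsembleConfig-class].
#' @param postprocCfg [PostprocConfig-class].
#' @param augmentCfg Optional [AugmentConfig-class] for postoperative
#'   training.
#' @param gtrFraction Fraction of cohort with true complete resection.
#' @param trainPostop Train postoperative models (with transfer
#'   initialization from the preoperative fold models) and assess EOR/GTR;
#'   when `FALSE`, only preoperative segmentation is assessed.
#' @param seed Master seed.
#' @param outDir Optional run directory for artifacts (manifest, metrics
#'   CSV, assessment JSON, resolved configuration, models).
#' @param verbose Emit per-stage progress messages.
#' @return A list: `manifest`, `folds`, `preopModels`, `postopModels`,
#'   `metrics` (per holdout case data.frame), `metricsSummary`,
#'   `reports` (auto/manual volumetry tables), `assessment` (when postop
#'   models are trained), `paths`.
#' @export
runPipeline <- function(nPatients = 40L, nHoldout = 8L,
                        phantomCfg = PhantomConfig(),
                        trainCfg = TrainConfig(epochs = 2L, depth = 2L,
                                               baseFilters = 4L),
                        ensembleCfg = EnsembleConfig(),
                        postprocCfg = PostprocConfig(),
                        augmentCfg = NULL, gtrFraction = 0.5,
                        trainPostop = TRUE, seed = 1L, outDir = NULL,
                        verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("[simulate] %d phantom studies (%d held out)", nPatients, nHoldout)
  cohort <- makeCohort(nPatients, phantomCfg, seed = seed,
                       gtrFraction = gtrFraction, nHoldout = nHoldout)
  manifest <- cohort$manifest
  studies <- cohort$studies
  trainIds <- manifest$patientId[!manifest$holdout]
  holdIds <- manifest$patientId[manifest$holdout]

  say("[train] %d-fold split over %d training patients", trainCfg@folds,
      length(trainIds))
  folds <- makeFolds(trainIds, trainCfg@folds, seed = seed)
  preopModels <- .trainPhaseModels(studies[trainIds], folds, trainCfg,
                                   "preop", verbose = verbose)
  postopModels <- NULL
  if (trainPostop) {
    postopModels <- .trainPhaseModels(studies[trainIds], folds, trainCfg,
                                      "postop", augment = augmentCfg,
                                      donors = preopModels,
                                      verbose = verbose)
  }

  say("[predict] segmenting %d holdout studies", length(holdIds))
  metrics <- NULL
  autoRep <- NULL
  manualRep <- NULL
  segmented <- list()
  for (id in holdIds) {
    s <- studies[[id]]
    segPre <- segmentStudy(preopModels, normalizeIntensity(s@preopImage),
                           phase = "preop", ensembleCfg = ensembleCfg,
                           postprocCfg = postprocCfg)
    row <- cbind(patientId = id, phase = "preop",
                 evaluateSegmentation(segPre$mask, s@preopMask))
    segmented[[id]] <- list(preop = segPre)
    if (trainPostop) {
      segPost <- segmentStudy(postopModels,
                              normalizeIntensity(s@postopImage),
                              phase = "postop", ensembleCfg = ensembleCfg,
                              postprocCfg = postprocCfg)
      segmented[[id]]$postop <- segPost
      row <- rbind(row, cbind(patientId = id, phase = "postop",
                              evaluateSegmentation(segPost$mask,
                                                   s@postopMask)))
      autoRep <- rbind(autoRep,
                       resectionReport(id, segPre$mask, segPost$mask))
      manualRep <- rbind(manualRep,
                         resectionReport(id, s@preopMask, s@postopMask))
    }
    metrics <- rbind(metrics, row)
  }
  assessment <- if (trainPostop) assessResection(autoRep, manualRep)
                else NULL

  paths <- list()
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths$manifest <- file.path(outDir, "manifest.csv")
    write.csv(manifest, paths$manifest, row.names = FALSE)
    paths$metrics <- file.path(outDir, "metrics.csv")
    write.csv(metrics, paths$metrics, row.names = FALSE)
    paths$config <- file.path(outDir, "config.json")
    jsonlite::write_json(list(
      seed = seed, nPatients = nPatients, nHoldout = nHoldout,
      gtrFraction = gtrFraction,
      grid = list(shape = phantomCfg@grid@shape,
                  spacing = phantomCfg@grid@spacing),
      train = list(folds = trainCfg@folds, epochs = trainCfg@epochs,
                   batchSize = trainCfg@batchSize,
                   learningRate = trainCfg@learningRate,
                   baseFilters = trainCfg@baseFilters,
                   depth = trainCfg@depth),
      thresholds = list(preop = ensembleCfg@thresholdPreop,
                        postop = ensembleCfg@thresholdPostop),
      postproc = list(minComponentVoxels = postprocCfg@minComponentVoxels)),
      paths$config, auto_unbox = TRUE, digits = NA)
    mdir <- file.path(outDir, "models")
    dir.create(mdir, showWarnings = FALSE)
    for (m in preopModels) {
      saveModel(m, file.path(mdir, sprintf("preop_fold%d.rds", m@fold)))
      write.csv(m@history,
                file.path(mdir, sprintf("preop_fold%d_history.csv", m@fold)),
                row.names = FALSE)
    }
    for (m in postopModels %||% list()) {
      saveModel(m, file.path(mdir, sprintf("postop_fold%d.rds", m@fold)))
      write.csv(m@history,
                file.path(mdir, sprintf("postop_fold%d_history.csv",
                                        m@fold)),
                row.names = FALSE)
    }
    if (trainPostop) {
      paths$report <- file.path(outDir, "report.json")
      jsonlite::write_json(list(
        volumeCorrelationPreop = assessment$volumeCorrelationPreop,
        volumeCorrelationPostop = assessment$volumeCorrelationPostop,
        eorCorrelation = assessment$eorCorrelation,
        eorDifference = assessment$eorDifference[c("mean", "sd", "median",
                                                   "iqr")],
        confusion = c(as.list(confusionCounts(assessment$confusion)),
                      as.list(confusionRates(assessment$confusion)))),
        paths$report, auto_unbox = TRUE, digits = NA, na = "null")
      paths$volumetry <- file.path(outDir, "volumetry.csv")
      write.csv(assessment$table, paths$volumetry, row.names = FALSE)
    }
  }

  list(manifest = manifest, folds = folds, preopModels = preopModels,
       postopModels = postopModels, metrics = metrics,
       metricsSummary = summarizeMetrics(metrics, naRm = TRUE),
       reports = list(auto = autoRep, manual = manualRep),
       assessment = assessment, segmented = segmented, paths = paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
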