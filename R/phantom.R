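# Synthetic sellar phantoms: contrast-enhancing ellipsoid-union tumors on a
# noisy low-frequency background, with a simulated resection leaving a
# connected residual of a prescribed volume fraction. These stand in for
# the clinical pre/postoperative T1 contrast-enhanced cohort.

#' Phantom generator configuration constructor
#'
#' Defaults emulate the clinical cohort at desk scale: a 64^3 grid at 1 mm;
#' tumor semi-axes of 6-14 mm (macroadenoma volumes of roughly 1-10 ml,
#' matching reported preoperative volumes of a few ml); a contrast of 3
#' intensity units over a unit-SD noise background (clearly enhancing
#' tumor); and residual fractions of 2-15% of the preoperative volume for
#' non-GTR cases (most reported postoperative volumes are small fractions
#' of the preoperative volume).
#'
#' @param grid [GridSpec-class] lattice (default `GridSpec(64)`).
#' @param tumorRadiiRange Ellipsoid semi-axis range in mm.
#' @param lobeRange Integer range for the number of overlapping ellipsoid
#'   lobes composing one tumor.
#' @param centerJitter Uniform jitter of lobe centers in mm.
#' @param tumorContrast Mean tumor-minus-background intensity offset.
#' @param noiseSd SD of additive Gaussian noise.
#' @param residualFractionRange Residual volume fraction range for non-GTR
#'   cases, within \[0, 1\].
#' @param seed Integer master seed.
#' @return A [PhantomConfig-class].
#' @export
#' @examples
#' cfg <- PhantomConfig(seed = 7)
#' makePhantom(cfg, "PH001")
PhantomConfig <- function(grid = GridSpec(64L), tumorRadiiRange = c(6, 14),
                          lobeRange = c(1L, 3L), centerJitter = 4,
                          tumorContrast = 3, noiseSd = 1,
                          residualFractionRange = c(0.02, 0.15),
                          seed = 1L) {
  new("PhantomConfig", grid = grid,
      tumorRadiiRange = as.numeric(tumorRadiiRange),
      lobeRange = as.integer(lobeRange),
      centerJitter = as.numeric(centerJitter),
      tumorContrast = as.numeric(tumorContrast),
      noiseSd = as.numeric(noiseSd),
      residualFractionRange = as.numeric(residualFractionRange),
      seed = as.integer(seed))
}

#' Voxelize an ellipsoid (or union of ellipsoids)
#'
#' A voxel is foreground iff its centre lies inside at least one of the
#' ellipsoids. Useful for analytic-volume cross-checks: a single ellipsoid
#' of semi-axes (a, b, c) has volume 4/3 pi a b c.
#'
#' @param grid A [GridSpec-class].
#' @param centers Numeric matrix (nLobes x 3) of centres in mm (voxel 0 is
#'   at 0 mm); a length-3 vector is a single centre.
#' @param radii Numeric matrix (nLobes x 3) of semi-axes in mm, or a
#'   length-3 vector.
#' @return A [MaskGrid] on `grid`.
#' @export
#' @examples
#' m <- ellipsoidMask(GridSpec(32), c(16, 16, 16), c(10, 8, 6))
#' maskVolume(m) / (4 / 3 * pi * 480)  # close to 1
ellipsoidMask <- function(grid, centers, radii) {
  if (is.null(dim(centers))) centers <- matrix(centers, nrow = 1L)
  if (is.null(dim(radii))) radii <- matrix(radii, nrow = 1L)
  MaskGrid(.ellipsoidMask(grid, centers, radii),
           spacing = rep(grid@spacing, 3L))
}

.stringHash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147480000
  h
}

.phantomSeed <- function(seed, patientId) {
  (as.numeric(seed) * 7919 + .stringHash(patientId)) %% 2147480000
}

# voxel-center world coordinates (mm) along each axis, voxel 0 at 0
.axisCoords <- function(grid) {
  lapply(grid@shape, function(n) (seq_len(n) - 1) * grid@spacing)
}

.ellipsoidMask <- function(grid, centers, radii) {
  co <- .axisCoords(grid)
  acc <- array(FALSE, grid@shape)
  for (l in seq_len(nrow(centers))) {
    dx2 <- ((co[[1L]] - centers[l, 1L]) / radii[l, 1L])^2
    dy2 <- ((co[[2L]] - centers[l, 2L]) / radii[l, 2L])^2
    dz2 <- ((co[[3L]] - centers[l, 3L]) / radii[l, 3L])^2
    acc <- acc | (outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1)
  }
  acc * 1
}

# union volume of overlapping ellipsoids, estimated on a 2x supersampled
# lattice; exact closed form is used for a single lobe
.analyticUnionVolume <- function(grid, centers, radii) {
  if (nrow(centers) == 1L)
    return(4 / 3 * pi * prod(radii[1L, ]))
  f <- 2L
  fine <- GridSpec(grid@shape * f, grid@spacing / f)
  sum(.ellipsoidMask(fine, centers, radii)) * (fine@spacing)^3
}

.backgroundField <- function(grid, noiseSd) {
  co <- .axisCoords(grid)
  fov <- max(grid@shape * grid@spacing)
  bg <- array(0, grid@shape)
  for (q in 1:3) {
    freq <- runif(3, 0.5, 1.5) / fov
    phase <- runif(3, 0, 2 * pi)
    amp <- 0.4 * noiseSd
    cx <- cos(2 * pi * freq[1L] * co[[1L]] + phase[1L])
    cy <- cos(2 * pi * freq[2L] * co[[2L]] + phase[2L])
    cz <- cos(2 * pi * freq[3L] * co[[3L]] + phase[3L])
    bg <- bg + amp * outer(outer(cx, cy, `+`), cz, `+`) / 3
  }
  bg + array(rnorm(prod(grid@shape), sd = noiseSd), grid@shape)
}

.phantomImage <- function(grid, maskData, contrast, noiseSd, phaseTag) {
  img <- .backgroundField(grid, noiseSd) + contrast * maskData
  VolumeGrid(img, spacing = rep(grid@spacing, 3L), phase = phaseTag)
}

#' Generate one synthetic pre/postoperative study pair
#'
#' Deterministic given `(cfg@seed, patientId)`: the tumor is a union of
#' 1-3 overlapping ellipsoids with jittered centers, the image adds the
#' configured contrast on the tumor over a smooth noisy background, and the
#' postoperative pair is derived by [simulateResection()].
#'
#' @param cfg A [PhantomConfig-class].
#' @param patientId Character identifier.
#' @param residualFraction Residual tumor volume fraction in \[0, 1\];
#'   `NULL` (default) draws it from `cfg@residualFractionRange`.
#' @return A [StudyPair-class] whose `truth` records the analytic
#'   preoperative volume (mm^3) and the residual fraction.
#' @export
makePhantom <- function(cfg, patientId, residualFraction = NULL) {
  validObject(cfg)
  grid <- cfg@grid
  seed <- .phantomSeed(cfg@seed, patientId)
  .withSeed(seed, {
    nLobes <- sample(cfg@lobeRange[1L]:cfg@lobeRange[2L], 1L)
    fov <- grid@shape * grid@spacing
    center0 <- fov / 2 + runif(3, -cfg@centerJitter, cfg@centerJitter)
    radii0 <- runif(3, cfg@tumorRadiiRange[1L], cfg@tumorRadiiRange[2L])
    centers <- matrix(center0, nrow = 1L, ncol = 3L, byrow = TRUE)
    radii <- matrix(radii0, nrow = 1L, ncol = 3L, byrow = TRUE)
    if (nLobes > 1L) {
      for (l in 2:nLobes) {
        # offset below the primary radii so lobes overlap and stay connected
        off <- runif(3, -0.6, 0.6) * radii0
        centers <- rbind(centers, center0 + off)
        radii <- rbind(radii, radii0 * runif(3, 0.4, 0.8))
      }
    }
    lo <- centers - radii
    hi <- centers + radii
    if (any(lo < 0) || any(t(hi) > fov))
      stop(sprintf("tumor of patient %s does not fit inside the grid",
                   patientId))
    maskData <- .ellipsoidMask(grid, centers, radii)
    rf <- if (is.null(residualFraction) || is.na(residualFraction))
      runif(1, cfg@residualFractionRange[1L], cfg@residualFractionRange[2L])
    else residualFraction
    if (rf < 0 || rf > 1) stop("residualFraction must lie in [0, 1]")
    preImg <- .phantomImage(grid, maskData, cfg@tumorContrast, cfg@noiseSd,
                            "preop")
    sp <- rep(grid@spacing, 3L)
    pair <- new("StudyPair", patientId = patientId,
                preopImage = preImg,
                preopMask = MaskGrid(maskData, spacing = sp),
                postopImage = preImg,
                postopMask = MaskGrid(maskData, spacing = sp),
                truth = list(
                  analyticVolumeMm3 = .analyticUnionVolume(grid, centers,
                                                           radii),
                  residualFraction = rf, nLobes = nLobes, seed = seed))
    simulateResection(pair, rf, seed = seed + 1,
                      contrast = cfg@tumorContrast, noiseSd = cfg@noiseSd)
  })
}

# connected residual of exactly `target` voxels grown by breadth-first
# search (6-connectivity) from a surface voxel extremal along a random
# direction; mimics a residual rim left at one side of the cavity
.carveResidual <- function(maskData, target) {
  d <- dim(maskData)
  inside <- which(maskData > 0)
  if (target >= length(inside)) return(maskData)
  coords <- arrayInd(inside, d)
  dir <- rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  proj <- coords %*% dir
  seedVox <- inside[which.max(proj)]
  member <- array(FALSE, d)
  member[inside] <- TRUE
  taken <- array(FALSE, d)
  nbr <- c(-1L, 1L, -d[1L], d[1L], -d[1L] * d[2L], d[1L] * d[2L])
  queue <- integer(target)
  queue[1L] <- seedVox
  taken[seedVox] <- TRUE
  head <- 1L
  count <- 1L
  while (head <= count && count < target) {
    v <- queue[head]
    head <- head + 1L
    vi <- arrayInd(v, d)
    for (t in 1:6) {
      w <- v + nbr[t]
      # guard against wrapping across array faces
      ax <- c(1L, 1L, 2L, 2L, 3L, 3L)[t]
      step <- c(-1L, 1L, -1L, 1L, -1L, 1L)[t]
      wi <- vi[ax] + step
      if (wi < 1L || wi > d[ax]) next
      if (w < 1L || w > length(maskData)) next
      if (member[w] && !taken[w]) {
        count <- count + 1L
        queue[count] <- w
        taken[w] <- TRUE
        if (count == target) break
      }
    }
  }
  out <- array(0, d)
  out[queue[seq_len(count)]] <- 1
  out
}

#' Simulate a (sub)total resection
#'
#' Replaces the postoperative half of a study pair: the residual mask is a
#' connected sub-region of the preoperative mask holding exactly
#' `round(residualFraction * preopCount)` voxels (empty when the target is
#' zero), grown from one side of the tumor. The postoperative image carries
#' tumor contrast only on the residual; resected tissue reverts to
#' background-level intensity.
#'
#' @param study A [StudyPair-class].
#' @param residualFraction Fraction of preoperative tumor volume remaining,
#'   in \[0, 1\].
#' @param seed Integer seed for the carve direction and postoperative
#'   image noise.
#' @param contrast,noiseSd Image formation parameters (defaults mirror
#'   [PhantomConfig()]).
#' @return The updated [StudyPair-class].
#' @export
simulateResection <- function(study, residualFraction, seed = 1L,
                              contrast = 3, noiseSd = 1) {
  if (residualFraction < 0 || residualFraction > 1)
    stop("residualFraction must lie in [0, 1]")
  preData <- study@preopMask@data
  d <- dim(preData)
  sp <- study@preopMask@spacing
  grid <- GridSpec(d, sp[1L])
  target <- round(residualFraction * sum(preData))
  .withSeed(seed, {
    postData <- if (target == 0) array(0, d)
                else .carveResidual(preData, target)
    postImg <- .phantomImage(grid, postData, contrast, noiseSd, "postop")
    truth <- study@truth
    truth$residualFraction <- residualFraction
    initialize(study, postopImage = postImg,
               postopMask = MaskGrid(postData, spacing = sp),
               truth = truth)
  })
}

#' Generate a seeded phantom cohort
#'
#' Creates `n` independent study pairs plus a manifest. A `gtrFraction` of
#' the cohort (rounded) receives a residual fraction of exactly 0 (true
#' gross total resections) so GTR confusion machinery is exercised; the
#' remainder draw residual fractions from the configured range. A trailing
#' `holdout` share can be flagged for exclusion from model training.
#'
#' @param n Number of patients (>= 1).
#' @param cfg A [PhantomConfig-class].
#' @param seed Cohort seed; defaults to `cfg@seed`.
#' @param gtrFraction Fraction of patients with complete resection.
#' @param nHoldout Number of patients flagged as the holdout set.
#' @return `list(studies = named list of StudyPair, manifest = data.frame)`
#'   with manifest columns `patientId`, `analyticVolumeMm3`,
#'   `preopVolumeMm3`, `postopVolumeMm3`, `residualFraction`, `gtr`,
#'   `holdout`.
#' @export
#' @examples
#' coh <- makeCohort(4, PhantomConfig(seed = 7), gtrFraction = 0.5)
#' coh$manifest
makeCohort <- function(n, cfg, seed = cfg@seed, gtrFraction = 0.5,
                       nHoldout = 0L) {
  stopifnot(n >= 1L, nHoldout >= 0L, nHoldout <= n)
  ids <- sprintf("PH%03d", seq_len(n))
  nGtr <- round(gtrFraction * n)
  gtrIdx <- .withSeed(as.numeric(seed) + 17, sample.int(n, nGtr))
  rfs <- rep(NA_real_, n)
  rfs[gtrIdx] <- 0
  cfgSeeded <- initialize(cfg, seed = as.integer(seed %% 2147480000))
  studies <- vector("list", n)
  names(studies) <- ids
  for (i in seq_len(n))
    studies[[i]] <- makePhantom(cfgSeeded, ids[i], residualFraction = rfs[i])
  manifest <- data.frame(
    patientId = ids,
    analyticVolumeMm3 = vapply(studies, function(s)
      s@truth$analyticVolumeMm3, numeric(1)),
    preopVolumeMm3 = vapply(studies, function(s)
      maskVolume(s@preopMask), numeric(1)),
    postopVolumeMm3 = vapply(studies, function(s)
      maskVolume(s@postopMask), numeric(1)),
    residualFraction = vapply(studies, function(s)
      s@truth$residualFraction, numeric(1)),
    row.names = NULL)
  manifest$gtr <- manifest$residualFraction == 0
  manifest$holdout <- c(rep(FALSE, n - nHoldout), rep(TRUE, nHoldout))
  list(studies = studies, manifest = manifest)
}

#' Write a cohort to disk as NIfTI pairs plus a CSV manifest
#'
#' Files are named `{patientId}_{phase}_{image|mask}.nii.gz`; the manifest
#' is written to `manifest.csv`.
#'
#' @param cohort Result of [makeCohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$studies) {
    base <- file.path(dir, s@patientId)
    writeVolume(s@preopImage, paste0(base, "_preop_image.nii.gz"))
    writeVolume(s@preopMask, paste0(base, "_preop_mask.nii.gz"))
    writeVolume(s@postopImage, paste0(base, "_postop_image.nii.gz"))
    writeVolume(s@postopMask, paste0(base, "_postop_mask.nii.gz"))
  }
  path <- file.path(dir, "manifest.csv")
  write.csv(cohort$manifest, path, row.names = FALSE)
  invisible(path)
}
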