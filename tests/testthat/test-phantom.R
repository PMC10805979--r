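# Synthetic study-pair generator: determinism, analytic volumes, resection
# semantics, cohort manifests.

test_that("phantoms are bit-identical given the same seed and patient id", {
  cfg <- PhantomConfig(seed = 42L)
  a <- makePhantom(cfg, "PH007")
  b <- makePhantom(cfg, "PH007")
  expect_identical(gridData(a@preopImage), gridData(b@preopImage))
  expect_identical(gridData(a@postopImage), gridData(b@postopImage))
  expect_identical(gridData(a@preopMask), gridData(b@preopMask))
  expect_identical(a@truth, b@truth)
  c <- makePhantom(PhantomConfig(seed = 43L), "PH007")
  expect_false(identical(gridData(a@preopImage), gridData(c@preopImage)))
})

test_that("a (10, 8, 6) mm ellipsoid voxelizes to within 2% of 4/3 pi abc", {
  m <- ellipsoidMask(GridSpec(64L), c(32, 32, 32), c(10, 8, 6))
  analytic <- 4 / 3 * pi * 480
  expect_lt(abs(maskVolume(m) - analytic) / analytic, 0.02)
})

test_that("manifest analytic volumes track voxel volumes within 2% for radii >= 8 mm", {
  cfg <- PhantomConfig(tumorRadiiRange = c(8, 12), seed = 5L)
  coh <- makeCohort(6, cfg, gtrFraction = 0.5)
  relErr <- abs(coh$manifest$preopVolumeMm3 - coh$manifest$analyticVolumeMm3) /
    coh$manifest$analyticVolumeMm3
  expect_true(all(relErr < 0.02))
})

test_that("resection limits behave: fraction 1 keeps the mask, 0 empties it", {
  cfg <- PhantomConfig(seed = 3L)
  full <- makePhantom(cfg, "A", residualFraction = 1)
  expect_identical(gridData(full@postopMask), gridData(full@preopMask))
  none <- makePhantom(cfg, "A", residualFraction = 0)
  expect_equal(sum(gridData(none@postopMask)), 0)
  expect_equal(extentOfResection(maskVolume(none@preopMask),
                                 maskVolume(none@postopMask)), 100)
})

test_that("a 10% resection residual hits the voxel-count target", {
  m <- ellipsoidMask(GridSpec(64L), c(32, 32, 32), c(10, 8, 6))
  n <- sum(gridData(m))
  expect_gt(n, 1900); expect_lt(n, 2100)
  img <- VolumeGrid(gridData(m) * 3, phase = "preop")
  pair <- new("StudyPair", patientId = "E", preopImage = img,
              preopMask = m, postopImage = img, postopMask = m,
              truth = list(analyticVolumeMm3 = 4 / 3 * pi * 480,
                           residualFraction = 1))
  res <- simulateResection(pair, 0.1, seed = 9L)
  cnt <- sum(gridData(res@postopMask))
  expect_gte(cnt, round(0.09 * n))
  expect_lte(cnt, round(0.11 * n))
  expect_equal(cnt, round(0.1 * n))  # the carve is exact by construction
})

test_that("residuals are connected subsets of the preoperative tumor", {
  cfg <- PhantomConfig(seed = 21L)
  for (id in c("R1", "R2", "R3")) {
    p <- makePhantom(cfg, id, residualFraction = 0.12)
    post <- gridData(p@postopMask)
    pre <- gridData(p@preopMask)
    expect_true(all(post <= pre))
    sizes <- rComponentSizes(post, connectivity = 26)
    expect_length(sizes, 1L)
  }
})

test_that("cohorts are seeded, sized, and honour the GTR fraction", {
  cfg <- PhantomConfig(seed = 1L)
  coh <- makeCohort(20, cfg, seed = 99L, gtrFraction = 0.5, nHoldout = 4L)
  expect_equal(nrow(coh$manifest), 20L)
  expect_length(coh$studies, 20L)
  expect_equal(sum(coh$manifest$residualFraction == 0), 10L)
  expect_equal(sum(coh$manifest$holdout), 4L)
  coh2 <- makeCohort(20, cfg, seed = 99L, gtrFraction = 0.5, nHoldout = 4L)
  expect_identical(coh$manifest, coh2$manifest)
})

test_that("phantom tumors that cannot fit in the grid are rejected", {
  expect_error(PhantomConfig(grid = GridSpec(16L),
                             tumorRadiiRange = c(6, 14)),
               "field of view")
})

test_that("cohorts round-trip through NIfTI files and a CSV manifest", {
  cfg <- PhantomConfig(grid = GridSpec(16L), tumorRadiiRange = c(3, 5),
                       centerJitter = 1, seed = 2L)
  coh <- makeCohort(2, cfg, gtrFraction = 0.5)
  dir <- tempfile("cohort")
  writeCohort(coh, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2L)
  id <- man$patientId[1]
  m <- readMask(file.path(dir, paste0(id, "_preop_mask.nii.gz")))
  expect_identical(gridData(m), gridData(coh$studies[[id]]@preopMask))
  unlink(dir, recursive = TRUE)
})
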