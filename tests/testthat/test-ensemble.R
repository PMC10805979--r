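# Slice-wise volume inference, ensemble averaging and thresholding.

untrainedModel <- function(depth = 2L, filters = 2L, seed = 13L) {
  ts <- tinyPhantomSlices(n = 1, grid = 16L, seed = seed)
  cfg <- TrainConfig(epochs = 1L, depth = depth, baseFilters = filters,
                     seed = seed)
  trainFold(ts$x[, , 1:4], ts$y[, , 1:4], cfg)
}

test_that("predictVolume preserves shape, stays in [0,1], and equals slice-wise prediction", {
  m <- untrainedModel()
  cfg <- PhantomConfig(grid = GridSpec(16L), tumorRadiiRange = c(3, 5),
                       centerJitter = 1, seed = 4L)
  vol <- normalizeIntensity(makePhantom(cfg, "V")@preopImage)
  prob <- predictVolume(m, vol)
  expect_identical(gridShape(prob), gridShape(vol))
  expect_true(all(gridData(prob) >= 0 & gridData(prob) <= 1))
  # slicing, predicting each coronal plane, and restacking gives the same grid
  d <- gridShape(vol)
  manual <- array(0, d)
  for (k in seq_len(d[2])) {
    sl <- gridData(vol)[, k, ]
    x1 <- array(sl, c(d[1], d[3], 1))
    manual[, k, ] <- AdenoVol:::.predictArray(m@parameters, x1,
                                              m@config@depth)[, , 1]
  }
  expect_equal(gridData(prob), manual, tolerance = 1e-12)
})

test_that("ensembleAverage is the voxel-wise mean with identity and symmetry laws", {
  set.seed(15)
  d <- c(6L, 6L, 6L)
  g1 <- ProbabilityGrid(array(runif(prod(d)), d))
  g0 <- ProbabilityGrid(array(0, d))
  gA <- ProbabilityGrid(array(1, d))
  expect_identical(gridData(ensembleAverage(rep(list(g1), 5))),
                   gridData(g1))
  expect_true(all(gridData(ensembleAverage(list(g0, gA))) == 0.5))
  g2 <- ProbabilityGrid(array(runif(prod(d)), d))
  g3 <- ProbabilityGrid(array(runif(prod(d)), d))
  e123 <- ensembleAverage(list(g1, g2, g3))
  e312 <- ensembleAverage(list(g3, g1, g2))
  expect_equal(gridData(e123), gridData(e312), tolerance = 1e-15)
  # bounded by the voxel-wise min and max of the inputs
  lo <- pmin(gridData(g1), gridData(g2), gridData(g3))
  hi <- pmax(gridData(g1), gridData(g2), gridData(g3))
  expect_true(all(gridData(e123) >= lo - 1e-15 & gridData(e123) <= hi + 1e-15))
  expect_error(ensembleAverage(list(g1,
    ProbabilityGrid(array(0, c(4L, 4L, 4L))))), "shape")
})

test_that("binarize uses >= at the threshold and is monotone in the threshold", {
  d <- c(4L, 4L, 4L)
  p <- array(0.2, d); p[1, 1, 1] <- 0.60; p[2, 1, 1] <- 0.599
  g <- ProbabilityGrid(p)
  m <- binarize(g, 0.60)
  expect_equal(gridData(m)[1, 1, 1], 1)  # tie counts as foreground
  expect_equal(gridData(m)[2, 1, 1], 0)
  expect_equal(sum(gridData(binarize(g, 0.7))), 0)
  set.seed(16)
  gr <- ProbabilityGrid(array(runif(prod(d)), d))
  m1 <- gridData(binarize(gr, 0.3))
  m2 <- gridData(binarize(gr, 0.6))
  expect_true(all(m2 <= m1))  # raising the threshold never adds voxels
  expect_error(binarize(gr, 1.2))
})

test_that("segmentStudy applies phase thresholds and postprocessing only postoperatively", {
  m <- untrainedModel()
  cfg <- PhantomConfig(grid = GridSpec(16L), tumorRadiiRange = c(3, 5),
                       centerJitter = 1, seed = 6L)
  s <- makePhantom(cfg, "S")
  pre <- normalizeIntensity(s@preopImage)
  prob <- ensembleAverage(list(predictVolume(m, pre)))
  segPre <- segmentStudy(list(m), pre, phase = "preop")
  expect_identical(gridData(segPre$mask),
                   gridData(binarize(prob, 0.6)))
  segPost <- segmentStudy(list(m), pre, phase = "postop",
                          postprocCfg = PostprocConfig(minComponentVoxels = 1L))
  manual <- postprocessPostop(binarize(prob, 0.44),
                              PostprocConfig(minComponentVoxels = 1L))
  expect_identical(gridData(segPost$mask), gridData(manual))
  expect_error(segmentStudy(list(m), pre, phase = "unknown"), "phase")
})
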