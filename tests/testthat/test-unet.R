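# Fold splitting, augmentation, training dynamics, serialization and
# transfer initialization of the slice-wise network.

test_that("makeFolds partitions patients evenly, exhaustively and reproducibly", {
  ids <- sprintf("P%02d", 1:20)
  fs <- makeFolds(ids, k = 5, seed = 7)
  asg <- foldAssignments(fs)
  expect_setequal(names(asg), ids)
  expect_equal(unname(tabulate(asg + 1L, 5L)), rep(4L, 5L))
  fs2 <- makeFolds(ids, k = 5, seed = 7)
  expect_identical(foldAssignments(fs2), asg)
  fs3 <- makeFolds(ids, k = 5, seed = 8)
  expect_false(identical(foldAssignments(fs3), asg))
  # uneven sizes differ by at most one
  asg22 <- foldAssignments(makeFolds(sprintf("Q%02d", 1:22), 5, seed = 1))
  expect_lte(diff(range(tabulate(asg22 + 1L, 5L))), 1L)
  expect_error(makeFolds(c("a", "a", "b"), 2), "duplicate")
  expect_error(makeFolds(c("a", "b"), 3), "at least")
})

test_that("augmentation applies one shared transform and keeps masks binary", {
  set.seed(30)
  img <- matrix(rnorm(32 * 32), 32, 32)
  msk <- matrix(0, 32, 32); msk[10:20, 12:22] <- 1
  idCfg <- AugmentConfig(rotationRange = c(0, 0), zoomRange = c(0, 0),
                         enabled = TRUE)
  out <- augmentSlice(img, msk, idCfg)
  expect_equal(out$image, img, tolerance = 1e-12)
  expect_equal(out$mask, msk)
  cfg <- AugmentConfig(enabled = TRUE)
  draws <- replicate(250, {
    o <- augmentSlice(img, msk, cfg)
    expect_true(all(o$mask %in% c(0, 1)))
    c(o$angle, o$zoom)
  })
  expect_true(all(draws[1, ] >= 0 & draws[1, ] <= 90))
  expect_true(all(draws[2, ] >= 1 & draws[2, ] <= 1.3))
  expect_error(augmentSlice(img, msk[1:10, 1:10], cfg), "shape")
})

test_that("augmentation ranges are validated", {
  expect_error(AugmentConfig(rotationRange = c(0, 120)), "rotation")
  expect_error(AugmentConfig(zoomRange = c(0, 0.5)), "zoom")
  expect_error(AugmentConfig(samplingRatio = 0), "samplingRatio")
})

test_that("training descends, is seeded, and can overfit a tiny batch", {
  ts <- tinyPhantomSlices(n = 2, grid = 16L)
  # pick 4 tumor-bearing slices
  fg <- which(apply(ts$y, 3, sum) > 10)[1:4]
  x4 <- ts$x[, , fg, drop = FALSE]
  y4 <- ts$y[, , fg, drop = FALSE]
  cfg <- TrainConfig(epochs = 60L, batchSize = 4L, depth = 2L,
                     baseFilters = 4L, learningRate = 5e-3, seed = 3L)
  m <- trainFold(x4, y4, cfg)
  expect_equal(nrow(m@history), 60L)
  expect_lt(m@history$trainLoss[60], m@history$trainLoss[1])
  p <- AdenoVol:::.predictArray(m@parameters, x4, cfg@depth)
  expect_true(all(p >= 0 & p <= 1))
  overfitDice <- rDice((p >= 0.5) * 1, y4)
  expect_gt(overfitDice, 0.9)
  # identical config and seed reproduce the loss history exactly
  m2 <- trainFold(x4, y4, cfg)
  expect_identical(m2@history, m@history)
  expect_identical(m2@parameters, m@parameters)
})

test_that("validation loss is recorded when a validation set is given", {
  ts <- tinyPhantomSlices(n = 2, grid = 16L)
  cfg <- TrainConfig(epochs = 1L, depth = 2L, baseFilters = 2L, seed = 1L)
  m <- trainFold(ts$x[, , 1:20], ts$y[, , 1:20], cfg,
                 valImages = ts$x[, , 21:32], valMasks = ts$y[, , 21:32])
  expect_true(is.finite(m@history$valLoss[1]))
})

test_that("slice shapes not divisible by the pooling factor are rejected", {
  x <- array(0, c(18, 18, 2)); y <- x
  cfg <- TrainConfig(epochs = 1L, depth = 3L, baseFilters = 2L)
  expect_error(trainFold(x, y, cfg), "divisible")
})

test_that("models survive serialization bit-exactly", {
  ts <- tinyPhantomSlices(n = 1, grid = 16L)
  cfg <- TrainConfig(epochs = 1L, depth = 2L, baseFilters = 2L, seed = 5L)
  m <- trainFold(ts$x, ts$y, cfg)
  path <- tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  p1 <- AdenoVol:::.predictArray(m@parameters, ts$x, cfg@depth)
  p2 <- AdenoVol:::.predictArray(m2@parameters, ts$x, cfg@depth)
  expect_identical(p1, p2)
  unlink(path)
})

test_that("transfer initialization copies predictions exactly and isolates the donor", {
  ts <- tinyPhantomSlices(n = 2, grid = 16L)
  cfg <- TrainConfig(epochs = 2L, depth = 2L, baseFilters = 4L, seed = 8L)
  donor <- trainFold(ts$x, ts$y, cfg, phase = "preop")
  recipient <- transferInit(cfg, donor)
  expect_identical(recipient@phase, "postop")
  pDonor <- AdenoVol:::.predictArray(donor@parameters, ts$x, cfg@depth)
  pRecip <- AdenoVol:::.predictArray(recipient@parameters, ts$x, cfg@depth)
  expect_identical(pDonor, pRecip)
  # training the recipient must not alter the donor
  donorBefore <- donor@parameters
  trained <- trainFold(ts$x, ts$y, cfg, phase = "postop",
                       initFrom = recipient)
  expect_identical(donor@parameters, donorBefore)
  expect_false(identical(trained@parameters, donor@parameters))
  # architecture mismatch is rejected
  cfgDeep <- TrainConfig(epochs = 1L, depth = 3L, baseFilters = 4L)
  expect_error(transferInit(cfgDeep, donor), "mismatch")
})

test_that("convolution gradients match numerical differentiation", {
  set.seed(44)
  x <- array(rnorm(6 * 6 * 2 * 1), c(6, 6, 2, 1))
  w <- array(rnorm(3 * 3 * 2 * 3, sd = 0.5), c(3, 3, 2, 3))
  b <- rnorm(3)
  lossOf <- function(w_) sum(AdenoVol:::cpp_conv2d_fwd(x, w_, b)^2) / 2
  y <- AdenoVol:::cpp_conv2d_fwd(x, w, b)
  g <- AdenoVol:::cpp_conv2d_bwd(x, w, y)
  eps <- 1e-6
  for (idx in c(1L, 10L, 25L, 54L)) {
    wp <- w; wp[idx] <- wp[idx] + eps
    wm <- w; wm[idx] <- wm[idx] - eps
    num <- (lossOf(wp) - lossOf(wm)) / (2 * eps)
    expect_equal(g$dw[idx], num, tolerance = 1e-5)
  }
})
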