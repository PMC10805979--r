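# Volumes, extent of resection, GTR classification, confusion statistics
# and correlation reporting.

test_that("mask volume is voxel count times voxel volume", {
  d <- c(10L, 10L, 10L)
  a <- array(0, d); a[1:4, 1:5, 1:5] <- 1  # 100 voxels
  expect_equal(maskVolume(MaskGrid(a)), 100)
  expect_equal(maskVolume(MaskGrid(a, spacing = c(0.5, 0.5, 2.0))), 50)
  expect_equal(maskVolume(MaskGrid(array(0, d))), 0)
})

test_that("extent of resection follows 100*(pre-post)/pre without clamping", {
  expect_equal(extentOfResection(10000, 0), 100)
  expect_equal(extentOfResection(10000, 5000), 50)
  expect_equal(extentOfResection(10000, 12000), -20)
  expect_error(extentOfResection(0, 0), "undefined")
  # scale invariance
  set.seed(70)
  pre <- runif(20, 1000, 9000)
  post <- runif(20, 0, 9000)
  expect_equal(extentOfResection(3 * pre, 3 * post),
               extentOfResection(pre, post), tolerance = 1e-12)
})

test_that("GTR is strictly zero residual volume", {
  rep0 <- data.frame(patientId = "a", preopVolumeMm3 = 7000,
                     postopVolumeMm3 = 0, eor = 100, gtr = TRUE)
  rep1 <- data.frame(patientId = "b", preopVolumeMm3 = 7000,
                     postopVolumeMm3 = 1, eor = 100 * 6999 / 7000,
                     gtr = FALSE)
  expect_true(classifyGTR(rep0))
  expect_false(classifyGTR(rep1))
  bad <- data.frame(patientId = "c", preopVolumeMm3 = 0,
                    postopVolumeMm3 = 0)
  expect_error(classifyGTR(bad), "undefined")
  d <- c(8L, 8L, 8L)
  pre <- array(0, d); pre[2:5, 2:5, 2:5] <- 1
  r <- resectionReport("p", MaskGrid(pre), MaskGrid(array(0, d)))
  expect_equal(r$eor, 100)
  expect_true(r$gtr)
})

test_that("confusion statistics reproduce counts and handle empty denominators", {
  cr <- confusionStats(c(TRUE, TRUE, FALSE, FALSE),
                       c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(confusionCounts(cr)), c(1L, 1L, 1L, 1L))
  expect_equal(cr@accuracy, 50)
  allRight <- confusionStats(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(unname(confusionRates(allRight)), rep(100, 5))
  nop <- confusionStats(c(FALSE, FALSE), c(TRUE, FALSE))
  expect_true(is.nan(nop@ppv))
  expect_error(confusionStats(TRUE, c(TRUE, FALSE)), "length")
  # counts always sum to n and regenerate the rates exactly
  set.seed(71)
  for (i in 1:10) {
    p <- runif(15) > 0.5; t <- runif(15) > 0.5
    cc <- confusionStats(p, t)
    k <- confusionCounts(cc)
    expect_equal(sum(k), 15)
    if (k["tp"] + k["fn"] > 0)
      expect_equal(cc@sensitivity,
                   unname(100 * k["tp"] / (k["tp"] + k["fn"])))
  }
})

test_that("pearsonR matches a direct covariance computation and flags degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearsonR(x, 2 * x + 1), 1.0)
  expect_equal(pearsonR(x, -x), -1.0)
  y <- x^2 - 3 * x + exp(x / 5)  # fixed nonlinear function
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_lt(abs(pearsonR(x, y) - oracle), 1e-12)
  expect_warning(r0 <- pearsonR(x, rep(2, 5)), "variance")
  expect_true(is.nan(r0))
  # invariance under positive affine transforms
  expect_equal(pearsonR(3 * x + 2, y), pearsonR(x, y), tolerance = 1e-12)
})

test_that("EOR error summaries aggregate per-patient absolute differences", {
  auto <- data.frame(patientId = c("a", "b"), eor = c(90, 100))
  manA <- data.frame(patientId = c("b", "a"), eor = c(90, 90))
  s <- eorErrorSummary(auto, manA)
  expect_equal(unname(s$differences), c(0, 10))
  expect_equal(s$mean, 5)
  same <- eorErrorSummary(auto, auto)
  expect_equal(same$mean, 0)
  expect_equal(same$sd, 0)
  expect_error(eorErrorSummary(auto,
    data.frame(patientId = c("a", "x"), eor = c(1, 2))), "same patients")
  # random cohorts against a direct recomputation
  set.seed(72)
  ids <- sprintf("r%02d", 1:12)
  a2 <- data.frame(patientId = ids, eor = runif(12, 0, 100))
  m2 <- data.frame(patientId = sample(ids), eor = runif(12, 0, 100))
  s2 <- eorErrorSummary(a2, m2)
  d2 <- abs(a2$eor - m2$eor[match(a2$patientId, m2$patientId)])
  expect_equal(s2$mean, mean(d2))
  expect_equal(s2$sd, sd(d2))
  expect_equal(s2$median, median(d2))
  expect_equal(s2$iqr, IQR(d2))
})

test_that("assessResection joins reports and computes Table-style summaries", {
  set.seed(73)
  ids <- sprintf("s%02d", 1:10)
  man <- data.frame(patientId = ids,
                    preopVolumeMm3 = runif(10, 2000, 9000),
                    postopVolumeMm3 = c(rep(0, 5), runif(5, 10, 400)))
  man$eor <- extentOfResection(man$preopVolumeMm3, man$postopVolumeMm3)
  man$gtr <- man$postopVolumeMm3 == 0
  auto <- man
  auto$preopVolumeMm3 <- man$preopVolumeMm3 * runif(10, 0.9, 1.1)
  auto$postopVolumeMm3 <- man$postopVolumeMm3 + c(rep(0, 7), 30, 30, 30)
  auto$eor <- extentOfResection(auto$preopVolumeMm3, auto$postopVolumeMm3)
  auto$gtr <- auto$postopVolumeMm3 == 0
  a <- assessResection(auto, man)
  expect_equal(nrow(a$table), 10)
  expect_equal(a$volumeCorrelationPreop,
               pearsonR(auto$preopVolumeMm3, man$preopVolumeMm3))
  expect_equal(unname(confusionCounts(a$confusion)["tp"]),
               sum(auto$gtr & man$gtr))
  expect_equal(a$eorDifference$mean, mean(abs(auto$eor - man$eor)))
})
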