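# Dice / Jaccard / HD95 with empty-mask conventions, against brute-force
# set-count and all-pairs-distance oracles.

maskOf <- function(a) MaskGrid(a)

test_that("dice and jaccard reproduce direct set-count values", {
  d <- c(6L, 6L, 6L)
  a <- array(0, d); a[1:2, 1:2, 1:2] <- 1            # |A| = 8
  b <- array(0, d); b[1:2, 1:2, 2:3] <- 1            # |B| = 8, |A n B| = 4
  expect_equal(diceScore(maskOf(a), maskOf(b)), 0.5)
  expect_equal(jaccardScore(maskOf(a), maskOf(b)), 1 / 3)
  expect_equal(diceScore(maskOf(a), maskOf(a)), 1.0)
  expect_equal(jaccardScore(maskOf(a), maskOf(a)), 1.0)
  disj <- array(0, d); disj[5:6, 5:6, 5:6] <- 1
  expect_equal(diceScore(maskOf(a), maskOf(disj)), 0.0)
  expect_equal(jaccardScore(maskOf(a), maskOf(disj)), 0.0)
  expect_error(diceScore(maskOf(a), maskOf(array(0, c(4L, 4L, 4L)))),
               "shape")
})

test_that("empty-mask conventions follow the documented policy", {
  d <- c(5L, 5L, 5L)
  e <- maskOf(array(0, d))
  fa <- array(0, d); fa[2:3, 2:3, 2:3] <- 1
  f <- maskOf(fa)
  # both empty: perfect agreement by default, 0 under the compatibility flag
  expect_equal(diceScore(e, e), 1.0)
  expect_equal(jaccardScore(e, e), 1.0)
  expect_equal(hd95(e, e), 0.0)
  expect_equal(diceScore(e, e, bothEmpty = 0), 0.0)
  expect_equal(jaccardScore(e, e, bothEmpty = 0), 0.0)
  # one empty: zero overlap, undefined surface distance
  expect_equal(diceScore(e, f), 0.0)
  expect_equal(jaccardScore(f, e), 0.0)
  expect_true(is.nan(hd95(e, f)))
  expect_true(is.nan(hd95(f, e)))
})

test_that("hd95 reproduces simple geometry and is symmetric", {
  d <- c(12L, 12L, 12L)
  a <- array(0, d); a[2, 2, 2] <- 1
  b <- array(0, d); b[7, 2, 2] <- 1   # 5 voxels apart along one axis
  expect_equal(hd95(maskOf(a), maskOf(b)), 5.0)
  expect_equal(hd95(maskOf(a), maskOf(a)), 0.0)
  # anisotropic spacing scales world distances
  am <- MaskGrid(a, spacing = c(2, 1, 1))
  bm <- MaskGrid(b, spacing = c(2, 1, 1))
  expect_equal(hd95(am, bm), 10.0)
  expect_error(hd95(am, maskOf(b)), "spacing")
})

test_that("metrics match brute-force oracles on random mask pairs", {
  set.seed(60)
  for (i in 1:30) {
    dd <- sample(6:16, 3)
    a <- randomMask(dd, runif(1, 0.1, 0.5))
    b <- randomMask(dd, runif(1, 0.1, 0.5))
    expect_identical(diceScore(a, b), rDice(gridData(a), gridData(b)))
    expect_identical(jaccardScore(a, b),
                     rJaccard(gridData(a), gridData(b)))
    D <- diceScore(a, b)
    expect_lt(abs(jaccardScore(a, b) - D / (2 - D)), 1e-12)
    if (sum(gridData(a)) > 0 && sum(gridData(b)) > 0)
      expect_lt(abs(hd95(a, b) - rHd95(gridData(a), gridData(b))), 1e-9)
    expect_equal(diceScore(a, b), diceScore(b, a))
    expect_equal(hd95(a, b), hd95(b, a))
  }
})

test_that("dice increases as nested masks approach the reference", {
  d <- c(12L, 12L, 12L)
  A <- array(0, d); A[5:6, 5:6, 5:6] <- 1
  B <- array(0, d); B[4:7, 4:7, 4:7] <- 1
  C <- array(0, d); C[3:8, 3:8, 3:8] <- 1
  expect_lte(diceScore(maskOf(A), maskOf(C)),
             diceScore(maskOf(B), maskOf(C)))
})

test_that("metric summaries expose NaN-propagating and NaN-excluding modes", {
  df <- rbind(
    data.frame(dice = 0.8, jaccard = 2 / 3, hd95_mm = 2.0),
    data.frame(dice = 0.0, jaccard = 0.0, hd95_mm = NaN),
    data.frame(dice = 0.6, jaccard = 0.6 / 1.4, hd95_mm = 4.0))
  prop <- summarizeMetrics(df, naRm = FALSE)
  excl <- summarizeMetrics(df, naRm = TRUE)
  expect_true(is.nan(prop$mean[prop$metric == "hd95_mm"]))
  expect_equal(excl$mean[excl$metric == "hd95_mm"], 3.0)
  expect_equal(excl$median[excl$metric == "dice"], 0.6)
  expect_equal(prop$nNA[prop$metric == "hd95_mm"], 1L)
})
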