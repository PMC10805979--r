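# Morphological cleanup of postoperative masks, checked against pure-R
# shift-based oracles.

blockMask <- function(dim3, from, to) {
  a <- array(0, dim3)
  a[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- 1
  a
}

test_that("components below the size floor are removed, at the floor kept", {
  d <- c(60L, 8L, 8L)
  m49 <- MaskGrid(blockMask(d, c(2, 2, 2), c(50, 2, 2)))  # 49-voxel line
  expect_equal(sum(gridData(m49)), 49)
  expect_equal(sum(gridData(removeSmallComponents(m49, 50))), 0)
  m50 <- MaskGrid(blockMask(d, c(2, 2, 2), c(51, 2, 2)))  # 50-voxel line
  expect_identical(gridData(removeSmallComponents(m50, 50)),
                   gridData(m50))
})

test_that("size filtering keeps exactly the large component of a two-blob mask", {
  d <- c(24L, 12L, 12L)
  a <- blockMask(d, c(1, 1, 1), c(5, 3, 2)) +          # 30 voxels
       blockMask(d, c(10, 1, 1), c(14, 4, 3))          # 60 voxels
  out <- removeSmallComponents(MaskGrid(a), 50)
  expect_equal(sum(gridData(out)), 60)
  expect_identical(gridData(out), blockMask(d, c(10, 1, 1), c(14, 4, 3)))
  expect_equal(sort(rComponentSizes(a)), c(30, 60))
})

test_that("diagonal contact joins components under 26-connectivity", {
  d <- c(8L, 8L, 8L)
  a <- array(0, d)
  a[2, 2, 2] <- 1; a[3, 3, 3] <- 1  # touch only at a corner
  a[6, 6, 6] <- 1                    # isolated
  expect_equal(sort(rComponentSizes(a, 26)), c(1, 2))
  expect_equal(sum(gridData(removeSmallComponents(MaskGrid(a), 2))), 2)
})

test_that("enclosed holes fill while boundary-open cavities stay open", {
  d <- c(9L, 9L, 9L)
  shell <- blockMask(d, c(3, 3, 3), c(7, 7, 7)) -
           blockMask(d, c(4, 4, 4), c(6, 6, 6))
  expect_equal(sum(shell), 98)
  filled <- fillHoles(MaskGrid(shell))
  expect_equal(sum(gridData(filled)), 125)
  expect_identical(gridData(filled), blockMask(d, c(3, 3, 3), c(7, 7, 7)))
  # solid masks are a fixed point
  solid <- MaskGrid(blockMask(d, c(2, 2, 2), c(6, 6, 6)))
  expect_identical(gridData(fillHoles(solid)), gridData(solid))
  # drill a 6-connected channel from the cavity to the lattice boundary
  open <- shell
  open[5, 5, 7] <- 0   # puncture the shell wall
  open[5, 5, 8:9] <- 0 # (already 0) path continues to the boundary
  openFilled <- fillHoles(MaskGrid(open))
  expect_identical(gridData(openFilled), open)
})

test_that("dilation matches the kernel footprint and morphology laws", {
  d <- c(9L, 9L, 9L)
  single <- array(0, d); single[5, 5, 5] <- 1
  out <- dilateMask(MaskGrid(single))
  expect_equal(sum(gridData(out)), 27)
  expect_identical(gridData(out), blockMask(d, c(4, 4, 4), c(6, 6, 6)))
  empty <- MaskGrid(array(0, d))
  expect_equal(sum(gridData(dilateMask(empty))), 0)
  # monotone: A subset of B implies dilate(A) subset of dilate(B)
  set.seed(50)
  for (i in 1:10) {
    B <- gridData(randomMask(c(10L, 10L, 10L), 0.2))
    A <- B * (runif(1000) < 0.5)
    dA <- gridData(dilateMask(MaskGrid(array(A, dim(B)))))
    dB <- gridData(dilateMask(MaskGrid(B)))
    expect_true(all(dA <= dB))
  }
})

test_that("dilation agrees with the shift-OR oracle on random masks", {
  set.seed(51)
  se <- array(0, c(3, 3, 3))
  se[2, 2, ] <- 1; se[, 2, 2] <- 1; se[2, , 2] <- 1  # 6-neighbourhood cross
  for (i in 1:5) {
    m <- randomMask(c(8L, 8L, 8L), 0.15)
    viaPkg <- gridData(dilateMask(m, PostprocConfig(structuringElement = se)))
    expect_identical(viaPkg, rDilate(gridData(m), se))
    cube <- gridData(dilateMask(m))
    expect_identical(cube, rDilate(gridData(m)))
  }
})

test_that("the postprocessing chain runs remove -> fill -> dilate in order", {
  d <- c(16L, 16L, 16L)
  # a 40-voxel blob dies at the size-filter step, so the output is empty
  small <- MaskGrid(blockMask(d, c(3, 3, 3), c(7, 6, 4)))  # 5*4*2 = 40
  expect_equal(sum(gridData(postprocessPostop(small))), 0)
  # a hollow 64-voxel shell survives, fills, then dilates
  shell <- blockMask(d, c(5, 5, 5), c(8, 8, 8)) -
           blockMask(d, c(6, 6, 6), c(7, 7, 7))
  expect_equal(sum(shell), 56)
  out <- postprocessPostop(MaskGrid(shell))
  oracle <- rDilate(rFillHoles(shell))  # 56 >= 50 so the filter keeps it
  expect_identical(gridData(out), oracle)
  expect_equal(sum(oracle), 6^3)
  # empty input stays empty
  expect_equal(sum(gridData(postprocessPostop(MaskGrid(array(0, d))))), 0)
})

test_that("postprocessing monotonicity laws hold on random masks", {
  set.seed(52)
  for (i in 1:20) {
    m <- randomMask(c(10L, 10L, 10L), runif(1, 0.05, 0.4))
    a <- gridData(m)
    expect_true(all(gridData(removeSmallComponents(m, 5)) <= a))
    expect_true(all(gridData(fillHoles(m)) >= a))
    expect_true(all(gridData(dilateMask(m)) >= a))
    out <- gridData(postprocessPostop(m, PostprocConfig(minComponentVoxels = 5L)))
    expect_true(all(out %in% c(0, 1)))
  }
})
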