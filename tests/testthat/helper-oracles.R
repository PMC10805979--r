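# Pure-R brute-force oracles, kept independent of the package's compiled
# morphology/distance code paths.

.defaultAffineForTest <- function(spacing, origin = c(0, 0, 0)) {
  A <- diag(4)
  A[1:3, 1:3] <- diag(spacing, nrow = 3)
  A[1:3, 4] <- origin
  A
}

# random binary mask on a small lattice
randomMask <- function(dim3, pFg = 0.3) {
  MaskGrid(array(as.numeric(runif(prod(dim3)) < pFg), dim3))
}

# shift an array by (di, dj, dk), filling with `fill`
shiftArray <- function(a, di, dj, dk, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- list(
    max(1, 1 - di):min(d[1], d[1] - di),
    max(1, 1 - dj):min(d[2], d[2] - dj),
    max(1, 1 - dk):min(d[3], d[3] - dk))
  if (any(vapply(src, length, 1L) == 0)) return(out)
  out[src[[1]] + di, src[[2]] + dj, src[[3]] + dk] <-
    a[src[[1]], src[[2]], src[[3]]]
  out
}

neighborOffsets <- function(connectivity) {
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  offs
}

# dilation by an arbitrary structuring element via shift-OR
rDilate <- function(a, se = array(1, c(3, 3, 3))) {
  r <- (dim(se) - 1L) %/% 2L
  out <- array(0, dim(a))
  for (dk in -r[3]:r[3]) for (dj in -r[2]:r[2]) for (di in -r[1]:r[1]) {
    if (se[di + r[1] + 1, dj + r[2] + 1, dk + r[3] + 1] == 0) next
    out <- pmax(out, shiftArray(a, di, dj, dk))
  }
  out
}

# hole filling: flood the complement from the lattice boundary with
# 6-connectivity by iterated constrained dilation to a fixed point
rFillHoles <- function(a) {
  d <- dim(a)
  outside <- array(0, d)
  outside[1, , ] <- 1 - a[1, , ]; outside[d[1], , ] <- 1 - a[d[1], , ]
  outside[, 1, ] <- pmax(outside[, 1, ], 1 - a[, 1, ])
  outside[, d[2], ] <- pmax(outside[, d[2], ], 1 - a[, d[2], ])
  outside[, , 1] <- pmax(outside[, , 1], 1 - a[, , 1])
  outside[, , d[3]] <- pmax(outside[, , d[3]], 1 - a[, , d[3]])
  se6 <- array(0, c(3, 3, 3)); se6[2, 2, 2] <- 1
  se6[1, 2, 2] <- se6[3, 2, 2] <- se6[2, 1, 2] <- se6[2, 3, 2] <- 1
  se6[2, 2, 1] <- se6[2, 2, 3] <- 1
  repeat {
    grown <- pmin(rDilate(outside, se6), 1 - a)
    if (all(grown == outside)) break
    outside <- grown
  }
  1 - pmin(outside, 1 - a) * 1
}

# component sizes by repeated seeded dilation (connectivity 6 or 26)
rComponentSizes <- function(a, connectivity = 26) {
  offs <- neighborOffsets(connectivity)
  remaining <- a
  sizes <- integer(0)
  while (sum(remaining) > 0) {
    seedIdx <- which(remaining > 0)[1]
    comp <- array(0, dim(a)); comp[seedIdx] <- 1
    repeat {
      grown <- comp
      for (r in seq_len(nrow(offs)))
        grown <- pmax(grown,
                      shiftArray(comp, offs$di[r], offs$dj[r], offs$dk[r]))
      grown <- pmin(grown, remaining)
      if (all(grown == comp)) break
      comp <- grown
    }
    sizes <- c(sizes, sum(comp))
    remaining <- remaining - comp
  }
  sizes
}

# surface voxels: foreground with >= 1 background 6-neighbour (outside the
# lattice counts as background); returns n x 3 voxel coordinates (0-based)
rSurfaceVoxels <- function(a) {
  eroded <- array(1, dim(a))
  for (o in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                 c(0, 0, -1), c(0, 0, 1)))
    eroded <- pmin(eroded, shiftArray(a, o[1], o[2], o[3], fill = 0))
  surf <- a * (1 - eroded)
  which(surf > 0, arr.ind = TRUE) - 1L
}

# brute-force 95th-percentile Hausdorff distance over all boundary pairs
rHd95 <- function(a, b, spacing = c(1, 1, 1), probs = 0.95) {
  sa <- sweep(rSurfaceVoxels(a), 2, spacing, `*`)
  sb <- sweep(rSurfaceVoxels(b), 2, spacing, `*`)
  dmat <- sqrt(outer(rowSums(sa^2), rep(1, nrow(sb))) +
               outer(rep(1, nrow(sa)), rowSums(sb^2)) -
               2 * sa %*% t(sb))
  dmat[dmat < 0] <- 0  # numerical dust from the expansion
  dab <- apply(dmat, 1, min)
  dba <- apply(dmat, 2, min)
  max(quantile(dab, probs, names = FALSE, type = 7),
      quantile(dba, probs, names = FALSE, type = 7))
}

rDice <- function(a, b) {
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a * b) / (na + nb)
}

rJaccard <- function(a, b) {
  u <- sum(pmax(a, b))
  if (u == 0) return(1)
  sum(a * b) / u
}

# tiny training set: coronal slice stacks from n small phantoms
tinyPhantomSlices <- function(n = 2, grid = 16L, seed = 11) {
  cfg <- PhantomConfig(grid = GridSpec(grid), tumorRadiiRange = c(3, 5),
                       centerJitter = 1, lobeRange = c(1L, 1L), seed = seed)
  studies <- lapply(sprintf("T%02d", seq_len(n)), function(id)
    makePhantom(cfg, id))
  x <- AdenoVol:::.stackSlices(lapply(studies, function(s)
    normalizeIntensity(s@preopImage)))
  y <- AdenoVol:::.stackSlices(lapply(studies, function(s) s@preopMask))
  list(x = x, y = y, studies = studies, cfg = cfg)
}
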