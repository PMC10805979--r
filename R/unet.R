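# Compact 2D U-Net on coronal slices, built on the package's compiled
# convolution/pooling kernels. Parameters live in a flat named list so that
# transfer initialization, serialization and Adam state stay trivial.

.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# numerically stable mean binary cross-entropy from logits
.bceFromLogits <- function(z, y) {
  mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
}

.filtersAt <- function(cfg, level) cfg@baseFilters * 2L^(level - 1L)

.heInit <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

# Parameter list for depth L: encoder levels 1..L-1, bottleneck level L,
# decoder levels L-1..1, then a 1x1 output convolution producing logits.
.unetInit <- function(cfg) {
  L <- cfg@depth
  p <- list()
  cin <- 1L
  for (l in seq_len(L)) {
    f <- .filtersAt(cfg, l)
    p[[sprintf("enc%da_w", l)]] <- .heInit(3L, cin, f)
    p[[sprintf("enc%da_b", l)]] <- numeric(f)
    p[[sprintf("enc%db_w", l)]] <- .heInit(3L, f, f)
    p[[sprintf("enc%db_b", l)]] <- numeric(f)
    cin <- f
  }
  for (l in rev(seq_len(L - 1L))) {
    f <- .filtersAt(cfg, l)
    fup <- .filtersAt(cfg, l + 1L)
    p[[sprintf("dec%da_w", l)]] <- .heInit(3L, fup + f, f)
    p[[sprintf("dec%da_b", l)]] <- numeric(f)
    p[[sprintf("dec%db_w", l)]] <- .heInit(3L, f, f)
    p[[sprintf("dec%db_b", l)]] <- numeric(f)
  }
  p[["out_w"]] <- .heInit(1L, .filtersAt(cfg, 1L), 1L)
  p[["out_b"]] <- numeric(1L)
  p
}

.convRelu <- function(p, name, x, cache) {
  z <- cpp_conv2d_fwd(x, p[[paste0(name, "_w")]], p[[paste0(name, "_b")]])
  a <- .relu(z)
  if (!is.null(cache)) {
    cache[[paste0(name, "_x")]] <- x
    cache[[paste0(name, "_m")]] <- z > 0
  }
  list(a = a, cache = cache)
}

.concatChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

# Forward pass; x is [H, W, 1, N]. Returns logits and, when wanted, the
# cache needed for backpropagation.
.unetForward <- function(params, x, depth, wantCache = FALSE) {
  cache <- if (wantCache) list() else NULL
  skips <- vector("list", depth - 1L)
  a <- x
  for (l in seq_len(depth)) {
    r <- .convRelu(params, sprintf("enc%da", l), a, cache); cache <- r$cache
    r <- .convRelu(params, sprintf("enc%db", l), r$a, cache); cache <- r$cache
    a <- r$a
    if (l < depth) {
      skips[[l]] <- a
      pl <- cpp_maxpool2_fwd(a)
      if (wantCache) {
        cache[[sprintf("pool%d_idx", l)]] <- pl$idx
        cache[[sprintf("pool%d_dim", l)]] <- dim(a)
      }
      a <- pl$y
    }
  }
  for (l in rev(seq_len(depth - 1L))) {
    up <- cpp_upsample2(a)
    cat0 <- .concatChannels(up, skips[[l]])
    if (wantCache) cache[[sprintf("cat%d_split", l)]] <- dim(up)[3L]
    r <- .convRelu(params, sprintf("dec%da", l), cat0, cache); cache <- r$cache
    r <- .convRelu(params, sprintf("dec%db", l), r$a, cache); cache <- r$cache
    a <- r$a
  }
  logits <- cpp_conv2d_fwd(a, params[["out_w"]], params[["out_b"]])
  if (wantCache) cache[["out_x"]] <- a
  list(logits = logits, cache = cache)
}

.convReluBwd <- function(params, grads, name, cache, da) {
  dz <- da * cache[[paste0(name, "_m")]]
  g <- cpp_conv2d_bwd(cache[[paste0(name, "_x")]],
                      params[[paste0(name, "_w")]], dz)
  grads[[paste0(name, "_w")]] <- g$dw
  grads[[paste0(name, "_b")]] <- g$db
  list(grads = grads, dx = g$dx)
}

.unetBackward <- function(params, cache, dlogits, depth) {
  grads <- list()
  g <- cpp_conv2d_bwd(cache[["out_x"]], params[["out_w"]], dlogits)
  grads[["out_w"]] <- g$dw
  grads[["out_b"]] <- g$db
  da <- g$dx
  dskips <- vector("list", depth - 1L)
  for (l in seq_len(depth - 1L)) {
    r <- .convReluBwd(params, grads, sprintf("dec%db", l), cache, da)
    grads <- r$grads
    r <- .convReluBwd(params, grads, sprintf("dec%da", l), cache, r$dx)
    grads <- r$grads
    nup <- cache[[sprintf("cat%d_split", l)]]
    dcat <- r$dx
    dup <- dcat[, , seq_len(nup), , drop = FALSE]
    dskips[[l]] <- dcat[, , nup + seq_len(dim(dcat)[3L] - nup), ,
                        drop = FALSE]
    da <- cpp_upsample2_bwd(dup)
  }
  for (l in rev(seq_len(depth))) {
    if (l < depth) {
      da <- cpp_maxpool2_bwd(cache[[sprintf("pool%d_idx", l)]], da,
                             cache[[sprintf("pool%d_dim", l)]])
      da <- da + dskips[[l]]
    }
    r <- .convReluBwd(params, grads, sprintf("enc%db", l), cache, da)
    grads <- r$grads
    r <- .convReluBwd(params, grads, sprintf("enc%da", l), cache, r$dx)
    grads <- r$grads
    da <- r$dx
  }
  grads
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration constructor
#'
#' @param folds Number of cross-validation folds (default 5).
#' @param epochs Training epochs per fold.
#' @param batchSize Slices per minibatch.
#' @param learningRate Adam step size.
#' @param baseFilters Channels at the first encoder level; doubled per level.
#' @param depth Number of resolution levels (>= 2).
#' @param seed Master seed for fold split, weight init, shuffling and
#'   augmentation.
#' @return A [TrainConfig-class].
#' @export
#' @examples
#' TrainConfig(epochs = 2, depth = 2, baseFilters = 4)
TrainConfig <- function(folds = 5L, epochs = 10L, batchSize = 8L,
                        learningRate = 1e-3, baseFilters = 16L, depth = 4L,
                        seed = 1L) {
  new("TrainConfig", folds = as.integer(folds), epochs = as.integer(epochs),
      batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate),
      baseFilters = as.integer(baseFilters), depth = as.integer(depth),
      seed = as.integer(seed))
}

#' Augmentation configuration constructor
#'
#' @param rotationRange Rotation range in degrees within \[0, 90\].
#' @param zoomRange Zoom-in range as fractions within \[0, 0.30\].
#' @param samplingRatio Fraction of training slices augmented per epoch
#'   (default 1/255).
#' @param enabled Logical switch (default `FALSE`).
#' @return An [AugmentConfig-class].
#' @export
AugmentConfig <- function(rotationRange = c(0, 90), zoomRange = c(0, 0.30),
                          samplingRatio = 1 / 255, enabled = FALSE) {
  new("AugmentConfig", rotationRange = as.numeric(rotationRange),
      zoomRange = as.numeric(zoomRange),
      samplingRatio = as.numeric(samplingRatio), enabled = enabled)
}

#' Patient-level k-fold split
#'
#' Deterministically partitions patient ids into `k` folds of sizes
#' differing by at most one; both scans of a patient always share a fold.
#'
#' @param patientIds Character vector of unique patient ids (length >= k).
#' @param k Number of folds.
#' @param seed Integer seed controlling the shuffle.
#' @return A [FoldSplit-class].
#' @export
#' @examples
#' makeFolds(sprintf("P%02d", 1:20), k = 5, seed = 7)
makeFolds <- function(patientIds, k, seed = 1L) {
  if (anyDuplicated(patientIds))
    stop("duplicate patient ids in fold split")
  if (length(patientIds) < k)
    stop("need at least k patients for a k-fold split")
  ord <- .withSeed(seed, sample.int(length(patientIds)))
  assignments <- integer(length(patientIds))
  assignments[ord] <- rep(seq_len(k) - 1L, length.out = length(patientIds))
  names(assignments) <- patientIds
  new("FoldSplit", assignments = assignments, k = as.integer(k))
}

#' @rdname makeFolds
#' @param x A `FoldSplit`.
#' @export
foldAssignments <- function(x) x@assignments

#' Jointly augment an image/mask slice pair
#'
#' Draws one rotation angle and one zoom factor from the configured ranges
#' (using R's current RNG stream) and applies the identical spatial
#' transform to both slices: bilinear interpolation for the image, nearest
#' neighbour for the mask so it stays binary.
#'
#' @param image,mask Numeric matrices of identical shape (mask binary).
#' @param cfg An [AugmentConfig-class].
#' @return `list(image=, mask=, angle=, zoom=)`.
#' @export
augmentSlice <- function(image, mask, cfg = AugmentConfig()) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask slices must share a shape")
  angle <- runif(1, cfg@rotationRange[1L], cfg@rotationRange[2L])
  zoom <- 1 + runif(1, cfg@zoomRange[1L], cfg@zoomRange[2L])
  list(image = cpp_warp2d(image, angle, zoom, TRUE, min(image)),
       mask = round(cpp_warp2d(mask, angle, zoom, FALSE, 0)),
       angle = angle, zoom = zoom)
}

.checkSliceShape <- function(x, depth) {
  d <- dim(x)
  div <- 2L^(depth - 1L)
  if (any(d[1:2] %% div != 0L))
    stop(sprintf("slice shape %dx%d is not divisible by 2^(depth-1) = %d",
                 d[1L], d[2L], div))
  invisible(TRUE)
}

#' Train one U-Net fold
#'
#' Minimizes slice-wise binary cross-entropy with Adam over the training
#' slices. The loop is fully seeded (from `cfg@seed` and `fold`): weight
#' initialization, shuffling and augmentation draws all derive from it.
#'
#' @param trainImages,trainMasks 3D arrays `[H, W, nSlices]` of normalized
#'   intensity slices and binary label slices.
#' @param cfg A [TrainConfig-class].
#' @param valImages,valMasks Optional validation arrays of the same form.
#' @param phase `"preop"` or `"postop"`.
#' @param fold 0-based fold index (bookkeeping only).
#' @param augment Optional [AugmentConfig-class]; when enabled, a
#'   `samplingRatio` fraction of slices is augmented each epoch.
#' @param initFrom Optional [TrainedModel-class] whose parameters initialize
#'   this model (transfer learning); architectures must match.
#' @return A [TrainedModel-class] with per-epoch loss history.
#' @export
trainFold <- function(trainImages, trainMasks, cfg, valImages = NULL,
                      valMasks = NULL, phase = "preop", fold = 0L,
                      augment = NULL, initFrom = NULL) {
  stopifnot(identical(dim(trainImages), dim(trainMasks)))
  n <- dim(trainImages)[3L]
  if (n < 1L) stop("empty training set")
  .checkSliceShape(trainImages, cfg@depth)
  H <- dim(trainImages)[1L]; W <- dim(trainImages)[2L]
  doAug <- !is.null(augment) && augment@enabled

  foldSeed <- (as.numeric(cfg@seed) * 1000 + as.numeric(fold)) %%
    (.Machine$integer.max - 1)
  .withSeed(foldSeed, {
    params <- if (is.null(initFrom)) .unetInit(cfg)
              else .checkedDonorParams(initFrom, cfg)
    state <- .adamInit(params)
    history <- data.frame(epoch = integer(), trainLoss = numeric(),
                          valLoss = numeric())
    for (epoch in seq_len(cfg@epochs)) {
      ord <- sample.int(n)
      lossAcc <- 0
      nb <- 0L
      for (b0 in seq(1L, n, by = cfg@batchSize)) {
        take <- ord[b0:min(b0 + cfg@batchSize - 1L, n)]
        xb <- trainImages[, , take, drop = FALSE]
        yb <- trainMasks[, , take, drop = FALSE]
        if (doAug) {
          for (s in seq_along(take)) {
            if (runif(1) < augment@samplingRatio) {
              a <- augmentSlice(xb[, , s], yb[, , s], augment)
              xb[, , s] <- a$image
              yb[, , s] <- a$mask
            }
          }
        }
        dim(xb) <- c(H, W, 1L, length(take))
        dim(yb) <- c(H, W, 1L, length(take))
        fw <- .unetForward(params, xb, cfg@depth, wantCache = TRUE)
        loss <- .bceFromLogits(fw$logits, yb)
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at epoch %d; lower the learning rate",
                       epoch))
        dlogits <- (.sigmoid(fw$logits) - yb) / length(yb)
        grads <- .unetBackward(params, fw$cache, dlogits, cfg@depth)
        upd <- .adamStep(params, grads, state, cfg@learningRate)
        params <- upd$params
        state <- upd$state
        lossAcc <- lossAcc + loss
        nb <- nb + 1L
      }
      valLoss <- NA_real_
      if (!is.null(valImages) && dim(valImages)[3L] > 0L) {
        vprob <- .predictArray(params, valImages, cfg@depth,
                               logits = TRUE)
        valLoss <- .bceFromLogits(vprob, valMasks)
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, trainLoss = lossAcc / nb,
                                  valLoss = valLoss))
    }
    new("TrainedModel", parameters = params, phase = phase,
        fold = as.integer(fold), history = history, config = cfg)
  })
}

# batched slice prediction; x is [H, W, N]; returns same-shaped array of
# probabilities (or logits)
.predictArray <- function(params, x, depth, logits = FALSE,
                          chunk = 16L) {
  d <- dim(x)
  out <- array(0, d)
  for (b0 in seq(1L, d[3L], by = chunk)) {
    take <- b0:min(b0 + chunk - 1L, d[3L])
    xb <- x[, , take, drop = FALSE]
    dim(xb) <- c(d[1L], d[2L], 1L, length(take))
    z <- .unetForward(params, xb, depth, wantCache = FALSE)$logits
    out[, , take] <- if (logits) z else .sigmoid(z)
  }
  out
}

.checkedDonorParams <- function(donor, cfg) {
  dc <- donor@config
  if (dc@depth != cfg@depth || dc@baseFilters != cfg@baseFilters)
    stop(sprintf(
      "architecture mismatch: donor depth %d/filters %d vs recipient depth %d/filters %d",
      dc@depth, dc@baseFilters, cfg@depth, cfg@baseFilters))
  donor@parameters
}

#' Transfer-learning initialization
#'
#' Returns an untrained postoperative model whose parameters are a copy of
#' a fully trained preoperative donor: before any training step its
#' predictions are exactly the donor's, and later training of the recipient
#' never touches the donor.
#'
#' @param cfg [TrainConfig-class] of the recipient; its architecture fields
#'   must match the donor's.
#' @param donor A trained [TrainedModel-class].
#' @param phase Phase tag of the recipient (default `"postop"`).
#' @return A [TrainedModel-class] with copied parameters, empty history.
#' @export
transferInit <- function(cfg, donor, phase = "postop") {
  params <- .checkedDonorParams(donor, cfg)
  new("TrainedModel", parameters = params, phase = phase,
      fold = donor@fold,
      history = data.frame(epoch = integer(), trainLoss = numeric(),
                           valLoss = numeric()),
      config = cfg)
}

#' Save / load a trained model
#'
#' Models serialize to RDS; a reloaded model reproduces its predictions
#' bit-exactly.
#'
#' @param model A [TrainedModel-class].
#' @param path File path (conventionally `{phase}_fold{j}.rds`).
#' @return `loadModel` returns the [TrainedModel-class].
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  m <- readRDS(path)
  stopifnot(is(m, "TrainedModel"))
  m
}
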