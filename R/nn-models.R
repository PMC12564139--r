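#' Training configuration for the neural models
#'
#' Defaults follow an Adam regime suited to this task family: initial
#' learning rate 0.001 for the direct classifier and 0.01 for the segmenter,
#' weight decay 1e-6, plateau-reduce scheduling (patience 10 epochs,
#' cooldown 10, factor 0.1), at most 50 epochs with batch size 4, and an
#' oversampling schedule that presents each fracture case 10 times and each
#' non-fracture case 3 times per epoch.
#'
#' @param learningRate initial Adam learning rate.
#' @param weightDecay L2 weight decay (default 1e-6).
#' @param schedulerPatience,schedulerCooldown,schedulerFactor plateau-reduce
#'   scheduler parameters (defaults 10, 10, 0.1).
#' @param maxEpochs maximum training epochs (default 50).
#' @param maxSteps optional cap on total optimization steps (NULL = none).
#' @param batchSize minibatch size (default 4).
#' @param inputShape integer(3) network input shape; 120^3 at clinical scale,
#'   32^3 for desk-scale experiments (default).
#' @param fractureRepeats,nonfractureRepeats oversampling repeats per epoch
#'   (defaults 10 and 3).
#' @param classWeights optional numeric(2) loss weights (no-fracture,
#'   fracture); `NULL` derives them from training prevalence via
#'   [computeClassWeights()].
#' @param augment logical; apply random flips and crops during training.
#' @param seed integer seed governing all training randomness.
#' @return A list of class `"TrainingConfig"`.
#' @export
trainingConfig <- function(learningRate = 0.001, weightDecay = 1e-6,
                           schedulerPatience = 10L, schedulerCooldown = 10L,
                           schedulerFactor = 0.1, maxEpochs = 50L,
                           maxSteps = NULL, batchSize = 4L,
                           inputShape = c(32L, 32L, 32L),
                           fractureRepeats = 10L, nonfractureRepeats = 3L,
                           classWeights = NULL, augment = TRUE, seed = 1L) {
  assertScalarNumeric(learningRate, "learningRate", positive = TRUE)
  assertScalarNumeric(weightDecay, "weightDecay", positive = TRUE)
  if (fractureRepeats < 1 || nonfractureRepeats < 1)
    stop("oversampling repeats must be >= 1", call. = FALSE)
  structure(list(learningRate = learningRate, weightDecay = weightDecay,
                 schedulerPatience = as.integer(schedulerPatience),
                 schedulerCooldown = as.integer(schedulerCooldown),
                 schedulerFactor = schedulerFactor,
                 maxEpochs = as.integer(maxEpochs), maxSteps = maxSteps,
                 batchSize = as.integer(batchSize),
                 inputShape = as.integer(inputShape),
                 fractureRepeats = as.integer(fractureRepeats),
                 nonfractureRepeats = as.integer(nonfractureRepeats),
                 classWeights = classWeights, augment = augment,
                 seed = as.integer(seed)),
            class = "TrainingConfig")
}

#' Configuration of the direct CNN+FNN classifier
#'
#' The trunk stacks DoubleConv blocks (two 3x3x3 convolutions, each followed
#' by batch normalization and ReLU) with max pooling between blocks; the
#' flattened features feed a five-layer feed-forward network with dropout
#' between layers and a softmax two-class output.
#'
#' @param convChannels integer vector of channels per DoubleConv block.
#' @param fnnWidths integer(5) feed-forward layer widths; the last must be 2.
#' @param dropoutRate dropout rate between FNN layers, in `[0, 1)`
#'   (default 0.1).
#' @return A list of class `"M1Config"`.
#' @export
m1Config <- function(convChannels = c(2L, 4L), fnnWidths = c(64L, 32L, 16L, 8L, 2L),
                     dropoutRate = 0.1) {
  if (length(fnnWidths) != 5L) stop("fnnWidths must have 5 layers", call. = FALSE)
  if (tail(fnnWidths, 1) != 2L) stop("final FNN width must be 2", call. = FALSE)
  if (dropoutRate < 0 || dropoutRate >= 1)
    stop("dropoutRate must lie in [0, 1)", call. = FALSE)
  structure(list(convChannels = as.integer(convChannels),
                 fnnWidths = as.integer(fnnWidths), dropoutRate = dropoutRate),
            class = "M1Config")
}

#' Configuration of the encoder-decoder segmentation network
#'
#' A compact 3D U-Net: a DoubleConv encoder level, a pooled DoubleConv
#' bottleneck, nearest-neighbour upsampling, a skip concatenation and a
#' DoubleConv decoder, closed by a 1x1x1 convolution to two per-voxel class
#' scores. The loss mixes soft-Dice and weighted cross-entropy.
#'
#' @param baseChannels channels of the encoder level (bottleneck uses twice
#'   as many; default 4).
#' @param diceWeight,ceWeight non-negative loss mix weights (defaults 0.5
#'   and 0.5; not both 0).
#' @return A list of class `"UNetConfig"`.
#' @export
unetConfig <- function(baseChannels = 4L, diceWeight = 0.5, ceWeight = 0.5) {
  if (diceWeight < 0 || ceWeight < 0 || (diceWeight == 0 && ceWeight == 0))
    stop("loss weights must be >= 0 and not both 0", call. = FALSE)
  structure(list(baseChannels = as.integer(baseChannels),
                 diceWeight = diceWeight, ceWeight = ceWeight),
            class = "UNetConfig")
}

#' Inverse-prevalence class weights
#'
#' `w_c = N_total / (K * N_c)` for K classes, so the prevalence-weighted
#' mean of the weights is 1 and rarer classes are penalized more strongly
#' when misclassified.
#'
#' @param nPerClass positive integer counts per class.
#' @return Numeric vector of per-class weights.
#' @examples
#' computeClassWeights(c(287, 79))
#' @export
computeClassWeights <- function(nPerClass) {
  if (any(nPerClass <= 0)) stop("all class counts must be > 0", call. = FALSE)
  sum(nPerClass) / (length(nPerClass) * nPerClass)
}

#' Combined soft-Dice and cross-entropy segmentation loss
#'
#' `loss = wDice * (1 - softDice) + wCe * weightedCE`, where soft-Dice is
#' `2 sum(p1 t) / (sum(p1) + sum(t))` on the foreground probability and the
#' cross-entropy is averaged over voxels with per-class weights.
#'
#' @param pred array `(d, h, w, 2)` of per-voxel class probabilities
#'   (channels sum to 1).
#' @param target a [CTMask-class] or 0/1 array of shape `(d, h, w)`.
#' @param weights numeric(2) class weights (background, foreground).
#' @param diceWeight,ceWeight loss mix (defaults 0.5 / 0.5).
#' @return Scalar non-negative loss with attributes `dice` (the soft-Dice
#'   term's value) and `ce`.
#' @export
diceCeLoss <- function(pred, target, weights = c(1, 1),
                       diceWeight = 0.5, ceWeight = 0.5) {
  t <- if (is(target, "CTMask")) target@voxels else target
  if (!identical(dim(pred)[1:3], dim(t)) || dim(pred)[4] != 2L)
    stop("pred must be (d, h, w, 2) matching the target shape", call. = FALSE)
  p1 <- pred[, , , 2]
  softDice <- 2 * sum(p1 * t) / (sum(p1) + sum(t) + 1e-8)
  pt <- ifelse(t == 1, p1, pred[, , , 1])
  w <- ifelse(t == 1, weights[2], weights[1])
  ce <- mean(w * -log(pmax(pt, 1e-12)))
  out <- diceWeight * (1 - softDice) + ceWeight * ce
  attr(out, "dice") <- softDice
  attr(out, "ce") <- ce
  out
}

# ---- DoubleConv block (shared by both networks) -----------------------------

dcInit <- function(inC, outC, prefix) {
  p <- list(); b <- list()
  ca <- convInit(inC, outC); cb <- convInit(outC, outC)
  p[[paste0(prefix, ".aW")]] <- ca$W; p[[paste0(prefix, ".ab")]] <- ca$b
  p[[paste0(prefix, ".bW")]] <- cb$W; p[[paste0(prefix, ".bb")]] <- cb$b
  for (half in c("a", "b")) {
    p[[paste0(prefix, ".", half, "G")]] <- rep(1, outC)
    p[[paste0(prefix, ".", half, "B")]] <- numeric(outC)
    b[[paste0(prefix, ".", half, "M")]] <- numeric(outC)
    b[[paste0(prefix, ".", half, "V")]] <- rep(1, outC)
  }
  list(params = p, buffers = b)
}

dcForward <- function(xs, params, buffers, prefix, train) {
  cache <- list()
  for (half in c("a", "b")) {
    cp <- list(W = params[[paste0(prefix, ".", half, "W")]],
               b = params[[paste0(prefix, ".", half, "b")]])
    cc <- lapply(xs, convForward, p = cp)
    bnp <- list(gamma = params[[paste0(prefix, ".", half, "G")]],
                beta = params[[paste0(prefix, ".", half, "B")]],
                runMean = buffers[[paste0(prefix, ".", half, "M")]],
                runVar = buffers[[paste0(prefix, ".", half, "V")]])
    bf <- bnForward(lapply(cc, `[[`, "out"), bnp, train = train)
    buffers[[paste0(prefix, ".", half, "M")]] <- bf$p$runMean
    buffers[[paste0(prefix, ".", half, "V")]] <- bf$p$runVar
    rl <- lapply(bf$out, reluForward)
    cache[[half]] <- list(conv = cc, bn = bf, relu = rl)
    xs <- lapply(rl, `[[`, "out")
  }
  list(out = xs, cache = cache, buffers = buffers)
}

dcBackward <- function(dxs, cache, params, prefix) {
  grads <- list()
  for (half in c("b", "a")) {
    ch <- cache[[half]]
    dxs <- mapply(function(d, c) reluBackward(d, c), dxs, ch$relu,
                  SIMPLIFY = FALSE)
    bnp <- list(gamma = params[[paste0(prefix, ".", half, "G")]])
    bb <- bnBackward(dxs, ch$bn, bnp)
    grads[[paste0(prefix, ".", half, "G")]] <- bb$dgamma
    grads[[paste0(prefix, ".", half, "B")]] <- bb$dbeta
    cp <- list(W = params[[paste0(prefix, ".", half, "W")]])
    dW <- 0; db <- 0
    newDxs <- vector("list", length(dxs))
    for (i in seq_along(dxs)) {
      cb <- convBackward(bb$dxs[[i]], ch$conv[[i]], cp)
      dW <- dW + cb$dW; db <- db + cb$db
      newDxs[[i]] <- cb$dx
    }
    grads[[paste0(prefix, ".", half, "W")]] <- dW
    grads[[paste0(prefix, ".", half, "b")]] <- db
    dxs <- newDxs
  }
  list(dxs = dxs, grads = grads)
}

# ---- U-Net ------------------------------------------------------------------

unetInit <- function(net) {
  C <- net$baseChannels
  e1 <- dcInit(1L, C, "enc1")
  bt <- dcInit(C, 2L * C, "bott")
  de <- dcInit(3L * C, C, "dec1")
  fin <- denseInit(C, 2L)
  params <- c(e1$params, bt$params, de$params,
              list(fin.W = fin$W, fin.b = fin$b))
  buffers <- c(e1$buffers, bt$buffers, de$buffers)
  list(params = params, buffers = buffers, cfg = net)
}

unetForward <- function(model, xs, train = TRUE) {
  p <- model$params; b <- model$buffers
  C <- model$cfg$baseChannels
  f1 <- dcForward(xs, p, b, "enc1", train); b <- f1$buffers
  pools <- lapply(f1$out, maxPoolForward)
  f2 <- dcForward(lapply(pools, `[[`, "out"), p, b, "bott", train); b <- f2$buffers
  ups <- lapply(f2$out, upsampleForward)
  cats <- mapply(function(e, u) {
    d <- dim(e)
    out <- array(0, c(d[1:3], 3L * C))
    out[, , , 1:C] <- e
    out[, , , (C + 1):(3 * C)] <- u$out
    out
  }, f1$out, ups, SIMPLIFY = FALSE)
  f3 <- dcForward(cats, p, b, "dec1", train); b <- f3$buffers
  logits <- lapply(f3$out, function(x) {
    d <- dim(x)
    array(sweep(matrix(x, ncol = C) %*% p$fin.W, 2, p$fin.b, `+`), c(d[1:3], 2L))
  })
  model$buffers <- b
  list(logits = logits, cache = list(f1 = f1, pools = pools, f2 = f2,
                                     ups = ups, f3 = f3, xs = xs),
       model = model)
}

unetBackward <- function(model, fwd, dLogits) {
  p <- model$params; C <- model$cfg$baseChannels
  grads <- list(fin.W = 0, fin.b = 0)
  dDec <- vector("list", length(dLogits))
  for (i in seq_along(dLogits)) {
    x <- fwd$cache$f3$cache$b$relu[[i]]$out
    d <- dim(x)
    dY <- matrix(dLogits[[i]], ncol = 2L)
    X <- matrix(x, ncol = C)
    grads$fin.W <- grads$fin.W + crossprod(X, dY)
    grads$fin.b <- grads$fin.b + colSums(dY)
    dDec[[i]] <- array(dY %*% t(p$fin.W), d)
  }
  b3 <- dcBackward(dDec, fwd$cache$f3$cache, p, "dec1")
  grads <- c(grads, b3$grads)
  dE1skip <- lapply(b3$dxs, function(dc) dc[, , , 1:C, drop = FALSE])
  dUp <- lapply(b3$dxs, function(dc) dc[, , , (C + 1):(3 * C), drop = FALSE])
  dBott <- mapply(function(du, u) upsampleBackward(du, u), dUp, fwd$cache$ups,
                  SIMPLIFY = FALSE)
  b2 <- dcBackward(dBott, fwd$cache$f2$cache, p, "bott")
  grads <- c(grads, b2$grads)
  dPool <- mapply(function(dp, pc) maxPoolBackward(dp, pc), b2$dxs,
                  fwd$cache$pools, SIMPLIFY = FALSE)
  dE1 <- mapply(`+`, dE1skip, dPool, SIMPLIFY = FALSE)
  b1 <- dcBackward(dE1, fwd$cache$f1$cache, p, "enc1")
  grads <- c(grads, b1$grads)
  grads
}

# ---- M1 CNN + FNN -----------------------------------------------------------

m1Init <- function(net, inputShape) {
  params <- list(); buffers <- list()
  inC <- 1L
  d <- as.integer(inputShape)
  for (i in seq_along(net$convChannels)) {
    dc <- dcInit(inC, net$convChannels[i], paste0("blk", i))
    params <- c(params, dc$params); buffers <- c(buffers, dc$buffers)
    inC <- net$convChannels[i]
    d <- d %/% 2L
  }
  nIn <- prod(d) * inC
  widths <- net$fnnWidths
  for (j in seq_along(widths)) {
    dl <- denseInit(if (j == 1) nIn else widths[j - 1], widths[j])
    params[[paste0("fc", j, ".W")]] <- dl$W
    params[[paste0("fc", j, ".b")]] <- dl$b
  }
  list(params = params, buffers = buffers, cfg = net, inputShape = as.integer(inputShape))
}

m1Forward <- function(model, xs, train = TRUE) {
  p <- model$params; b <- model$buffers
  net <- model$cfg
  cache <- list(blocks = list(), pools = list())
  for (i in seq_along(net$convChannels)) {
    f <- dcForward(xs, p, b, paste0("blk", i), train); b <- f$buffers
    pl <- lapply(f$out, maxPoolForward)
    xs <- lapply(pl, `[[`, "out")
    cache$blocks[[i]] <- f$cache
    cache$pools[[i]] <- pl
  }
  cache$flatDim <- dim(xs[[1]])
  H <- do.call(rbind, lapply(xs, as.vector))
  cache$fc <- list()
  nL <- length(net$fnnWidths)
  for (j in seq_len(nL)) {
    dp <- dropoutForward(H, if (j > 1) net$dropoutRate else 0, train = train)
    dn <- denseForward(dp$out, list(W = p[[paste0("fc", j, ".W")]],
                                    b = p[[paste0("fc", j, ".b")]]))
    cache$fc[[j]] <- list(drop = dp, dense = dn)
    H <- if (j < nL) pmax(dn$out, 0) else dn$out
    cache$fc[[j]]$reluMask <- if (j < nL) dn$out > 0 else NULL
  }
  model$buffers <- b
  list(logits = H, probs = softmaxRows(H), cache = cache, model = model)
}

m1Backward <- function(model, fwd, dLogits) {
  p <- model$params; net <- model$cfg
  grads <- list()
  dH <- dLogits
  nL <- length(net$fnnWidths)
  for (j in rev(seq_len(nL))) {
    fc <- fwd$cache$fc[[j]]
    if (j < nL) dH <- dH * fc$reluMask
    db <- denseBackward(dH, fc$dense, list(W = p[[paste0("fc", j, ".W")]]))
    grads[[paste0("fc", j, ".W")]] <- db$dW
    grads[[paste0("fc", j, ".b")]] <- db$db
    dH <- dropoutBackward(db$dx, fc$drop)
  }
  fd <- fwd$cache$flatDim
  dxs <- lapply(seq_len(nrow(dH)), function(i) array(dH[i, ], fd))
  for (i in rev(seq_along(net$convChannels))) {
    dxs <- mapply(function(d, pc) maxPoolBackward(d, pc), dxs,
                  fwd$cache$pools[[i]], SIMPLIFY = FALSE)
    bb <- dcBackward(dxs, fwd$cache$blocks[[i]], p, paste0("blk", i))
    grads <- c(grads, bb$grads)
    dxs <- bb$dxs
  }
  grads
}
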