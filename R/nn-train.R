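caseVolume <- function(x) if (is(x, "PhantomCase")) x@volume else x$volume
caseDensMask <- function(x) if (is(x, "PhantomCase")) x@densMask else x$densMask
caseFracMask <- function(x) if (is(x, "PhantomCase")) x@fractureMask else x$fractureMask
caseLabel <- function(x) if (is(x, "PhantomCase")) x@label else x$label

#' Per-epoch oversampling schedule
#'
#' Returns the case indices presented in one epoch: each fracture case
#' exactly `fractureRepeats` times and each non-fracture case exactly
#' `nonfractureRepeats` times, in seeded shuffled order.
#'
#' @param labels logical vector of case fracture labels.
#' @param cfg a [trainingConfig()].
#' @param epochSeed seed for this epoch's shuffle.
#' @return Integer vector of case indices.
#' @export
oversamplingSchedule <- function(labels, cfg, epochSeed = 1L) {
  idx <- c(rep(which(labels), times = cfg$fractureRepeats),
           rep(which(!labels), times = cfg$nonfractureRepeats))
  withSeed(epochSeed, sample(idx))
}

#' Randomly augment one case
#'
#' Applies, in order: a random isotropic scaling by a factor in
#' `[0.8, 1.2]` (trilinear for the volume, nearest-neighbour for masks),
#' independent mirror flips along each axis with probability 0.5, and a
#' random crop to `cfg$inputShape` that is resampled until at least 90% of
#' the dens-mask voxels remain inside the crop. The identical transform is
#' applied to the volume and both masks.
#'
#' @param case a [PhantomCase-class] (or list with `volume`, `densMask`,
#'   `fractureMask`, `label`).
#' @param cfg a [trainingConfig()].
#' @param seed seed for this augmentation draw.
#' @param maxTries crop rejection-sampling budget (default 50).
#' @return List with fields `volume`, `densMask`, `fractureMask`, `label`
#'   and `retention` (the fraction of dens voxels kept by the crop).
#' @export
augmentCase <- function(case, cfg, seed = 1L, maxTries = 50L) {
  vol <- caseVolume(case); dm <- caseDensMask(case); fm <- caseFracMask(case)
  withSeed(seed, {
    s <- runif(1, 0.8, 1.2)
    d <- dim(vol@voxels)
    n2 <- pmax(4L, as.integer(round(d * s)))
    pos <- lapply(1:3, function(ax) (seq_len(n2[ax]) - 1) / s)
    va <- sampleGrid(vol@voxels, pos[[1]], pos[[2]], pos[[3]], "linear")
    da <- sampleGrid(dm@voxels, pos[[1]], pos[[2]], pos[[3]], "nearest")
    fa <- sampleGrid(fm@voxels, pos[[1]], pos[[2]], pos[[3]], "nearest")
    for (ax in 1:3) if (runif(1) < 0.5) {
      rev_idx <- lapply(dim(va), seq_len)
      rev_idx[[ax]] <- rev(rev_idx[[ax]])
      va <- va[rev_idx[[1]], rev_idx[[2]], rev_idx[[3]], drop = FALSE]
      da <- da[rev_idx[[1]], rev_idx[[2]], rev_idx[[3]], drop = FALSE]
      fa <- fa[rev_idx[[1]], rev_idx[[2]], rev_idx[[3]], drop = FALSE]
    }
    sp <- vol@spacing
    volS <- ctVolume(va, spacing = sp); dmS <- ctMask(da, spacing = sp)
    fmS <- ctMask(fa, spacing = sp)
    nDens <- sum(da)
    target <- cfg$inputShape
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      center <- vapply(1:3, function(ax) runif(1, 0, dim(va)[ax] - 1), numeric(1))
      cv <- padCrop(dmS, target, center = center)
      if (nDens == 0 || sum(cv@voxels) >= 0.9 * nDens) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("augmentation failed: no crop retains >= 90% of the dens mask",
           call. = FALSE)
    croppedDens <- padCrop(dmS, target, center = center)
    list(volume = padCrop(volS, target, center = center),
         densMask = croppedDens,
         fractureMask = padCrop(fmS, target, center = center),
         label = caseLabel(case),
         retention = if (nDens > 0) sum(croppedDens@voxels) / nDens else 1)
  })
}

prepInput <- function(vol, inputShape, mask = NULL) {
  v <- zscoreNormalize(vol)
  out <- padCrop(v, inputShape, center = NULL)
  x <- array(out@voxels, c(dim(out@voxels), 1L))
  list(x = x, offset = attr(out, "cropOffset"))
}

segLossGrad <- function(logits, target, weights, diceW, ceW) {
  d <- dim(logits)
  z <- matrix(logits, ncol = 2L)
  z <- z - apply(z, 1, max)
  e <- exp(z); P <- e / rowSums(e)
  t <- as.vector(target)
  N <- length(t)
  p1 <- P[, 2]
  S <- sum(p1) + sum(t) + 1e-8
  I <- sum(p1 * t)
  softDice <- 2 * I / S
  wv <- ifelse(t == 1, weights[2], weights[1])
  pt <- ifelse(t == 1, p1, P[, 1])
  ce <- mean(wv * -log(pmax(pt, 1e-12)))
  loss <- diceW * (1 - softDice) + ceW * ce
  # gradients w.r.t. logits
  dz <- ceW * wv / N * (P - cbind(1 - t, t))
  dDice_dp1 <- (2 * I - 2 * t * S) / S^2
  pp <- p1 * P[, 1]
  dz[, 2] <- dz[, 2] + diceW * dDice_dp1 * pp
  dz[, 1] <- dz[, 1] - diceW * dDice_dp1 * pp
  list(loss = loss, dice = softDice, dLogits = array(dz, d))
}

#' Train the dens segmentation network
#'
#' Optimizes a compact 3D U-Net with Adam on the combined soft-Dice /
#' weighted cross-entropy loss, using the oversampling schedule and (when
#' enabled) random augmentation, a plateau-reduce learning-rate scheduler on
#' the validation Dice, and best-validation-checkpoint selection: the
#' returned model is the epoch checkpoint with the highest validation Dice.
#' All randomness flows from `cfg$seed`.
#'
#' @param trainCases,valCases non-empty lists of [PhantomCase-class] (or
#'   compatible lists).
#' @param cfg a [trainingConfig()] (learning rate default for segmentation
#'   is 0.01; pass it explicitly).
#' @param net a [unetConfig()].
#' @return An object of class `"densSegmenter"` with fields `params`,
#'   `buffers`, `cfg`, `net`, `inputShape`, `history` (per-epoch data frame
#'   with `epoch`, `meanLoss`, `valDice`, `lr`) and `bestValDice`.
#' @export
trainSegmenter <- function(trainCases, valCases, cfg = trainingConfig(learningRate = 0.01),
                           net = unetConfig()) {
  if (length(trainCases) < 1 || length(valCases) < 1)
    stop("need at least one training and one validation case", call. = FALSE)
  labels <- vapply(trainCases, caseLabel, logical(1))
  model <- withSeed(cfg$seed, unetInit(net))
  opt <- adamInit(model$params)
  sch <- plateauScheduler(cfg$learningRate, cfg$schedulerPatience,
                          cfg$schedulerCooldown, cfg$schedulerFactor)
  weights <- if (is.null(cfg$classWeights)) c(1, 1) else cfg$classWeights
  best <- NULL; bestDice <- -Inf
  hist <- NULL
  step <- 0L
  for (epoch in seq_len(cfg$maxEpochs)) {
    sched <- if (any(labels) && any(!labels))
      oversamplingSchedule(labels, cfg, deriveSeed(cfg$seed, epoch))
    else withSeed(deriveSeed(cfg$seed, epoch),
                  sample(rep(seq_along(trainCases),
                             times = cfg$nonfractureRepeats)))
    lossAcc <- c()
    for (bStart in seq(1, length(sched), by = cfg$batchSize)) {
      idx <- sched[bStart:min(bStart + cfg$batchSize - 1, length(sched))]
      xs <- list(); ts <- list()
      for (j in seq_along(idx)) {
        cs <- trainCases[[idx[j]]]
        if (cfg$augment) {
          cs <- augmentCase(cs, cfg, seed = deriveSeed(cfg$seed, epoch * 100003L +
                                                        bStart * 101L + j))
          xs[[j]] <- array(zscoreNormalize(cs$volume)@voxels,
                           c(cfg$inputShape, 1L))
          ts[[j]] <- cs$densMask@voxels
        } else {
          pr <- prepInput(caseVolume(cs), cfg$inputShape)
          xs[[j]] <- pr$x
          ts[[j]] <- padCrop(caseDensMask(cs), cfg$inputShape)@voxels
        }
      }
      fwd <- unetForward(model, xs, train = TRUE)
      model <- fwd$model
      dLogits <- vector("list", length(xs))
      lossB <- 0
      for (j in seq_along(xs)) {
        lg <- segLossGrad(fwd$logits[[j]], ts[[j]], weights,
                          net$diceWeight, net$ceWeight)
        lossB <- lossB + lg$loss
        dLogits[[j]] <- lg$dLogits / length(xs)
      }
      lossB <- lossB / length(xs)
      if (!is.finite(lossB))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
             call. = FALSE)
      lossAcc <- c(lossAcc, lossB)
      grads <- unetBackward(model, fwd, dLogits)
      upd <- adamStep(model$params, grads, opt, lr = sch$lr,
                      weightDecay = cfg$weightDecay)
      model$params <- upd$params; opt <- upd$state
      step <- step + 1L
      if (!is.null(cfg$maxSteps) && step >= cfg$maxSteps) break
    }
    valDice <- mean(vapply(valCases, function(cs) {
      pm <- predictMaskInternal(model, cfg$inputShape, caseVolume(cs))
      diceCoefficient(pm, caseDensMask(cs))
    }, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = epoch, meanLoss = mean(lossAcc),
                                   valDice = valDice, lr = sch$lr))
    if (valDice >= bestDice) {
      bestDice <- valDice
      best <- list(params = model$params, buffers = model$buffers)
    }
    schedulerStep(sch, valDice)
    if (!is.null(cfg$maxSteps) && step >= cfg$maxSteps) break
  }
  structure(list(params = best$params, buffers = best$buffers, cfg = cfg,
                 net = net, inputShape = cfg$inputShape, history = hist,
                 bestValDice = bestDice),
            class = "densSegmenter")
}

predictMaskInternal <- function(model, inputShape, vol) {
  pr <- prepInput(vol, inputShape)
  fwd <- unetForward(model, list(pr$x), train = FALSE)
  lg <- fwd$logits[[1]]
  m <- array(as.numeric(lg[, , , 2] > lg[, , , 1]), dim(lg)[1:3])
  cropped <- ctMask(m, spacing = vol@spacing)
  if (sum(m) > 0) cropped <- largestComponent(cropped)
  # place the cropped-frame mask back into the original grid
  d <- dim(vol@voxels)
  out <- array(0, d)
  s <- pr$offset
  inLo <- pmax(s, 0); inHi <- pmin(d, s + inputShape)
  outLo <- inLo - s
  out[(inLo[1] + 1):inHi[1], (inLo[2] + 1):inHi[2], (inLo[3] + 1):inHi[3]] <-
    cropped@voxels[(outLo[1] + 1):(outLo[1] + inHi[1] - inLo[1]),
                   (outLo[2] + 1):(outLo[2] + inHi[2] - inLo[2]),
                   (outLo[3] + 1):(outLo[3] + inHi[3] - inLo[3])]
  ctMask(out, spacing = vol@spacing, origin = vol@origin)
}

#' Segment a volume with a trained model
#'
#' Pads/crops the volume to the model's input shape, runs the network in
#' evaluation mode, thresholds the per-voxel class scores, and keeps the
#' largest connected component of the predicted foreground.
#'
#' @param model a `"densSegmenter"` from [trainSegmenter()].
#' @param vol a [CTVolume-class].
#' @return A binary [CTMask-class] on the original grid.
#' @export
predictMask <- function(model, vol) {
  stopifnot(inherits(model, "densSegmenter"))
  predictMaskInternal(list(params = model$params, buffers = model$buffers,
                           cfg = model$net), model$inputShape, vol)
}

#' Train the direct CNN+FNN fracture classifier
#'
#' Optimizes the [m1Config()] network with Adam on class-weighted
#' cross-entropy, using the oversampling schedule and optional augmentation;
#' the checkpoint with the best validation accuracy is returned. Requires
#' both classes in the training set.
#'
#' @param trainCases,valCases lists of [PhantomCase-class].
#' @param cfg a [trainingConfig()] (classification default learning rate
#'   0.001).
#' @param net an [m1Config()].
#' @return Object of class `"densM1"` with `params`, `buffers`, `cfg`,
#'   `net`, `inputShape`, `history` and `bestValAcc`.
#' @export
trainM1 <- function(trainCases, valCases, cfg = trainingConfig(learningRate = 0.001),
                    net = m1Config()) {
  labels <- vapply(trainCases, caseLabel, logical(1))
  if (length(unique(labels)) < 2)
    stop("training set must contain both classes", call. = FALSE)
  # class weights compensate the imbalance that remains after the
  # oversampling schedule, so the two mechanisms compose instead of both
  # correcting the full prevalence gap
  weights <- if (is.null(cfg$classWeights))
    computeClassWeights(c(sum(!labels) * cfg$nonfractureRepeats,
                          sum(labels) * cfg$fractureRepeats))
  else cfg$classWeights
  model <- withSeed(cfg$seed, m1Init(net, cfg$inputShape))
  opt <- adamInit(model$params)
  sch <- plateauScheduler(cfg$learningRate, cfg$schedulerPatience,
                          cfg$schedulerCooldown, cfg$schedulerFactor)
  best <- NULL; bestAcc <- -Inf; hist <- NULL; step <- 0L
  for (epoch in seq_len(cfg$maxEpochs)) {
    sched <- oversamplingSchedule(labels, cfg, deriveSeed(cfg$seed, epoch))
    lossAcc <- c()
    for (bStart in seq(1, length(sched), by = cfg$batchSize)) {
      idx <- sched[bStart:min(bStart + cfg$batchSize - 1, length(sched))]
      xs <- list(); ys <- integer(length(idx))
      for (j in seq_along(idx)) {
        cs <- trainCases[[idx[j]]]
        if (cfg$augment) {
          ac <- augmentCase(cs, cfg, seed = deriveSeed(cfg$seed, epoch * 100003L +
                                                        bStart * 101L + j))
          xs[[j]] <- array(zscoreNormalize(ac$volume)@voxels, c(cfg$inputShape, 1L))
        } else {
          xs[[j]] <- prepInput(caseVolume(cs), cfg$inputShape)$x
        }
        ys[j] <- as.integer(caseLabel(cs))
      }
      fwd <- withSeed(deriveSeed(cfg$seed, 777L + step),
                      m1Forward(model, xs, train = TRUE))
      model <- fwd$model
      P <- fwd$probs
      B <- length(idx)
      wv <- weights[ys + 1L]
      loss <- mean(wv * -log(pmax(P[cbind(seq_len(B), ys + 1L)], 1e-12)))
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
             call. = FALSE)
      lossAcc <- c(lossAcc, loss)
      onehot <- matrix(0, B, 2); onehot[cbind(seq_len(B), ys + 1L)] <- 1
      dLogits <- wv / B * (P - onehot)
      grads <- m1Backward(model, fwd, dLogits)
      upd <- adamStep(model$params, grads, opt, lr = sch$lr,
                      weightDecay = cfg$weightDecay)
      model$params <- upd$params; opt <- upd$state
      step <- step + 1L
      if (!is.null(cfg$maxSteps) && step >= cfg$maxSteps) break
    }
    pv <- predictM1Internal(model, cfg$inputShape, valCases)
    valAcc <- mean((pv[, 2] > 0.5) ==
                     vapply(valCases, caseLabel, logical(1)))
    hist <- rbind(hist, data.frame(epoch = epoch, meanLoss = mean(lossAcc),
                                   valAcc = valAcc, lr = sch$lr))
    if (valAcc >= bestAcc) {
      bestAcc <- valAcc
      best <- list(params = model$params, buffers = model$buffers)
    }
    schedulerStep(sch, valAcc)
    if (!is.null(cfg$maxSteps) && step >= cfg$maxSteps) break
  }
  structure(list(params = best$params, buffers = best$buffers, cfg = cfg,
                 net = net, inputShape = cfg$inputShape, history = hist,
                 bestValAcc = bestAcc),
            class = "densM1")
}

predictM1Internal <- function(model, inputShape, cases) {
  xs <- lapply(cases, function(cs) prepInput(caseVolume(cs), inputShape)$x)
  out <- matrix(0, length(xs), 2)
  for (i in seq_along(xs)) {
    fwd <- m1Forward(model, xs[i], train = FALSE)
    out[i, ] <- fwd$probs
  }
  colnames(out) <- c("noFracture", "fracture")
  out
}

#' Per-case fracture probabilities from a trained direct classifier
#'
#' @param model a `"densM1"` from [trainM1()].
#' @param cases list of [PhantomCase-class] (or compatible lists).
#' @return Matrix `(n, 2)` of class probabilities (rows sum to 1).
#' @export
predictM1 <- function(model, cases) {
  stopifnot(inherits(model, "densM1"))
  predictM1Internal(list(params = model$params, buffers = model$buffers,
                         cfg = model$net), model$inputShape, cases)
}
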