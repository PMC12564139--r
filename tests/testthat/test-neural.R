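test_that("inverse-prevalence class weights follow N/(K*Nc)", {
  w <- computeClassWeights(c(287, 79))
  expect_equal(w, c(366 / 574, 366 / 158))
  expect_equal(computeClassWeights(c(50, 50)), c(1, 1))
  expect_equal(computeClassWeights(c(1, 1)), c(1, 1))
  # prevalence-weighted mean of the weights is 1
  expect_equal(sum(w * c(287, 79)) / 366, 1)
  expect_error(computeClassWeights(c(10, 0)), "> 0")
})

test_that("the combined Dice/cross-entropy loss matches closed forms", {
  t <- array(c(rep(1, 4), rep(0, 4)), c(2, 2, 2))
  onehot <- array(0, c(2, 2, 2, 2))
  onehot[, , , 2][t == 1] <- 1
  onehot[, , , 1][t == 0] <- 1
  perfect <- pmin(pmax(onehot, 1e-9), 1 - 1e-9)
  l <- diceCeLoss(perfect, t)
  expect_equal(attr(l, "dice"), 1, tolerance = 1e-6)
  expect_lt(attr(l, "ce"), 1e-6)
  expect_lt(as.numeric(l), 1e-6)

  complement <- onehot[, , , 2:1]
  lc <- diceCeLoss(pmin(pmax(complement, 1e-9), 1 - 1e-9), t)
  expect_equal(attr(lc, "dice"), 0, tolerance = 1e-6)

  # uniform 0.5 on a half-full 2x2x2 mask: softDice = 2*(0.5*|T|)/(0.5*N+|T|)
  unif <- array(0.5, c(2, 2, 2, 2))
  lu <- diceCeLoss(unif, t)
  expect_equal(attr(lu, "dice"), 2 * (0.5 * 4) / (0.5 * 8 + 4), tolerance = 1e-6)
  expect_error(diceCeLoss(unif, array(1, c(3, 3, 3))), "shape")
})

test_that("the oversampling schedule presents each case the configured number of times", {
  cfg <- trainingConfig(fractureRepeats = 10L, nonfractureRepeats = 3L)
  labels <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  sched <- oversamplingSchedule(labels, cfg, epochSeed = 3)
  counts <- tabulate(sched, nbins = 5)
  expect_equal(counts, c(10L, 3L, 10L, 3L, 3L))
  expect_identical(sched, oversamplingSchedule(labels, cfg, epochSeed = 3))
})

test_that("augmentation is deterministic and keeps at least 90% of the dens in the crop", {
  case <- generateCase(testScaleSpec(seed = 71, fracture = TRUE))
  cfg <- trainingConfig(inputShape = c(24L, 24L, 24L))
  a1 <- augmentCase(case, cfg, seed = 5)
  a2 <- augmentCase(case, cfg, seed = 5)
  expect_identical(voxels(a1$volume), voxels(a2$volume))
  expect_identical(voxels(a1$densMask), voxels(a2$densMask))
  expect_equal(dim(a1$volume), c(24L, 24L, 24L))
  for (s in 1:6) {
    a <- augmentCase(case, cfg, seed = s)
    expect_gte(a$retention, 0.9)
  }
  # a dens larger than the crop is rejected after bounded retries
  big <- generateCase(testScaleSpec(seed = 72))
  expect_error(augmentCase(big, trainingConfig(inputShape = c(6L, 6L, 6L)),
                           seed = 1), "90%")
})

test_that("a tiny U-Net overfits four phantoms and generalizes to a held-out case", {
  cases <- lapply(1:4, function(i) generateCase(testScaleSpec(i, i %% 2 == 0)))
  val <- list(generateCase(testScaleSpec(5, TRUE)),
              generateCase(testScaleSpec(6, FALSE)))
  cfg <- trainingConfig(learningRate = 0.01, inputShape = c(32L, 32L, 32L),
                        augment = FALSE, maxSteps = 150L, maxEpochs = 100L,
                        batchSize = 2L, seed = 42)
  model <- trainSegmenter(cases, val, cfg, unetConfig(baseChannels = 2))

  trainDice <- vapply(cases, function(cs)
    diceCoefficient(predictMask(model, cs@volume), cs@densMask), numeric(1))
  expect_gte(mean(trainDice), 0.85)

  heldout <- generateCase(testScaleSpec(7, TRUE))
  pm <- predictMask(model, heldout@volume)
  expect_true(all(voxels(pm) %in% c(0, 1)))
  expect_gte(diceCoefficient(pm, heldout@densMask), 0.7)

  # best-checkpoint contract: returned model's validation Dice is at least
  # the final epoch's
  expect_gte(model$bestValDice, tail(model$history$valDice, 1))
  # loss decreases over training (first epoch vs last, allowing plateaus)
  expect_lt(tail(model$history$meanLoss, 1), model$history$meanLoss[1])
})

test_that("segmentation training is reproducible from its seed", {
  cases <- lapply(1:2, function(i) generateCase(testScaleSpec(i + 80, i == 1)))
  val <- cases[1]
  cfg <- trainingConfig(learningRate = 0.01, inputShape = c(16L, 16L, 16L),
                        augment = FALSE, maxSteps = 6L, maxEpochs = 3L,
                        batchSize = 2L, seed = 7)
  m1 <- trainSegmenter(cases, val, cfg, unetConfig(baseChannels = 2))
  m2 <- trainSegmenter(cases, val, cfg, unetConfig(baseChannels = 2))
  expect_identical(m1$history$valDice, m2$history$valDice)
  expect_identical(m1$params, m2$params)
})

test_that("the direct classifier outputs softmax probabilities deterministically", {
  cases <- lapply(1:8, function(i) generateCase(testScaleSpec(i + 90, i %% 2 == 0)))
  cfg <- trainingConfig(learningRate = 0.001, inputShape = c(16L, 16L, 16L),
                        augment = FALSE, maxSteps = 10L, maxEpochs = 2L,
                        fractureRepeats = 2L, nonfractureRepeats = 1L, seed = 3)
  net <- m1Config(convChannels = c(2L, 2L), fnnWidths = c(16L, 8L, 8L, 4L, 2L))
  m <- trainM1(cases[1:6], cases[7:8], cfg, net)
  p1 <- predictM1(m, cases[7:8])
  expect_equal(rowSums(p1), c(1, 1), tolerance = 1e-6)
  m2 <- trainM1(cases[1:6], cases[7:8], cfg, net)
  expect_identical(predictM1(m2, cases[7:8]), p1)
  expect_error(trainM1(cases[c(2, 4, 6)], cases[7:8], cfg, net),
               "both classes")
})
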