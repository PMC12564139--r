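test_that("the split sizing rule reproduces the 366-case study split", {
  sp <- splitDataset(1:366, splitPlan(seed = 1))
  expect_equal(lengths(sp), c(train = 256L, val = 37L, test = 73L))
  expect_equal(sort(unname(unlist(sp))), 1:366)  # disjoint and exhaustive

  expect_equal(unname(lengths(splitDataset(1:10, splitPlan(seed = 2)))),
               c(7L, 1L, 2L))
  expect_error(splitDataset(1:2, splitPlan()), "at least 3")
  expect_error(splitDataset(1:4, splitPlan()), "empty")
})

test_that("split membership, not just sizes, is reproducible from the seed", {
  a <- splitDataset(1:50, splitPlan(seed = 4))
  b <- splitDataset(1:50, splitPlan(seed = 4))
  expect_identical(a, b)
  c <- splitDataset(1:50, splitPlan(seed = 5))
  expect_false(identical(a$train, c$train))
})

test_that("stratified splits hold both classes in every subset", {
  labels <- rep(c(TRUE, FALSE), c(13, 47))
  sp <- splitDataset(1:60, splitPlan(stratified = TRUE, seed = 1),
                     labels = labels)
  expect_equal(sort(unname(unlist(sp))), 1:60)
  for (part in sp) {
    expect_gt(sum(labels[part]), 0)
    expect_gt(sum(!labels[part]), 0)
  }
  expect_error(splitDataset(1:60, splitPlan(stratified = TRUE)), "labels")
})

test_that("perturbed-mask pipeline at DSC target 1 equals the oracle-mask pipeline", {
  cohort <- generateCohort(16, 0.5, separablePhantomSpec(), seed = 3)
  plan <- splitPlan(stratified = TRUE, seed = 2)
  a <- runM2Pipeline(cohort, windowSpec("bone"), classifierSpec("decision_tree"),
                     plan, segSource = "oracle-mask", seed = 4)
  b <- runM2Pipeline(cohort, windowSpec("bone"), classifierSpec("decision_tree"),
                     plan, segSource = "perturbed-mask", perturbTarget = 1,
                     seed = 4)
  expect_identical(a$confusion, b$confusion)
  expect_identical(a$predictions, b$predictions)
  # and the full configuration is reproducible
  a2 <- runM2Pipeline(cohort, windowSpec("bone"), classifierSpec("decision_tree"),
                      plan, segSource = "oracle-mask", seed = 4)
  expect_identical(a$confusion, a2$confusion)
})

test_that("the stability grid is complete with one row per cell and seed", {
  cohort <- generateCohort(16, 0.5, separablePhantomSpec(), seed = 3)
  plan <- splitPlan(stratified = TRUE, seed = 2)
  grid <- stabilityAnalysis(cohort, dscLevels = c(0.9, 1.0),
                            windowSpecs = list(bone = windowSpec("bone"),
                                               roi = windowSpec("roi")),
                            classifierSpecs = list(
                              dt = classifierSpec("decision_tree"),
                              nb = classifierSpec("gaussian_nb")),
                            plan = plan, seeds = c(1, 2))
  expect_s3_class(grid, "StabilityGrid")
  expect_equal(nrow(grid), 2 * 2 * 2 * 2)
  expect_true(isTRUE(attr(grid, "complete")))
  expect_true(all(grid$accuracy >= 0 & grid$accuracy <= 1))
  expect_true(all(grid$balancedAccuracy >= 0 & grid$balancedAccuracy <= 1))

  f <- tempfile(fileext = ".png")
  plotStabilityGrid(grid, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("grid cells are order independent", {
  cohort <- generateCohort(12, 0.5, separablePhantomSpec(), seed = 5)
  plan <- splitPlan(stratified = TRUE, seed = 1)
  g1 <- stabilityAnalysis(cohort, dscLevels = c(0.86, 0.94),
                          windowSpecs = list(bone = windowSpec("bone")),
                          classifierSpecs = list(dt = classifierSpec("decision_tree")),
                          plan = plan, seeds = 1)
  g2 <- stabilityAnalysis(cohort, dscLevels = c(0.94, 0.86),
                          windowSpecs = list(bone = windowSpec("bone")),
                          classifierSpecs = list(dt = classifierSpec("decision_tree")),
                          plan = plan, seeds = 1)
  key <- function(g) g[order(g$dsc), c("dsc", "accuracy", "balancedAccuracy")]
  expect_equal(key(as.data.frame(g1)), key(as.data.frame(g2)),
               ignore_attr = TRUE)
})
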