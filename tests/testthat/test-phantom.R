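test_that("identical specs reproduce bit-identical cases and labels follow fracture masks", {
  spec <- testScaleSpec(seed = 11, fracture = TRUE)
  a <- generateCase(spec)
  b <- generateCase(spec)
  expect_identical(voxels(a@volume), voxels(b@volume))
  expect_identical(voxels(a@densMask), voxels(b@densMask))
  expect_true(a@label)
  expect_gt(sum(voxels(a@fractureMask)), 0)

  noFrac <- generateCase(testScaleSpec(seed = 11, fracture = FALSE))
  expect_false(noFrac@label)
  expect_equal(sum(voxels(noFrac@fractureMask)), 0)
})

test_that("a noise-free phantom shows exactly the configured intensity plateaus", {
  spec <- testScaleSpec(seed = 2, fracture = TRUE,
                        noiseSd = 0, backgroundSd = 0, zBlurSd = 0)
  case <- generateCase(spec)
  plateaus <- sort(unique(as.numeric(voxels(case@volume))))
  expect_equal(plateaus, sort(c(spec@backgroundHu, spec@trabecularHu,
                                spec@corticalHu)))
})

test_that("the fracture cleft is darker than the surrounding dens", {
  case <- generateCase(testScaleSpec(seed = 3, fracture = TRUE,
                                     noiseSd = 0, backgroundSd = 0))
  v <- voxels(case@volume)
  inCleft <- v[voxels(case@fractureMask) == 1]
  inBone <- v[voxels(case@densMask) == 1 & voxels(case@fractureMask) == 0]
  expect_lt(mean(inCleft), mean(inBone))
})

test_that("dens mask volume matches the analytic cylinder within digitization tolerance", {
  spec <- phantomSpec(gridSize = 64L, seed = 5)
  case <- generateCase(spec)
  vox <- sum(voxels(case@densMask)) * prod(spec@voxelSpacing)
  analytic <- pi * spec@densRadius^2 * spec@densHeight
  expect_lt(abs(vox - analytic) / analytic, 0.10)
})

test_that("dens mask is a single connected component before displacement", {
  case <- generateCase(testScaleSpec(seed = 8, fracture = TRUE))
  lab <- connectedComponents(voxels(case@densMask))
  expect_equal(max(lab), 1L)
})

test_that("oversized dens geometry is rejected with the offending dimension named", {
  expect_error(generateCase(testScaleSpec(seed = 1, densRadius = 20)),
               "densRadius")
  expect_error(generateCase(testScaleSpec(seed = 1, densHeight = 40)),
               "densHeight")
})

test_that("cohorts honour the requested prevalence exactly after rounding", {
  smallSpec <- phantomSpec(gridSize = 16L, voxelSpacing = c(1, 1, 1),
                           densRadius = 4, densHeight = 8, shellThickness = 1,
                           fractureWidth = 1.5, noiseSd = 10, backgroundSd = 5,
                           zBlurSd = 0.5)
  cohort <- generateCohort(366, 79 / 366, smallSpec, seed = 3)
  expect_equal(sum(cohortLabels(cohort)), 79)
  expect_equal(sum(!cohortLabels(cohort)), 287)

  none <- generateCohort(10, 0, smallSpec, seed = 1)
  expect_equal(sum(cohortLabels(none)), 0)
})

test_that("cohort labels are reproducible and cases carry their own seeds", {
  smallSpec <- phantomSpec(gridSize = 16L, voxelSpacing = c(1, 1, 1),
                           densRadius = 4, densHeight = 8, shellThickness = 1,
                           fractureWidth = 1.5)
  a <- generateCohort(20, 0.5, smallSpec, seed = 9)
  b <- generateCohort(20, 0.5, smallSpec, seed = 9)
  expect_identical(cohortLabels(a), cohortLabels(b))
  expect_equal(sum(cohortLabels(a)), 10)
  expect_identical(voxels(a[[7]]@volume), voxels(b[[7]]@volume))
  # different seeds give different volumes
  c <- generateCohort(20, 0.5, smallSpec, seed = 10)
  expect_false(identical(voxels(a[[7]]@volume), voxels(c[[7]]@volume)))
})

test_that("spec validity enforces intensity ordering and fracture width", {
  expect_error(phantomSpec(trabecularHu = 2000), "ordering")
  expect_error(phantomSpec(fracturePresent = TRUE, fractureWidth = 0),
               "fractureWidth")
  expect_error(phantomSpec(gridSize = 8), "gridSize")
})
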