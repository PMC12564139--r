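test_that("linear windowing matches its closed form and clips at the edges", {
  v <- ctVolume(array(c(-600, 400, 900, 1400, -1000, 2000), c(6, 1, 1)))
  out <- as.numeric(voxels(windowLinear(v, 400, 2000)))
  expect_equal(out, c(0, 0.5, 0.75, 1, 0, 1))
  expect_error(windowLinear(v, 400, 0), "width")
  expect_error(windowSpec("bone", width = -5), "width")
})

test_that("gamma correction follows v^gamma and gamma 1 is the identity", {
  v <- ctVolume(array(c(0.25, 0.5, 0, 1), c(4, 1, 1)))
  expect_equal(as.numeric(voxels(gammaCorrect(v, 0.5))), c(0.5, sqrt(0.5), 0, 1))
  expect_equal(as.numeric(voxels(gammaCorrect(v, 2))), c(0.0625, 0.25, 0, 1))
  expect_identical(voxels(gammaCorrect(v, 1)), voxels(v))
  expect_error(gammaCorrect(ctVolume(array(c(-0.5, 2), c(2, 1, 1))), 0.5),
               "\\[0, 1\\]")
})

test_that("percentile windowing matches the sort-based oracle on whole images", {
  v <- ctVolume(array(0:100, c(101, 1, 1)))
  pw <- percentileWindow(v)
  expect_equal(attr(pw, "windowBounds"), c(5, 95))
  expect_equal(voxels(pw)[51, 1, 1], 0.5)

  set.seed(4)
  r <- ctVolume(array(rnorm(6^3, 100, 50), c(6, 6, 6)))
  pr <- percentileWindow(r, 10, 90)
  b <- attr(pr, "windowBounds")
  expect_equal(b[1], oracleQuantile(as.numeric(voxels(r)), 0.10), tolerance = 1e-12)
  expect_equal(b[2], oracleQuantile(as.numeric(voxels(r)), 0.90), tolerance = 1e-12)
  expect_error(percentileWindow(ctVolume(array(5, c(4, 4, 4)))), "degenerate")
})

test_that("ROI percentile windowing uses the dilated mask and maps background to 0", {
  case <- generateCase(phantomSpec(gridSize = 16L, voxelSpacing = c(1, 1, 1),
                                   densRadius = 4, densHeight = 8,
                                   shellThickness = 1, noiseSd = 0,
                                   backgroundSd = 0, zBlurSd = 0, seed = 31))
  mask <- case@densMask
  out <- percentileWindow(case@volume, mask = mask, roiDilationMm = 3)
  # oracle: enumerate the dilated region by explicit distance checks
  idx <- which(voxels(mask) == 1, arr.ind = TRUE)
  d <- dim(voxels(mask))
  inDil <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (inDil[i, j, k]) next
    dd <- sqrt((idx[, 1] - i)^2 + (idx[, 2] - j)^2 + (idx[, 3] - k)^2)
    if (min(dd) <= 3) inDil[i, j, k] <- TRUE
  }
  src <- voxels(case@volume)[inDil]
  b <- attr(out, "windowBounds")
  expect_equal(b[1], oracleQuantile(src, 0.05), tolerance = 1e-9)
  expect_equal(b[2], oracleQuantile(src, 0.95), tolerance = 1e-9)
  # soft-tissue background falls below the bone-dominated window
  bg <- voxels(out)[voxels(dilateMm(mask, 6)) == 0]
  expect_true(all(bg == 0))
})

test_that("slice-wise CLAHE keeps range, leaves constants, and raises local contrast", {
  const <- ctVolume(array(0.4, c(16, 16, 4)))
  expect_identical(voxels(claheSlicewise(const)), voxels(const))

  set.seed(9)
  v <- ctVolume(array(runif(32 * 32 * 4), c(32, 32, 4)))
  out <- claheSlicewise(v, tiles = 4)
  expect_true(min(voxels(out)) >= 0 && max(voxels(out)) <= 1)

  # low-contrast graded slab: within-tile spread increases
  slab <- array(rep(seq(0.45, 0.55, length.out = 32), 32), c(32, 32, 1))
  eq <- claheSlicewise(ctVolume(slab), tiles = 4)
  tileSd <- function(a) stats::sd(a[1:8, 1:8, 1])
  expect_gt(tileSd(voxels(eq)), tileSd(slab))
})

test_that("windowing transforms are monotone and bounded on random volumes", {
  set.seed(12)
  for (rep in 1:5) {
    v <- array(rnorm(6^3, 300, 400), c(6, 6, 6))
    o <- order(v)
    lin <- voxels(windowLinear(ctVolume(v), 400, 2000))
    expect_true(all(diff(lin[o]) >= 0))
    expect_true(all(lin >= 0 & lin <= 1))
    pct <- voxels(percentileWindow(ctVolume(v)))
    expect_true(all(diff(pct[o]) >= 0))
    gam <- voxels(gammaCorrect(ctVolume(pct), 0.5))
    expect_true(all(diff(gam[o]) >= 0))
  }
})

test_that("percentile windowing is invariant to distribution-preserving permutations", {
  set.seed(5)
  v <- array(rnorm(4^3), c(4, 4, 4))
  p1 <- attr(percentileWindow(ctVolume(v)), "windowBounds")
  vp <- array(sample(v), c(4, 4, 4))
  p2 <- attr(percentileWindow(ctVolume(vp)), "windowBounds")
  expect_equal(p1, p2)
})

test_that("the windowing dispatcher routes and composes correctly", {
  case <- generateCase(testScaleSpec(seed = 41))
  v <- case@volume
  # min-max scaling maps a known value as (v - min) / (max - min)
  mm <- applyWindowing(v, windowSpec("none"))
  rng <- range(voxels(v))
  expect_equal(voxels(mm)[1, 1, 1],
               (voxels(v)[1, 1, 1] - rng[1]) / (rng[2] - rng[1]))
  # bone_gamma with gamma 1 equals bone
  bg <- applyWindowing(v, windowSpec("bone_gamma", gamma = 1))
  bo <- applyWindowing(v, windowSpec("bone"))
  expect_identical(voxels(bg), voxels(bo))
  # roi dispatch equals percentileWindow with a mask source
  roi <- applyWindowing(v, windowSpec("roi"), mask = case@densMask)
  direct <- percentileWindow(v, mask = case@densMask, roiDilationMm = 3)
  expect_identical(voxels(roi), voxels(direct))
  expect_error(applyWindowing(v, windowSpec("roi")), "mask")
})
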