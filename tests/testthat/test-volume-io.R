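test_that("NIfTI round trip preserves voxels, spacing and origin", {
  case <- generateCase(testScaleSpec(seed = 21))
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(case@volume, f)
  back <- readVolume(f)
  expect_equal(voxels(back), voxels(case@volume), tolerance = 1e-6)
  expect_equal(voxelSpacing(back), voxelSpacing(case@volume))

  fm <- tempfile(fileext = ".nii.gz")
  writeVolume(case@densMask, fm)
  backMask <- readMask(fm)
  expect_identical(voxels(backMask), voxels(case@densMask))
})

test_that("non-3D images and non-binary masks are rejected", {
  f2d <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(rnorm(64), 8, 8)), f2d)
  expect_error(readVolume(f2d), "3D")

  f3 <- tempfile(fileext = ".nii.gz")
  labeled <- array(sample(0:2, 4^3, replace = TRUE), c(4, 4, 4))
  RNifti::writeNifti(RNifti::asNifti(labeled), f3)
  expect_error(readMask(f3), "outside \\{0, 1\\}")

  suppressWarnings(
    expect_error(readVolume(tempfile(fileext = ".nii")), "readable"))
})

test_that("isotropic resampling preserves extent, identity and the binary value set", {
  v <- ctVolume(array(rnorm(16 * 16 * 8), c(16, 16, 8)), spacing = c(1, 1, 2))
  r <- resampleIsotropic(v, 1)
  expect_equal(dim(r), c(16L, 16L, 16L))
  expect_equal(voxelSpacing(r), c(1, 1, 1))
  # grid-aligned output slices coincide with input slices (exact for
  # linear interpolation at zero fractional offset)
  expect_equal(voxels(r)[, , 5], voxels(v)[, , 3], tolerance = 1e-12)
  # off-grid slices are the midpoint average of their neighbours
  expect_equal(voxels(r)[, , 4],
               (voxels(v)[, , 2] + voxels(v)[, , 3]) / 2, tolerance = 1e-12)

  iso <- ctVolume(array(rnorm(8^3), c(8, 8, 8)), spacing = c(1, 1, 1))
  expect_identical(voxels(resampleIsotropic(iso, 1)), voxels(iso))

  const <- ctVolume(array(7, c(8, 8, 4)), spacing = c(1, 1, 2))
  expect_true(all(abs(voxels(resampleIsotropic(const, 1)) - 7) < 1e-12))

  m <- array(0, c(8, 8, 4)); m[3:5, 3:5, 2:3] <- 1
  rm <- resampleIsotropic(ctMask(m, spacing = c(1, 1, 2)), 0.7)
  expect_true(all(voxels(rm) %in% c(0, 1)))
})

test_that("z-score normalization has zero mean, unit sd, and rejects constants", {
  v <- ctVolume(array(c(rep(0, 32), rep(10, 32)), c(4, 4, 4)))
  z <- zscoreNormalize(v)
  expect_equal(mean(voxels(z)), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean(voxels(z)^2)), 1, tolerance = 1e-6)
  expect_equal(sort(unique(as.numeric(voxels(z)))), c(-1, 1))
  # idempotence
  z2 <- zscoreNormalize(z)
  expect_equal(voxels(z2), voxels(z), tolerance = 1e-6)
  expect_error(zscoreNormalize(ctVolume(array(5, c(4, 4, 4)))), "constant")
})

test_that("padCrop is an exact inverse pair and clamps near-corner centroids", {
  v <- ctVolume(array(rnorm(16^3), c(16, 16, 16)))
  padded <- padCrop(v, 32)
  expect_equal(dim(padded), c(32L, 32L, 32L))
  back <- padCrop(padded, 16)
  expect_identical(voxels(back), voxels(v))

  # a centroid near the corner shifts the window inward
  r <- padCrop(v, 8, center = c(1, 1, 15))
  expect_identical(attr(r, "cropOffset"), c(0L, 0L, 8L))
  expect_identical(voxels(r), voxels(v)[1:8, 1:8, 9:16])

  # hand-computed window for a 6^3 crop about an interior centroid
  r2 <- padCrop(v, 6, center = c(8, 9, 10))
  expect_identical(attr(r2, "cropOffset"), c(5L, 6L, 7L))

  # dens-centroid cropping recentres on the mask
  m <- array(0, c(16, 16, 16)); m[12:14, 12:14, 12:14] <- 1
  rc <- padCrop(v, 6, center = "dens-centroid", mask = ctMask(m))
  expect_identical(attr(rc, "cropOffset"), c(9L, 9L, 9L))
  expect_error(padCrop(v, 6, center = "dens-centroid"), "mask")
})
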