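test_that("first-order features match direct enumeration on worked examples", {
  vol <- ctVolume(array(c(1, 2, 3, 4), c(4, 1, 1)))
  mask <- ctMask(array(1, c(4, 1, 1)))
  f <- firstOrderFeatures(vol, mask)
  expect_equal(f[["fo_mean"]], 2.5)
  expect_equal(f[["fo_variance"]], 1.25)   # population variance
  expect_equal(f[["fo_skewness"]], 0)
  expect_equal(f[["fo_energy"]], 30)

  # constant ROI
  cv <- ctVolume(array(7, c(3, 3, 3)))
  cm <- ctMask(array(1, c(3, 3, 3)))
  fc <- firstOrderFeatures(cv, cm)
  expect_equal(fc[["fo_variance"]], 0)
  expect_equal(fc[["fo_entropy"]], 0)
  expect_equal(fc[["fo_uniformity"]], 1)

  # two values in equal proportion -> 1 bit
  tv <- ctVolume(array(rep(c(0, 10), 4), c(2, 2, 2)))
  ft <- firstOrderFeatures(tv, ctMask(array(1, c(2, 2, 2))))
  expect_equal(ft[["fo_entropy"]], 1)

  expect_error(firstOrderFeatures(vol, ctMask(array(0, c(4, 1, 1)))), "empty")
})

test_that("shape features match closed forms for canonical masks", {
  single <- shapeFeatures(ctMask(array(1, c(1, 1, 1))))
  expect_equal(single[["shape_volume"]], 1)
  expect_equal(single[["shape_surface_area"]], 6)
  expect_equal(single[["shape_sphericity"]], pi^(1 / 3) * 6^(2 / 3) / 6)
  expect_equal(single[["shape_elongation"]], 1)

  cube <- array(0, c(4, 4, 4)); cube[2:3, 2:3, 2:3] <- 1
  fc <- shapeFeatures(ctMask(cube))
  expect_equal(fc[["shape_volume"]], 8)
  expect_equal(fc[["shape_surface_area"]], 24)

  # sphericity invariant under axis permutation
  set.seed(2)
  m <- array(rbinom(5^3, 1, 0.5), c(5, 5, 5))
  s1 <- shapeFeatures(ctMask(m))[["shape_sphericity"]]
  s2 <- shapeFeatures(ctMask(aperm(m, c(3, 1, 2))))[["shape_sphericity"]]
  expect_equal(s1, s2)
})

test_that("GLCM features match the hand-enumerated 3-voxel example", {
  vol <- ctVolume(array(c(10, 20, 10), c(3, 1, 1)))
  mask <- ctMask(array(1, c(3, 1, 1)))
  g <- glcmFeatures(vol, mask, discretizationSpec(nBins = 2))
  # directed pairs along x: (1,2), (2,1), (2,1)+(1,2) symmetrized ->
  # P(1,2) = P(2,1) = 0.5
  expect_equal(g[["glcm_contrast"]], 1)
  expect_equal(g[["glcm_energy"]], 0.5)
  expect_equal(g[["glcm_entropy"]], 1)
  expect_equal(g[["glcm_homogeneity"]], 0.5)

  const <- glcmFeatures(ctVolume(array(5, c(3, 3, 3))),
                        ctMask(array(1, c(3, 3, 3))))
  expect_equal(const[["glcm_contrast"]], 0)
  expect_equal(const[["glcm_energy"]], 1)
  expect_equal(const[["glcm_entropy"]], 0)
  expect_equal(const[["glcm_correlation"]], 1)

  lone <- array(0, c(5, 5, 5)); lone[1, 1, 1] <- 1; lone[5, 5, 5] <- 1
  expect_error(glcmFeatures(ctVolume(array(rnorm(125), c(5, 5, 5))),
                            ctMask(lone)), "degenerate")
})

test_that("every feature equals its brute-force oracle on random tiny ROIs", {
  for (seed in 1:10) {
    roi <- randomTinyROI(seed)
    vol <- ctVolume(roi$vol, spacing = roi$spacing)
    mask <- ctMask(roi$mask, spacing = roi$spacing)
    f <- extractFeatures(vol, mask)
    ref <- c(oracleFirstOrder(roi$vol[roi$mask == 1]),
             oracleShape(roi$mask, roi$spacing),
             tryCatch(oracleGLCM(roi$vol, roi$mask), error = function(e) NULL))
    for (nm in names(ref)) {
      expect_equal(f[[nm]], ref[[nm]], tolerance = 1e-9,
                   label = sprintf("seed %d feature %s", seed, nm))
    }
  }
})

test_that("first-order moments are permutation invariant but GLCM texture is not", {
  set.seed(77)
  v <- array(seq(0, 100, length.out = 64), c(4, 4, 4))
  vs <- array(sample(v), c(4, 4, 4))
  mask <- ctMask(array(1, c(4, 4, 4)))
  f1 <- firstOrderFeatures(ctVolume(v), mask)
  f2 <- firstOrderFeatures(ctVolume(vs), mask)
  expect_equal(f1, f2, tolerance = 1e-12)
  g1 <- glcmFeatures(ctVolume(v), mask)
  g2 <- glcmFeatures(ctVolume(vs), mask)
  expect_false(isTRUE(all.equal(g1[["glcm_contrast"]], g2[["glcm_contrast"]])))
})

test_that("the full feature vector is deterministic, schema-stable and fracture-sensitive", {
  spec <- testScaleSpec(seed = 61, fracture = TRUE, noiseSd = 0,
                        backgroundSd = 0)
  withFrac <- generateCase(spec)
  spec2 <- spec; spec2@fracturePresent <- FALSE
  noFrac <- generateCase(spec2)

  fv1 <- extractFeatures(withFrac@volume, withFrac@densMask)
  fv2 <- extractFeatures(withFrac@volume, withFrac@densMask)
  expect_identical(fv1, fv2)
  expect_identical(names(fv1), featureSchema())
  expect_equal(length(fv1), length(featureSchema()))

  fvn <- extractFeatures(noFrac@volume, noFrac@densMask)
  expect_false(isTRUE(all.equal(fv1[["glcm_contrast"]], fvn[["glcm_contrast"]])))
  expect_false(isTRUE(all.equal(fv1[["fo_variance"]], fvn[["fo_variance"]])))

  # degenerate single-voxel ROI: GLCM sentinel + flag
  lone <- array(0, c(6, 6, 6)); lone[3, 3, 3] <- 1
  fd <- extractFeatures(ctVolume(array(rnorm(216), c(6, 6, 6))), ctMask(lone))
  expect_true(isTRUE(attr(fd, "degenerateTexture")))
  expect_equal(fd[["glcm_contrast"]], 0)
})
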