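# Shared fixtures, generated once per test session.

.fixtures <- new.env(parent = emptyenv())

# 32^3 isotropic test-scale spec
testScaleSpec <- function(seed = 1L, fracture = FALSE, noiseSd = 10,
                          backgroundSd = 5, zBlurSd = 0.5, ...) {
  phantomSpec(gridSize = 32L, voxelSpacing = c(1, 1, 1), densRadius = 5,
              densHeight = 12, fracturePresent = fracture, fractureWidth = 2,
              noiseSd = noiseSd, backgroundSd = backgroundSd,
              zBlurSd = zBlurSd, seed = seed, ...)
}

# the seeded 60-case low-noise cohort used by the pipeline-sanity and
# stability checks
separableCohort60 <- function() {
  if (is.null(.fixtures$cohort60))
    .fixtures$cohort60 <- generateCohort(60, 79 / 366, separablePhantomSpec(),
                                         seed = 1)
  .fixtures$cohort60
}

# oracle-mask ROI-windowed feature table for a small separable cohort
separableFeatures30 <- function() {
  if (is.null(.fixtures$feat30)) {
    cohort <- generateCohort(30, 0.4, separablePhantomSpec(), seed = 7)
    feats <- t(vapply(cohort, function(cs) {
      wv <- applyWindowing(cs@volume, windowSpec("roi"), mask = cs@densMask)
      scaled <- ctVolume(voxels(wv) * 1000, spacing = voxelSpacing(wv))
      extractFeatures(scaled, cs@densMask)
    }, numeric(length(featureSchema()))))
    .fixtures$feat30 <- list(features = feats, labels = cohortLabels(cohort))
  }
  .fixtures$feat30
}
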