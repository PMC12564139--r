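#' Create a phantom specification
#'
#' Constructor for [PhantomSpec-class] with defaults that emulate a dens
#' (odontoid process) CT appearance at desk scale: a cortical shell around a
#' trabecular core embedded in soft tissue, sub-millimetre in-plane spacing
#' with thicker slices, and an optional thin low-intensity fracture cleft.
#'
#' @param gridSize voxels per axis (cubic grid), >= 16. Default 64.
#' @param voxelSpacing numeric(3) mm per axis. Default `c(0.6, 0.6, 1.2)`
#'   (anisotropic, matching routine cervical CT protocols).
#' @param backgroundHu,backgroundSd soft-tissue plateau mean and spatial
#'   heterogeneity SD in HU. Defaults 40 and 10.
#' @param corticalHu cortical shell plateau (default 1200 HU).
#' @param trabecularHu trabecular interior plateau (default 300 HU).
#' @param densRadius,densHeight dens cylinder radius and height in mm
#'   (defaults 6 and 15).
#' @param shellThickness cortical shell thickness in mm (default 1.5).
#' @param fracturePresent logical; add a fracture cleft?
#' @param fractureWidth cleft thickness in mm (default 1.5, i.e. within the
#'   1-2 mm range typical of acute dens fracture lines).
#' @param fractureDisplacement rigid lateral displacement of the distal
#'   fragment in mm; 0 = non-displaced (default).
#' @param fractureAngle tilt of the cleft plane from transverse, degrees.
#' @param noiseSd additive Gaussian noise SD in HU (default 20).
#' @param zBlurSd Gaussian blur SD along z in mm emulating partial-volume
#'   blending from thick slices (default 1).
#' @param seed integer case seed; the same spec reproduces a bit-identical
#'   phantom.
#' @return A validated [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(fracturePresent = TRUE, seed = 7)
#' case <- generateCase(spec)
#' @export
phantomSpec <- function(gridSize = 64L, voxelSpacing = c(0.6, 0.6, 1.2),
                        backgroundHu = 40, backgroundSd = 10,
                        corticalHu = 1200, trabecularHu = 300,
                        densRadius = 6, densHeight = 15, shellThickness = 1.5,
                        fracturePresent = FALSE, fractureWidth = 1.5,
                        fractureDisplacement = 0, fractureAngle = 0,
                        noiseSd = 20, zBlurSd = 1, seed = 1L) {
  new("PhantomSpec", gridSize = as.integer(gridSize),
      voxelSpacing = as.numeric(voxelSpacing),
      backgroundHu = backgroundHu, backgroundSd = backgroundSd,
      corticalHu = corticalHu, trabecularHu = trabecularHu,
      densRadius = densRadius, densHeight = densHeight,
      shellThickness = shellThickness,
      fracturePresent = fracturePresent, fractureWidth = fractureWidth,
      fractureDisplacement = fractureDisplacement, fractureAngle = fractureAngle,
      noiseSd = noiseSd, zBlurSd = zBlurSd, seed = as.integer(seed))
}

# 1D Gaussian blur along z, reflecting at borders; sigma in voxels.
blurZ <- function(a, sigmaVox) {
  if (sigmaVox <= 0) return(a)
  r <- max(1L, ceiling(3 * sigmaVox))
  k <- exp(-((-r:r)^2) / (2 * sigmaVox^2)); k <- k / sum(k)
  d <- dim(a)
  out <- array(0, d)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- pmin(pmax(seq_len(d[3]) + off, 1L), d[3])
    out <- out + k[j] * a[, , src, drop = FALSE]
  }
  out
}

#' Generate one synthetic phantom case
#'
#' Builds a piecewise-constant "clean" volume (soft-tissue background,
#' trabecular core, cortical shell; a fracture cleft at background intensity
#' when requested), optionally displaces the distal fragment rigidly by an
#' integer number of voxels, then applies z-axis Gaussian blur (partial
#' volume) and additive Gaussian noise. All randomness derives from
#' `spec@seed`, so identical specs yield bit-identical cases.
#'
#' The dens mask is the full cylinder (including cleft voxels, as a manual
#' segmentation of the dens would be); the fracture mask is the cleft slab
#' inside the cylinder.
#'
#' @param spec a [PhantomSpec-class].
#' @return A validated [PhantomCase-class].
#' @export
generateCase <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  n <- spec@gridSize
  sp <- spec@voxelSpacing
  halfExtent <- n / 2 * sp
  if (spec@densRadius + 2 * max(sp[1:2]) > min(halfExtent[1:2]))
    stop("densRadius too large for the grid (needs a 2-voxel margin)", call. = FALSE)
  if (spec@densHeight / 2 + 2 * sp[3] > halfExtent[3])
    stop("densHeight too large for the grid (needs a 2-voxel margin)", call. = FALSE)

  withSeed(spec@seed, {
    # world coordinates of voxel centres, centred on the grid middle
    cx <- ((seq_len(n) - 1) - (n - 1) / 2) * sp[1]
    cy <- ((seq_len(n) - 1) - (n - 1) / 2) * sp[2]
    cz <- ((seq_len(n) - 1) - (n - 1) / 2) * sp[3]
    X <- array(cx, c(n, n, n))
    Y <- array(rep(cy, each = n), c(n, n, n))
    Z <- array(rep(cz, each = n * n), c(n, n, n))
    r <- sqrt(X^2 + Y^2)

    dens <- r <= spec@densRadius & abs(Z) <= spec@densHeight / 2
    inner <- r <= (spec@densRadius - spec@shellThickness) &
      abs(Z) <= (spec@densHeight / 2 - spec@shellThickness)
    vol <- array(spec@backgroundHu, c(n, n, n))
    vol[dens] <- spec@corticalHu
    vol[inner] <- spec@trabecularHu

    frac <- array(FALSE, c(n, n, n))
    if (spec@fracturePresent) {
      theta <- spec@fractureAngle * pi / 180
      # signed distance to the cleft plane through the dens centre whose
      # normal is the z axis tilted by theta toward x
      sd <- Z * cos(theta) + X * sin(theta)
      frac <- dens & abs(sd) <= spec@fractureWidth / 2
      vol[frac] <- spec@backgroundHu
      if (spec@fractureDisplacement != 0) {
        shiftVox <- as.integer(round(spec@fractureDisplacement / sp[1]))
        if (shiftVox != 0) {
          fragment <- dens & sd > spec@fractureWidth / 2
          fragVals <- vol[fragment]
          idx <- which(fragment, arr.ind = TRUE)
          vol[fragment] <- spec@backgroundHu
          dens[fragment] <- FALSE
          newIdx <- idx
          newIdx[, 1] <- pmin(pmax(idx[, 1] + shiftVox, 1L), n)
          vol[newIdx] <- fragVals
          dens[newIdx] <- TRUE
          # keep the cleft annotation adjacent to bone after displacement
          frac <- frac & (binaryDilate(array(as.numeric(dens), c(n, n, n))) == 1)
        }
      }
    }

    vol <- blurZ(vol, spec@zBlurSd / sp[3])
    if (spec@backgroundSd > 0) {
      het <- array(rnorm(n^3, 0, spec@backgroundSd), c(n, n, n))
      vol[!dens] <- vol[!dens] + het[!dens]
    }
    if (spec@noiseSd > 0)
      vol <- vol + array(rnorm(n^3, 0, spec@noiseSd), c(n, n, n))

    new("PhantomCase",
        volume = ctVolume(vol, spacing = sp),
        densMask = ctMask(array(as.numeric(dens), c(n, n, n)), spacing = sp),
        fractureMask = ctMask(array(as.numeric(frac), c(n, n, n)), spacing = sp),
        label = any(frac), spec = spec)
  })
}

#' Generate a seeded cohort of phantom cases
#'
#' Draws `n` cases from jittered copies of `baseSpec`. Exactly
#' `round(n * fracturePrevalence)` cases carry a fracture; which indices they
#' are, and each case's jitter (dens radius and height, cleft angle and
#' width, displacement, noise), is determined by a per-case seed derived from
#' `(seed, case index)`, so cohorts are reproducible and order-independent.
#'
#' The default prevalence, 79/366, matches the class imbalance of a clinical
#' dens-fracture cohort (287 cases without and 79 with fracture).
#'
#' @param n number of cases (>= 1).
#' @param fracturePrevalence fraction of fracture cases in `[0, 1]`.
#' @param baseSpec template [PhantomSpec-class].
#' @param seed cohort seed.
#' @param jitter logical; apply per-case geometric/noise jitter (default TRUE).
#' @return List of [PhantomCase-class] objects.
#' @examples
#' cohort <- generateCohort(10, 0.3, phantomSpec(gridSize = 32,
#'   densRadius = 4.5, densHeight = 10), seed = 1)
#' sum(vapply(cohort, function(x) x@label, logical(1)))
#' @export
generateCohort <- function(n, fracturePrevalence = 79 / 366,
                           baseSpec = phantomSpec(), seed = 1L, jitter = TRUE) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (fracturePrevalence < 0 || fracturePrevalence > 1)
    stop("fracturePrevalence must lie in [0, 1]", call. = FALSE)
  nFrac <- round(n * fracturePrevalence)
  fracIdx <- withSeed(seed, sample.int(n, nFrac))
  lapply(seq_len(n), function(i) {
    caseSeed <- deriveSeed(seed, i)
    sp <- baseSpec
    sp@seed <- caseSeed
    sp@fracturePresent <- i %in% fracIdx
    if (jitter) {
      withSeed(deriveSeed(caseSeed, 1L), {
        sp@densRadius <- baseSpec@densRadius * runif(1, 0.9, 1.1)
        sp@densHeight <- baseSpec@densHeight * runif(1, 0.9, 1.1)
        sp@noiseSd <- baseSpec@noiseSd * runif(1, 0.8, 1.2)
        if (sp@fracturePresent) {
          sp@fractureAngle <- runif(1, -30, 30)
          sp@fractureWidth <- runif(1, max(0.5, baseSpec@fractureWidth * 0.75),
                                    baseSpec@fractureWidth * 1.25)
          sp@fractureDisplacement <- if (runif(1) < 0.5) 0 else runif(1, 1, 3)
        }
      })
    }
    generateCase(sp)
  })
}

#' Desk-scale phantom specification with a strong fracture signal
#'
#' A 32^3, 1 mm isotropic template whose fracture cleft is wide (2.5 mm) and
#' whose noise is low (5 HU), so the fracture signal is well separated from
#' the noise floor. This is the cohort template used by the package's
#' pipeline-sanity and stability experiments: on cohorts drawn from it, a
#' correctly wired pipeline should classify nearly perfectly, so failures
#' indicate plumbing defects rather than a hard learning problem.
#'
#' @param seed case seed (overridden per case by [generateCohort()]).
#' @return A [PhantomSpec-class].
#' @export
separablePhantomSpec <- function(seed = 1L) {
  phantomSpec(gridSize = 32L, voxelSpacing = c(1, 1, 1),
              densRadius = 5, densHeight = 12, shellThickness = 1.5,
              fractureWidth = 2.5, noiseSd = 5, backgroundSd = 5,
              zBlurSd = 0.5, seed = seed)
}

#' Fracture labels of a cohort
#' @param cohort list of [PhantomCase-class].
#' @return Logical vector of per-case fracture labels.
#' @export
cohortLabels <- function(cohort) {
  vapply(cohort, function(x) x@label, logical(1))
}
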