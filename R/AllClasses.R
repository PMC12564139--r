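#' 3D CT volume with voxel-spacing metadata
#'
#' `CTVolume` is the package's central image container: a 3D array of
#' Hounsfield-unit (or normalized) intensities together with voxel spacing
#' (mm per axis) and a world-space origin (mm). Voxel indices are 0-based in
#' world-coordinate arithmetic: `world = origin + index * spacing`.
#'
#' @slot voxels 3D numeric array of intensities.
#' @slot spacing numeric(3), mm per axis, strictly positive.
#' @slot origin numeric(3), world coordinate (mm) of voxel (0,0,0).
#'
#' @seealso [ctVolume()], [CTMask-class]
#' @export
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (!all(is.finite(object@voxels)))
    msg <- c(msg, "voxels must be finite everywhere")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values")
  if (length(msg)) msg else TRUE
})

#' Binary 3D mask aligned with a CTVolume
#'
#' A `CTMask` is a `CTVolume` whose voxel values are restricted to {0, 1}.
#' It is used for dens segmentations and fracture-cleft annotations, and is
#' expected to share grid shape and spacing with its paired volume.
#'
#' @seealso [ctMask()], [CTVolume-class]
#' @export
setClass("CTMask", contains = "CTVolume")

setValidity("CTMask", function(object) {
  v <- object@voxels
  if (!all(v == 0 | v == 1))
    return("mask voxels must all be 0 or 1")
  TRUE
})

#' Parameter set describing one synthetic dens phantom
#'
#' A `PhantomSpec` holds every parameter of the synthetic bone-phantom
#' generator: grid geometry, tissue intensity plateaus (HU), dens cylinder
#' geometry (mm), fracture-cleft parameters, noise and partial-volume
#' controls, and the case seed. Given the same spec, [generateCase()]
#' reproduces a bit-identical phantom.
#'
#' Intensity defaults follow typical CT appearance: cortical shell ~1200 HU,
#' trabecular interior ~300 HU, soft-tissue background ~40 +/- 10 HU; the
#' anisotropic default spacing mirrors routine cervical-spine protocols
#' (sub-millimetre in-plane, 1-2 mm slices).
#'
#' @slot gridSize integer, voxels per axis (cubic grid, >= 16).
#' @slot voxelSpacing numeric(3), mm per axis.
#' @slot backgroundHu,backgroundSd soft-tissue mean and heterogeneity SD (HU).
#' @slot corticalHu,trabecularHu shell and interior plateau means (HU).
#' @slot densRadius,densHeight,shellThickness dens cylinder geometry (mm).
#' @slot fracturePresent logical flag.
#' @slot fractureWidth cleft thickness (mm), > 0 when a fracture is present.
#' @slot fractureDisplacement rigid lateral shift of the distal fragment (mm);
#'   0 means non-displaced.
#' @slot fractureAngle tilt of the cleft plane away from transverse (degrees).
#' @slot noiseSd additive Gaussian noise SD (HU).
#' @slot zBlurSd Gaussian blur SD along z (mm), emulating partial volume.
#' @slot seed integer case seed.
#'
#' @seealso [phantomSpec()], [generateCase()]
#' @export
setClass("PhantomSpec",
  representation(
    gridSize = "integer", voxelSpacing = "numeric",
    backgroundHu = "numeric", backgroundSd = "numeric",
    corticalHu = "numeric", trabecularHu = "numeric",
    densRadius = "numeric", densHeight = "numeric", shellThickness = "numeric",
    fracturePresent = "logical", fractureWidth = "numeric",
    fractureDisplacement = "numeric", fractureAngle = "numeric",
    noiseSd = "numeric", zBlurSd = "numeric", seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@gridSize < 16L)
    msg <- c(msg, "gridSize must be >= 16")
  if (!(object@corticalHu > object@trabecularHu &&
        object@trabecularHu > object@backgroundHu))
    msg <- c(msg, "intensity ordering corticalHu > trabecularHu > backgroundHu violated")
  if (object@fracturePresent && object@fractureWidth <= 0)
    msg <- c(msg, "fractureWidth must be > 0 when fracturePresent")
  if (any(object@voxelSpacing <= 0))
    msg <- c(msg, "voxelSpacing must be strictly positive")
  if (object@densRadius <= 0 || object@densHeight <= 0 || object@shellThickness <= 0)
    msg <- c(msg, "dens geometry must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' One synthetic phantom case
#'
#' Bundles the generated volume, the ground-truth dens mask, the fracture
#' cleft mask (empty when no fracture), the binary fracture label and the
#' generating [PhantomSpec-class]. Class invariants: the label is `TRUE` iff
#' the fracture mask is non-empty, and the fracture mask lies within a
#' 1-voxel dilation of the dens mask.
#'
#' @slot volume [CTVolume-class] of intensities in HU.
#' @slot densMask,fractureMask [CTMask-class] ground-truth masks.
#' @slot label logical fracture status.
#' @slot spec generating [PhantomSpec-class].
#'
#' @seealso [generateCase()], [generateCohort()]
#' @export
setClass("PhantomCase",
  representation(
    volume = "CTVolume", densMask = "CTMask", fractureMask = "CTMask",
    label = "logical", spec = "PhantomSpec"
  )
)

setValidity("PhantomCase", function(object) {
  msg <- character()
  dv <- dim(object@volume@voxels)
  if (!identical(dv, dim(object@densMask@voxels)) ||
      !identical(dv, dim(object@fractureMask@voxels)))
    msg <- c(msg, "volume and masks must share one grid shape")
  hasFrac <- sum(object@fractureMask@voxels) > 0
  if (!identical(object@label, hasFrac))
    msg <- c(msg, "label must be TRUE iff fractureMask is non-empty")
  if (hasFrac) {
    dil <- binaryDilate(object@densMask@voxels, iterations = 1L)
    if (any(object@fractureMask@voxels > dil))
      msg <- c(msg, "fractureMask must lie within a 1-voxel dilation of densMask")
  }
  if (length(msg)) msg else TRUE
})
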