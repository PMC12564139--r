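#' Construct a CTVolume
#'
#' @param voxels 3D numeric array.
#' @param spacing numeric(3) voxel spacing in mm (default 1 mm isotropic).
#' @param origin numeric(3) world origin in mm.
#' @return A validated [CTVolume-class].
#' @examples
#' v <- ctVolume(array(0, c(8, 8, 8)), spacing = c(0.5, 0.5, 2))
#' dim(v)
#' @export
ctVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a CTMask
#'
#' @param voxels 3D array of 0/1 (logical arrays are coerced).
#' @inheritParams ctVolume
#' @return A validated [CTMask-class].
#' @export
ctMask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(voxels) <- "double"
  new("CTMask", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Read a 3D NIfTI volume
#'
#' Reads a `.nii` / `.nii.gz` file into a [CTVolume-class], carrying voxel
#' spacing from the NIfTI pixdim and the translation part of the affine as
#' origin. Non-3D images are rejected.
#'
#' @param path path to a NIfTI file.
#' @return A [CTVolume-class].
#' @seealso [writeVolume()], [readMask()]
#' @export
readVolume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ",
                                           conditionMessage(e), call. = FALSE))
  a <- as.array(img)
  a <- array(as.numeric(a), dim(a))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L)
    stop("expected a 3D image, got ", length(dim(a)), " dimensions", call. = FALSE)
  pd <- RNifti::pixdim(img)[seq_len(3)]
  xf <- RNifti::xform(img)
  tr <- if (is.matrix(xf) && all(dim(xf) == c(4, 4))) xf[1:3, 4] else c(0, 0, 0)
  ctVolume(a, spacing = pd, origin = tr)
}

#' Read a binary mask from NIfTI
#'
#' As [readVolume()] but validates that the image is strictly binary; values
#' outside {0, 1} raise a validation error.
#'
#' @inheritParams readVolume
#' @return A [CTMask-class].
#' @export
readMask <- function(path) {
  v <- readVolume(path)
  if (!all(v@voxels %in% c(0, 1)))
    stop("mask file contains values outside {0, 1}", call. = FALSE)
  ctMask(v@voxels, spacing = v@spacing, origin = v@origin)
}

#' Write a volume or mask to NIfTI
#'
#' Round-tripping through [writeVolume()] and [readVolume()] preserves the
#' voxel grid, spacing and origin.
#'
#' @param vol a [CTVolume-class] or [CTMask-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "CTVolume"))
  img <- RNifti::asNifti(vol@voxels)
  RNifti::pixdim(img) <- vol@spacing
  sf <- diag(c(vol@spacing, 1))
  sf[1:3, 4] <- vol@origin
  RNifti::qform(img) <- structure(sf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Trilinear / nearest sampling of a 3D array at fractional voxel coordinates
# given as per-axis position vectors (0-based). Returns an array of
# length(px) x length(py) x length(pz).
sampleGrid <- function(a, px, py, pz, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(a)
  clamp <- function(p, n) pmin(pmax(p, 0), n - 1)
  px <- clamp(px, d[1]); py <- clamp(py, d[2]); pz <- clamp(pz, d[3])
  if (mode == "nearest") {
    ix <- round(px) + 1; iy <- round(py) + 1; iz <- round(pz) + 1
    return(array(a[cbind(rep(ix, times = length(iy) * length(iz)),
                         rep(rep(iy, each = length(ix)), times = length(iz)),
                         rep(iz, each = length(ix) * length(iy)))],
                 c(length(ix), length(iy), length(iz))))
  }
  x0 <- pmin(floor(px), d[1] - 2); fx <- px - x0
  y0 <- pmin(floor(py), d[2] - 2); fy <- py - y0
  z0 <- pmin(floor(pz), d[3] - 2); fz <- pz - z0
  if (d[1] == 1) { x0 <- rep(0, length(px)); fx <- rep(0, length(px)) }
  if (d[2] == 1) { y0 <- rep(0, length(py)); fy <- rep(0, length(py)) }
  if (d[3] == 1) { z0 <- rep(0, length(pz)); fz <- rep(0, length(pz)) }
  nx <- length(px); ny <- length(py); nz <- length(pz)
  FX <- array(fx, c(nx, ny, nz))
  FY <- array(rep(fy, each = nx), c(nx, ny, nz))
  FZ <- array(rep(fz, each = nx * ny), c(nx, ny, nz))
  out <- array(0, c(nx, ny, nz))
  gx <- function(o) pmin(x0 + o, d[1] - 1) + 1
  gy <- function(o) pmin(y0 + o, d[2] - 1) + 1
  gz <- function(o) pmin(z0 + o, d[3] - 1) + 1
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    w <- (if (ox == 1) FX else 1 - FX) *
         (if (oy == 1) FY else 1 - FY) *
         (if (oz == 1) FZ else 1 - FZ)
    idx <- cbind(rep(gx(ox), times = ny * nz),
                 rep(rep(gy(oy), each = nx), times = nz),
                 rep(gz(oz), each = nx * ny))
    out <- out + w * array(a[idx], c(nx, ny, nz))
  }
  out
}

#' Resample a volume to isotropic resolution
#'
#' Resamples to a grid with identical spacing `targetMm` on every axis,
#' preserving physical extent to within one voxel. Intensity volumes should
#' use linear (trilinear) interpolation and masks nearest-neighbour, which
#' preserves the binary value set.
#'
#' @param vol a [CTVolume-class] or [CTMask-class].
#' @param targetMm target isotropic spacing in mm (default 1).
#' @param mode `"linear"` or `"nearest"`; defaults to `"nearest"` for masks
#'   and `"linear"` otherwise.
#' @return Resampled object of the same class as `vol`.
#' @examples
#' v <- ctVolume(array(rnorm(64 * 64 * 32), c(64, 64, 32)), spacing = c(1, 1, 2))
#' dim(resampleIsotropic(v, 1))
#' @export
resampleIsotropic <- function(vol, targetMm = 1,
                              mode = if (is(vol, "CTMask")) "nearest" else "linear") {
  stopifnot(is(vol, "CTVolume"))
  assertScalarNumeric(targetMm, "targetMm", positive = TRUE)
  mode <- match.arg(mode, c("linear", "nearest"))
  d <- dim(vol@voxels); sp <- vol@spacing
  if (all(abs(sp - targetMm) < 1e-12)) return(vol)
  nOut <- pmax(1L, as.integer(round(d * sp / targetMm)))
  pos <- lapply(1:3, function(ax) (seq_len(nOut[ax]) - 1) * targetMm / sp[ax])
  out <- sampleGrid(vol@voxels, pos[[1]], pos[[2]], pos[[3]], mode)
  if (is(vol, "CTMask"))
    ctMask(out, spacing = rep(targetMm, 3), origin = vol@origin)
  else
    ctVolume(out, spacing = rep(targetMm, 3), origin = vol@origin)
}

#' Z-score normalize a volume
#'
#' Subtracts the mean intensity and divides by the (population) standard
#' deviation, so the output has mean 0 and SD 1 (within 1e-6). Used to
#' standardize neural-network inputs after windowing.
#'
#' @param vol a [CTVolume-class].
#' @return Normalized [CTVolume-class].
#' @export
zscoreNormalize <- function(vol) {
  stopifnot(is(vol, "CTVolume"))
  v <- vol@voxels
  s <- sqrt(mean((v - mean(v))^2))
  if (!is.finite(s) || s == 0)
    stop("cannot z-score a constant volume (sd = 0)", call. = FALSE)
  ctVolume((v - mean(v)) / s, spacing = vol@spacing, origin = vol@origin)
}

#' Pad and/or crop a volume to a target shape
#'
#' Produces a grid of exactly `targetDim` voxels, zero-padding where the
#' window extends beyond the input and cropping where the input exceeds it.
#' The window is centred on `center` (0-based voxel index, or the centroid of
#' `mask` when `center = "dens-centroid"`), clamped so it never leaves the
#' input bounds; with even target sizes the tie is broken toward the lower
#' index.
#'
#' @param vol a [CTVolume-class] or [CTMask-class].
#' @param targetDim integer(3) output shape.
#' @param center numeric(3) 0-based voxel index, `NULL` (volume centre), or
#'   `"dens-centroid"` (requires `mask`).
#' @param mask optional [CTMask-class] used when `center = "dens-centroid"`.
#' @param padValue fill value for padded voxels (default 0).
#' @return Object of the same class as `vol`, with attribute `"cropOffset"`
#'   giving the 0-based input index of the output's first voxel (may be
#'   negative when padding).
#' @export
padCrop <- function(vol, targetDim, center = NULL, mask = NULL, padValue = 0) {
  stopifnot(is(vol, "CTVolume"))
  targetDim <- as.integer(targetDim)
  if (length(targetDim) == 1L) targetDim <- rep(targetDim, 3L)
  if (any(targetDim < 1L)) stop("targetDim must be >= 1 per axis", call. = FALSE)
  d <- dim(vol@voxels)
  if (is.character(center) && identical(center, "dens-centroid")) {
    if (is.null(mask)) stop("center = 'dens-centroid' requires a mask", call. = FALSE)
    center <- maskCentroid(mask)
  }
  if (is.null(center)) center <- (d - 1) / 2
  s <- integer(3)
  for (ax in 1:3) {
    # window start so the centroid sits at the window centre; with even
    # target sizes the tie breaks toward the lower index
    st <- as.integer(floor(center[ax] - (targetDim[ax] - 1) / 2 + 1e-9))
    lo <- min(0L, d[ax] - targetDim[ax]); hi <- max(0L, d[ax] - targetDim[ax])
    s[ax] <- min(max(st, lo), hi)
  }
  out <- array(padValue, targetDim)
  inLo <- pmax(s, 0); inHi <- pmin(d, s + targetDim)
  outLo <- inLo - s
  out[(outLo[1] + 1):(outLo[1] + inHi[1] - inLo[1]),
      (outLo[2] + 1):(outLo[2] + inHi[2] - inLo[2]),
      (outLo[3] + 1):(outLo[3] + inHi[3] - inLo[3])] <-
    vol@voxels[(inLo[1] + 1):inHi[1], (inLo[2] + 1):inHi[2], (inLo[3] + 1):inHi[3]]
  res <- if (is(vol, "CTMask"))
    ctMask(out, spacing = vol@spacing, origin = vol@origin + s * vol@spacing)
  else
    ctVolume(out, spacing = vol@spacing, origin = vol@origin + s * vol@spacing)
  attr(res, "cropOffset") <- s
  res
}

#' Centroid of a mask in 0-based voxel indices
#' @param mask a [CTMask-class].
#' @return numeric(3) centroid (0-based voxel coordinates).
#' @export
maskCentroid <- function(mask) {
  stopifnot(is(mask, "CTMask"))
  idx <- which(mask@voxels == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty", call. = FALSE)
  colMeans(idx) - 1
}
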