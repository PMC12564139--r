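#' Specify a windowing / contrast-adjustment method
#'
#' Describes one of six intensity transforms applied to an HU volume before
#' segmentation, classification or radiomics: `none` (min-max scaling),
#' `bone` (linear bone window), `bone_gamma` (bone window followed by gamma
#' correction), `histogram` (whole-image 5th-95th percentile window),
#' `clahe` (slice-wise contrast-limited adaptive histogram equalization) and
#' `roi` (percentile window computed inside a segmentation mask plus its
#' immediate surroundings, applied to the whole image).
#'
#' Defaults follow standard clinical practice for bone: window level 400 HU,
#' window width 2000 HU, gamma in {0.5, 1, 2}, 5th/95th percentile bounds.
#'
#' @param method one of `"none"`, `"bone"`, `"bone_gamma"`, `"histogram"`,
#'   `"clahe"`, `"roi"`.
#' @param level,width window level and width in HU (defaults 400 and 2000).
#' @param gamma gamma exponent (> 0, default 1).
#' @param loPct,hiPct percentile bounds, `0 <= loPct < hiPct <= 100`
#'   (defaults 5 and 95).
#' @param claheClip CLAHE clip limit as a fraction of tile pixels per
#'   histogram bin (default 0.01).
#' @param claheTiles CLAHE tiles per in-plane axis (default 8).
#' @param roiDilationMm Euclidean dilation radius (mm) defining the ROI's
#'   immediate surroundings (default 3).
#' @return A list of class `"WindowSpec"`.
#' @export
windowSpec <- function(method = c("none", "bone", "bone_gamma", "histogram",
                                  "clahe", "roi"),
                       level = 400, width = 2000, gamma = 1,
                       loPct = 5, hiPct = 95,
                       claheClip = 0.01, claheTiles = 8L, roiDilationMm = 3) {
  method <- match.arg(method)
  assertScalarNumeric(width, "width", positive = TRUE)
  assertScalarNumeric(gamma, "gamma", positive = TRUE)
  if (!(loPct >= 0 && loPct < hiPct && hiPct <= 100))
    stop("need 0 <= loPct < hiPct <= 100", call. = FALSE)
  structure(list(method = method, level = level, width = width, gamma = gamma,
                 loPct = loPct, hiPct = hiPct, claheClip = claheClip,
                 claheTiles = as.integer(claheTiles),
                 roiDilationMm = roiDilationMm),
            class = "WindowSpec")
}

withVoxels <- function(vol, v) ctVolume(v, spacing = vol@spacing, origin = vol@origin)

#' Linear HU windowing
#'
#' Maps the HU interval `[level - width/2, level + width/2]` linearly onto
#' `[0, 1]`, clipping outside; the classic display window, here as a
#' monotone preprocessing transform.
#'
#' @param vol a [CTVolume-class] in HU.
#' @param level,width window level and width in HU (`width > 0`).
#' @return Normalized [CTVolume-class] with values in `[0, 1]`.
#' @examples
#' v <- ctVolume(array(c(-600, 400, 900, 1400), c(4, 1, 1)))
#' voxels(windowLinear(v, 400, 2000))
#' @export
windowLinear <- function(vol, level = 400, width = 2000) {
  stopifnot(is(vol, "CTVolume"))
  if (!is.numeric(width) || width <= 0) stop("width must be > 0", call. = FALSE)
  v <- (vol@voxels - (level - width / 2)) / width
  withVoxels(vol, pmin(pmax(v, 0), 1))
}

#' Gamma correction of a normalized volume
#'
#' Applies `v^gamma` pointwise. Gamma < 1 brightens dark regions, gamma > 1
#' darkens; gamma = 1 is the identity. Input must already lie in `[0, 1]`.
#'
#' @param vol a normalized [CTVolume-class] with values in `[0, 1]`.
#' @param gamma exponent, > 0.
#' @return [CTVolume-class] with values in `[0, 1]`.
#' @export
gammaCorrect <- function(vol, gamma) {
  stopifnot(is(vol, "CTVolume"))
  assertScalarNumeric(gamma, "gamma", positive = TRUE)
  v <- vol@voxels
  if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
    stop("gammaCorrect expects input in [0, 1]; window the volume first",
         call. = FALSE)
  withVoxels(vol, pmin(pmax(v, 0), 1)^gamma)
}

#' Percentile-based windowing (histogram or ROI source)
#'
#' Computes low/high percentile bounds of the intensity distribution --
#' either over the whole image or over a mask dilated by `roiDilationMm`
#' (the ROI and its immediate surroundings) -- and maps `[p_lo, p_hi]`
#' linearly to `[0, 1]` with clipping, applied to the entire volume
#' regardless of the source region. Percentiles use linear interpolation
#' between order statistics.
#'
#' @param vol a [CTVolume-class] in HU.
#' @param loPct,hiPct percentile bounds (defaults 5 and 95).
#' @param mask optional [CTMask-class]; when given, percentiles are computed
#'   inside the dilated mask.
#' @param roiDilationMm dilation radius in mm for the mask source (default 3).
#' @return Normalized [CTVolume-class].
#' @export
percentileWindow <- function(vol, loPct = 5, hiPct = 95, mask = NULL,
                             roiDilationMm = 3) {
  stopifnot(is(vol, "CTVolume"))
  if (!(loPct >= 0 && loPct < hiPct && hiPct <= 100))
    stop("need 0 <= loPct < hiPct <= 100", call. = FALSE)
  if (is.null(mask)) {
    src <- vol@voxels
  } else {
    stopifnot(is(mask, "CTMask"))
    if (sum(mask@voxels) == 0) stop("percentile source mask is empty", call. = FALSE)
    dil <- dilateMm(mask, roiDilationMm)
    src <- vol@voxels[dil@voxels == 1]
  }
  p <- stats::quantile(src, c(loPct, hiPct) / 100, names = FALSE, type = 7)
  if (p[1] >= p[2])
    stop("degenerate window: percentile bounds coincide (constant region)",
         call. = FALSE)
  v <- (vol@voxels - p[1]) / (p[2] - p[1])
  out <- withVoxels(vol, pmin(pmax(v, 0), 1))
  attr(out, "windowBounds") <- p
  out
}

#' Slice-wise contrast-limited adaptive histogram equalization
#'
#' Applies CLAHE independently to each axial (xy) slice of a volume already
#' scaled to `[0, 1]`, with `tiles x tiles` contextual regions and a clip
#' limit expressed as the fraction of tile pixels a histogram bin may hold.
#' Constant slices are passed through unchanged (a flat histogram carries no
#' contrast to redistribute; this also keeps pure-background slices stable).
#'
#' @param vol a [CTVolume-class] with values in `[0, 1]`.
#' @param clip clip limit (fraction of tile pixels per bin, default 0.01).
#' @param tiles contextual regions per in-plane axis (default 8).
#' @param bins histogram bins (default 256).
#' @return [CTVolume-class] with values in `[0, 1]`.
#' @export
claheSlicewise <- function(vol, clip = 0.01, tiles = 8L, bins = 256L) {
  stopifnot(is(vol, "CTVolume"))
  if (tiles < 1) stop("tiles must be >= 1", call. = FALSE)
  v <- vol@voxels
  if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
    stop("claheSlicewise expects input in [0, 1]", call. = FALSE)
  limit <- max(clip * bins, 1)
  out <- v
  for (k in seq_len(dim(v)[3])) {
    sl <- v[, , k]
    if (max(sl) - min(sl) < 1e-12) next
    eq <- EBImage::clahe(sl, nx = as.integer(tiles), ny = as.integer(tiles),
                         bins = as.integer(bins), limit = limit)
    out[, , k] <- pmin(pmax(as.numeric(eq), 0), 1)
  }
  withVoxels(vol, out)
}

#' Apply a windowing method to a volume
#'
#' Dispatcher over the six contrast-adjustment methods of [windowSpec()].
#' `none` min-max scales the volume; `bone_gamma` is [windowLinear()]
#' followed by [gammaCorrect()]; `roi` requires a mask.
#'
#' @param vol a [CTVolume-class] in HU.
#' @param spec a `WindowSpec` from [windowSpec()].
#' @param mask optional [CTMask-class]; required when `spec$method == "roi"`.
#' @return Normalized [CTVolume-class] with values in `[0, 1]`.
#' @export
applyWindowing <- function(vol, spec, mask = NULL) {
  stopifnot(is(vol, "CTVolume"), inherits(spec, "WindowSpec"))
  minMax <- function(v) {
    rng <- range(v@voxels)
    if (rng[1] == rng[2])
      stop("cannot min-max scale a constant volume", call. = FALSE)
    withVoxels(v, (v@voxels - rng[1]) / (rng[2] - rng[1]))
  }
  switch(spec$method,
    none = minMax(vol),
    bone = windowLinear(vol, spec$level, spec$width),
    bone_gamma = gammaCorrect(windowLinear(vol, spec$level, spec$width),
                              spec$gamma),
    histogram = percentileWindow(vol, spec$loPct, spec$hiPct),
    clahe = claheSlicewise(minMax(vol), clip = spec$claheClip,
                           tiles = spec$claheTiles),
    roi = {
      if (is.null(mask))
        stop("method 'roi' requires a segmentation mask", call. = FALSE)
      percentileWindow(vol, spec$loPct, spec$hiPct, mask = mask,
                       roiDilationMm = spec$roiDilationMm)
    })
}
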