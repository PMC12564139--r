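#' Specify gray-level discretization for histogram and texture features
#'
#' @param strategy `"fixed-bin-count"` (default) or `"fixed-bin-width"`.
#'   Fixed bin count is robust across windowing methods that rescale
#'   intensities, which is why it is the package default.
#' @param nBins number of bins for fixed-bin-count (>= 2, default 32).
#' @param binWidth bin width for fixed-bin-width (> 0).
#' @return A list of class `"DiscretizationSpec"`.
#' @export
discretizationSpec <- function(strategy = c("fixed-bin-count", "fixed-bin-width"),
                               nBins = 32L, binWidth = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "fixed-bin-count" && nBins < 2)
    stop("nBins must be >= 2", call. = FALSE)
  if (strategy == "fixed-bin-width" &&
      (is.null(binWidth) || binWidth <= 0))
    stop("binWidth must be > 0", call. = FALSE)
  structure(list(strategy = strategy, nBins = as.integer(nBins),
                 binWidth = binWidth),
            class = "DiscretizationSpec")
}

# Map ROI intensities to integer gray levels 1..L.
discretizeValues <- function(v, disc) {
  if (disc$strategy == "fixed-bin-count") {
    lo <- min(v); hi <- max(v)
    if (hi == lo) return(list(levels = rep(1L, length(v)), L = 1L))
    g <- pmin(pmax(floor((v - lo) / (hi - lo) * disc$nBins) + 1L, 1L), disc$nBins)
    list(levels = as.integer(g), L = disc$nBins)
  } else {
    g <- floor(v / disc$binWidth) - floor(min(v) / disc$binWidth) + 1L
    list(levels = as.integer(g), L = as.integer(max(g)))
  }
}

#' First-order (intensity histogram) features of a masked region
#'
#' Moments are computed on the raw masked intensities using population
#' (biased) definitions: variance `m2`, skewness `m3/m2^1.5`, kurtosis
#' `m4/m2^2` (Pearson, not excess). Percentiles use linear interpolation
#' between order statistics. Entropy (bits) and uniformity are computed on
#' the discretized histogram. Degenerate constant regions have skewness and
#' kurtosis reported as 0.
#'
#' @param vol a [CTVolume-class].
#' @param mask a non-empty [CTMask-class] of the same shape.
#' @param disc a [discretizationSpec()].
#' @return Named numeric vector of 14 `fo_*` features.
#' @export
firstOrderFeatures <- function(vol, mask, disc = discretizationSpec()) {
  v <- maskedValues(vol, mask)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  sk <- if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0
  ku <- if (m2 > 0) mean((v - m)^4) / m2^2 else 0
  q <- stats::quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  dz <- discretizeValues(v, disc)
  p <- tabulate(dz$levels, nbins = dz$L) / length(v)
  p <- p[p > 0]
  c(fo_mean = m, fo_variance = m2, fo_skewness = sk, fo_kurtosis = ku,
    fo_min = min(v), fo_max = max(v), fo_range = max(v) - min(v),
    fo_median = q[3], fo_p10 = q[1], fo_p90 = q[5], fo_iqr = q[4] - q[2],
    fo_energy = sum(v^2), fo_entropy = -sum(p * log2(p)),
    fo_uniformity = sum(p^2))
}

maskedValues <- function(vol, mask) {
  stopifnot(is(vol, "CTVolume"), is(mask, "CTMask"))
  if (!identical(dim(vol@voxels), dim(mask@voxels)))
    stop("volume and mask shapes differ", call. = FALSE)
  v <- vol@voxels[mask@voxels == 1]
  if (length(v) == 0) stop("empty ROI: mask has no foreground voxels", call. = FALSE)
  v
}

#' Shape features of a mask
#'
#' Volume is voxel count times voxel volume; surface area counts exposed
#' voxel faces (systematically larger than a mesh-based area, but exactly
#' reproducible by brute-force enumeration); sphericity is
#' `pi^(1/3) (6V)^(2/3) / A`; elongation is `sqrt(lambda2 / lambda1)` of the
#' two largest principal values of the physical voxel-coordinate covariance
#' (1 for a degenerate single-voxel region).
#'
#' @param mask a non-empty [CTMask-class].
#' @return Named numeric vector of 4 `shape_*` features.
#' @export
shapeFeatures <- function(mask) {
  stopifnot(is(mask, "CTMask"))
  a <- mask@voxels
  nvox <- sum(a)
  if (nvox == 0) stop("empty ROI: mask has no foreground voxels", call. = FALSE)
  sp <- mask@spacing
  vol <- nvox * prod(sp)
  area <- 0
  faceArea <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  for (ax in 1:3) for (s in c(-1L, 1L))
    area <- area + faceArea[ax] * sum(a == 1 & shiftArray(a, ax, s, fill = 0) == 0)
  spher <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  idx <- which(a == 1, arr.ind = TRUE)
  xyz <- sweep(idx - 1, 2, sp, `*`)
  elong <- 1
  if (nvox > 1) {
    cc <- crossprod(sweep(xyz, 2, colMeans(xyz))) / nvox
    ev <- sort(eigen(cc, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    elong <- if (ev[1] > 0) sqrt(max(ev[2], 0) / ev[1]) else 1
  }
  c(shape_volume = vol, shape_surface_area = area, shape_sphericity = spher,
    shape_elongation = elong)
}

# The 13 unique nearest-neighbour 3D offsets (one per +/- direction pair).
glcmOffsets <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), ]
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
    (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0)
  offs[keep, , drop = FALSE]
}

#' Gray-level co-occurrence (GLCM) texture features
#'
#' Discretizes the masked intensities, counts co-occurrences between voxel
#' pairs that both lie inside the mask over the 13 unique distance-1 3D
#' offsets, symmetrizes and normalizes each offset's matrix, computes
#' contrast, correlation, angular second moment (energy), inverse difference
#' moment (homogeneity) and entropy (bits) per offset, and averages the
#' features over offsets with at least one pair. Correlation of a constant
#' region (zero marginal variance) is defined as 1.
#'
#' @inheritParams firstOrderFeatures
#' @return Named numeric vector of 5 `glcm_*` features.
#' @export
glcmFeatures <- function(vol, mask, disc = discretizationSpec()) {
  v <- maskedValues(vol, mask)
  d <- dim(vol@voxels)
  dz <- discretizeValues(v, disc)
  L <- dz$L
  g <- array(0L, d)
  g[mask@voxels == 1] <- dz$levels
  feats <- NULL
  offs <- glcmOffsets()
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    gShift <- shiftArray(g, 1L, -o[1], fill = 0L)
    gShift <- shiftArray(gShift, 2L, -o[2], fill = 0L)
    gShift <- shiftArray(gShift, 3L, -o[3], fill = 0L)
    ok <- g > 0L & gShift > 0L
    if (!any(ok)) next
    g1 <- g[ok]; g2 <- gShift[ok]
    cnt <- matrix(tabulate((g2 - 1L) * L + g1, nbins = L * L), L, L)
    P <- cnt + t(cnt)
    P <- P / sum(P)
    feats <- rbind(feats, glcmMatrixFeatures(P))
  }
  if (is.null(feats))
    stop("degenerate texture: no in-mask voxel pairs at distance 1", call. = FALSE)
  colMeans(feats)
}

glcmMatrixFeatures <- function(P) {
  L <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(seq_len(L) * px)
  s2 <- sum((seq_len(L) - mu)^2 * px)
  corr <- if (s2 > 0) (sum(i * j * P) - mu^2) / s2 else 1
  pPos <- P[P > 0]
  c(glcm_contrast = sum(P * (i - j)^2),
    glcm_correlation = corr,
    glcm_energy = sum(P^2),
    glcm_homogeneity = sum(P / (1 + (i - j)^2)),
    glcm_entropy = -sum(pPos * log2(pPos)))
}

#' The stable radiomic feature schema
#' @return Character vector of the 23 feature names, in extraction order.
#' @export
featureSchema <- function() {
  c("fo_mean", "fo_variance", "fo_skewness", "fo_kurtosis", "fo_min",
    "fo_max", "fo_range", "fo_median", "fo_p10", "fo_p90", "fo_iqr",
    "fo_energy", "fo_entropy", "fo_uniformity",
    "shape_volume", "shape_surface_area", "shape_sphericity",
    "shape_elongation",
    "glcm_contrast", "glcm_correlation", "glcm_energy", "glcm_homogeneity",
    "glcm_entropy")
}

#' Extract the full radiomic feature vector for one ROI
#'
#' Concatenates first-order, shape and GLCM blocks under the stable
#' [featureSchema()] order. If the ROI has no valid distance-1 voxel pairs
#' (e.g. a single voxel), the GLCM block is filled with the sentinel 0 and
#' the result carries attribute `degenerateTexture = TRUE`.
#'
#' @inheritParams firstOrderFeatures
#' @return Named numeric vector of length `length(featureSchema())`.
#' @export
extractFeatures <- function(vol, mask, disc = discretizationSpec()) {
  fo <- firstOrderFeatures(vol, mask, disc)
  sh <- shapeFeatures(mask)
  degenerate <- FALSE
  gl <- tryCatch(glcmFeatures(vol, mask, disc), error = function(e) {
    degenerate <<- TRUE
    c(glcm_contrast = 0, glcm_correlation = 0, glcm_energy = 0,
      glcm_homogeneity = 0, glcm_entropy = 0)
  })
  out <- c(fo, sh, gl)[featureSchema()]
  if (degenerate) attr(out, "degenerateTexture") <- TRUE
  out
}
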