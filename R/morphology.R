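# Binary 3D morphology on plain arrays, 6-connected structuring element.
# These run on modest desk-scale grids (<= 128^3) via vectorized array shifts.

shiftArray <- function(a, ax, by, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  idxIn <- lapply(d, seq_len)
  idxOut <- idxIn
  n <- d[ax]
  if (abs(by) >= n) return(out)
  if (by > 0) { idxOut[[ax]] <- (by + 1):n; idxIn[[ax]] <- 1:(n - by) }
  if (by < 0) { idxOut[[ax]] <- 1:(n + by); idxIn[[ax]] <- (1 - by):n }
  out[idxOut[[1]], idxOut[[2]], idxOut[[3]]] <- a[idxIn[[1]], idxIn[[2]], idxIn[[3]]]
  out
}

#' Binary dilation with the 6-connected structuring element
#' @param x 3D 0/1 array (or [CTMask-class]).
#' @param iterations number of one-voxel dilation passes.
#' @return Array (or mask) of the same shape.
#' @export
binaryDilate <- function(x, iterations = 1L) {
  isMask <- is(x, "CTMask")
  a <- if (isMask) x@voxels else x
  for (i in seq_len(iterations)) {
    out <- a
    for (ax in 1:3) for (s in c(-1L, 1L)) out <- pmax(out, shiftArray(a, ax, s))
    a <- out
  }
  if (isMask) ctMask(a, spacing = x@spacing, origin = x@origin) else a
}

#' Binary erosion with the 6-connected structuring element
#' @inheritParams binaryDilate
#' @return Array (or mask) of the same shape.
#' @export
binaryErode <- function(x, iterations = 1L) {
  isMask <- is(x, "CTMask")
  a <- if (isMask) x@voxels else x
  for (i in seq_len(iterations)) {
    out <- a
    for (ax in 1:3) for (s in c(-1L, 1L)) out <- pmin(out, shiftArray(a, ax, s, fill = 0))
    a <- out
  }
  if (isMask) ctMask(a, spacing = x@spacing, origin = x@origin) else a
}

# Exact squared Euclidean distance transform (distance in mm to the nearest
# foreground voxel), separable lower-envelope algorithm, one pass per axis.
squaredEDT <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  INF <- 1e18
  f <- array(ifelse(mask == 1, 0, INF), d)
  edt1d <- function(fv, h) {
    n <- length(fv)
    if (n == 1L) return(fv)
    v <- integer(n); z <- numeric(n + 1)
    dOut <- numeric(n)
    k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
    for (q in 2:n) {
      s <- ((fv[q] + (q * h)^2) - (fv[v[k]] + (v[k] * h)^2)) / (2 * h^2 * (q - v[k]))
      while (s <= z[k]) {
        k <- k - 1L
        s <- ((fv[q] + (q * h)^2) - (fv[v[k]] + (v[k] * h)^2)) / (2 * h^2 * (q - v[k]))
      }
      k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1] <- Inf
    }
    k <- 1L
    for (q in 1:n) {
      while (z[k + 1] < q * h) k <- k + 1L
      dOut[q] <- (h * (q - v[k]))^2 + fv[v[k]]
    }
    dOut
  }
  for (ax in 1:3) {
    f <- apply(f, setdiff(1:3, ax), edt1d, h = spacing[ax])
    # apply() returns the processed axis first; rotate back into place
    f <- aperm(f, order(c(ax, setdiff(1:3, ax))))
  }
  f
}

#' Euclidean dilation of a mask by a radius in millimetres
#'
#' Marks every voxel whose centre lies within `radiusMm` of a foreground
#' voxel centre, using an exact Euclidean distance transform so anisotropic
#' spacing is respected. Used to define the "immediate surroundings" of an
#' ROI for ROI-based windowing.
#'
#' @param mask a [CTMask-class].
#' @param radiusMm dilation radius in mm.
#' @return Dilated [CTMask-class].
#' @export
dilateMm <- function(mask, radiusMm) {
  stopifnot(is(mask, "CTMask"))
  assertScalarNumeric(radiusMm, "radiusMm")
  if (radiusMm <= 0) return(mask)
  d2 <- squaredEDT(mask@voxels, mask@spacing)
  out <- array(as.numeric(d2 <= radiusMm^2 + 1e-9), dim(mask@voxels))
  ctMask(out, spacing = mask@spacing, origin = mask@origin)
}

#' Label 6-connected components of a binary array
#' @param x 3D 0/1 array (or [CTMask-class]).
#' @return Integer array of component labels (0 = background).
#' @export
connectedComponents <- function(x) {
  a <- if (is(x, "CTMask")) x@voxels else x
  d <- dim(a)
  fg <- which(a == 1)
  lab <- array(0L, d)
  if (length(fg) == 0L) return(lab)
  pos <- arrayInd(fg, d)
  id <- integer(prod(d)); id[fg] <- seq_along(fg)
  edges <- NULL
  for (ax in 1:3) {
    ok <- pos[, ax] < d[ax]
    nb <- fg[ok] + c(1L, d[1], d[1] * d[2])[ax]
    nbOk <- id[nb] > 0L
    if (any(nbOk))
      edges <- rbind(edges, cbind(id[fg[ok]][nbOk], id[nb[nbOk]]))
  }
  g <- igraph::graph_from_edgelist(rbind(edges, cbind(seq_along(fg), seq_along(fg))),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(fg)]
  lab[fg] <- as.integer(comp)
  lab
}

#' Keep only the largest connected component of a mask
#' @param mask a [CTMask-class].
#' @return [CTMask-class] reduced to its largest 6-connected component
#'   (unchanged if empty).
#' @export
largestComponent <- function(mask) {
  stopifnot(is(mask, "CTMask"))
  lab <- connectedComponents(mask@voxels)
  if (max(lab) <= 1L) return(mask)
  keep <- which.max(tabulate(lab[lab > 0L]))
  ctMask(array(as.numeric(lab == keep), dim(lab)),
         spacing = mask@spacing, origin = mask@origin)
}
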