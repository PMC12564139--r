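# Independent brute-force oracles for the radiomics features: plain loops
# and full enumeration, sharing no code with the package implementation.

# percentile with linear interpolation between order statistics
oracleQuantile <- function(v, p) {
  x <- sort(v)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  hi <- min(lo + 1, n)
  x[lo] + (h - (lo - 1)) * (x[hi] - x[lo])
}

oracleDiscretize <- function(v, nBins) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(rep(1L, length(v)))
  g <- integer(length(v))
  for (i in seq_along(v)) {
    b <- floor((v[i] - lo) / (hi - lo) * nBins) + 1
    g[i] <- max(1, min(nBins, b))
  }
  g
}

oracleFirstOrder <- function(v, nBins = 32) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m3 <- sum((v - m)^3) / n
  m4 <- sum((v - m)^4) / n
  g <- oracleDiscretize(v, nBins)
  p <- as.numeric(table(g)) / n
  c(fo_mean = m, fo_variance = m2,
    fo_skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    fo_kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    fo_min = min(v), fo_max = max(v), fo_range = max(v) - min(v),
    fo_median = oracleQuantile(v, 0.5), fo_p10 = oracleQuantile(v, 0.1),
    fo_p90 = oracleQuantile(v, 0.9),
    fo_iqr = oracleQuantile(v, 0.75) - oracleQuantile(v, 0.25),
    fo_energy = sum(v^2), fo_entropy = -sum(p * log2(p)),
    fo_uniformity = sum(p^2))
}

oracleShape <- function(mask, spacing) {
  d <- dim(mask)
  nvox <- 0; faces <- 0
  faceArea <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                spacing[1] * spacing[2])
  coords <- NULL
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (mask[i, j, k] != 1) next
    nvox <- nvox + 1
    coords <- rbind(coords, (c(i, j, k) - 1) * spacing)
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (q in 1:6) {
      p <- nb[[q]]
      outside <- any(p < 1) || any(p > d) ||
        mask[p[1], p[2], p[3]] != 1
      if (outside) faces <- faces + faceArea[ceiling(q / 2)]
    }
  }
  vol <- nvox * prod(spacing)
  elong <- 1
  if (nvox > 1) {
    cc <- matrix(0, 3, 3)
    cm <- colMeans(coords)
    for (r in seq_len(nrow(coords)))
      cc <- cc + tcrossprod(coords[r, ] - cm)
    ev <- sort(eigen(cc / nvox, symmetric = TRUE)$values, decreasing = TRUE)
    if (ev[1] > 0) elong <- sqrt(max(ev[2], 0) / ev[1])
  }
  c(shape_volume = vol, shape_surface_area = faces,
    shape_sphericity = pi^(1 / 3) * (6 * vol)^(2 / 3) / faces,
    shape_elongation = elong)
}

oracleGLCM <- function(vol, mask, nBins = 32) {
  d <- dim(vol)
  v <- vol[mask == 1]
  g <- array(0L, d)
  g[mask == 1] <- oracleDiscretize(v, nBins)
  L <- nBins
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                c(0, 1, 1), c(0, 1, -1),
                c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  acc <- NULL
  for (r in 1:13) {
    P <- matrix(0, L, L)
    npair <- 0
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (g[i, j, k] == 0) next
      for (sgn in c(1, -1)) {
        p <- c(i, j, k) + sgn * offs[r, ]
        if (any(p < 1) || any(p > d)) next
        if (g[p[1], p[2], p[3]] == 0) next
        P[g[i, j, k], g[p[1], p[2], p[3]]] <-
          P[g[i, j, k], g[p[1], p[2], p[3]]] + 1
        npair <- npair + 1
      }
    }
    if (npair == 0) next
    P <- P / sum(P)
    mu <- 0; for (i in 1:L) mu <- mu + i * sum(P[i, ])
    s2 <- 0; for (i in 1:L) s2 <- s2 + (i - mu)^2 * sum(P[i, ])
    co <- 0; cr <- 0; en <- 0; hm <- 0; ent <- 0
    for (i in 1:L) for (j in 1:L) {
      co <- co + P[i, j] * (i - j)^2
      cr <- cr + i * j * P[i, j]
      en <- en + P[i, j]^2
      hm <- hm + P[i, j] / (1 + (i - j)^2)
      if (P[i, j] > 0) ent <- ent - P[i, j] * log2(P[i, j])
    }
    cr <- if (s2 > 0) (cr - mu^2) / s2 else 1
    acc <- rbind(acc, c(glcm_contrast = co, glcm_correlation = cr,
                        glcm_energy = en, glcm_homogeneity = hm,
                        glcm_entropy = ent))
  }
  colMeans(acc)
}

# random small ROI fixture: volume + mask with at least minVox foreground
randomTinyROI <- function(seed, maxSide = 6, minVox = 2) {
  set.seed(seed)
  d <- sample(2:maxSide, 3, replace = TRUE)
  mask <- array(0, d)
  repeat {
    mask[] <- rbinom(prod(d), 1, runif(1, 0.3, 0.8))
    if (sum(mask) >= minVox) break
  }
  vol <- array(round(rnorm(prod(d), 100, 40), 2), d)
  list(vol = vol, mask = mask, spacing = round(runif(3, 0.5, 2), 2))
}
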