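# Minimal 3D neural-network toolkit: im2col convolutions over BLAS matrix
# multiplies, batch normalization, ReLU, 2x max pooling, nearest-neighbour
# upsampling, dense layers, dropout and Adam. Tensors are R arrays with dims
# (d, h, w, channels); a batch is a list of such arrays. Everything is
# deterministic given the R RNG state.

.idxCache <- new.env(parent = emptyenv())

# Linear indices into a zero-padded (d+2, h+2, w+2) array for the 27
# neighbourhood taps of every voxel of a (d, h, w) grid.
im2colIndices <- function(d) {
  key <- paste(d, collapse = "x")
  if (!is.null(.idxCache[[key]])) return(.idxCache[[key]])
  pd <- d + 2L
  base <- as.vector(outer(outer(seq_len(d[1]), (seq_len(d[2]) - 1L) * pd[1], `+`),
                          (seq_len(d[3]) - 1L) * pd[1] * pd[2], `+`))
  idx <- matrix(0L, length(base), 27L)
  t <- 1L
  for (oz in 0:2) for (oy in 0:2) for (ox in 0:2) {
    idx[, t] <- base + ox + oy * pd[1] + oz * pd[1] * pd[2]
    t <- t + 1L
  }
  .idxCache[[key]] <- idx
  idx
}

padOne <- function(x) {
  d <- dim(x)
  out <- array(0, d + c(2L, 2L, 2L, 0L))
  out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), ] <- x
  out
}

# Cached gather indices into a padded multi-channel array: column
# (c-1)*27 + t holds the linear index of tap t for channel c.
im2colIndicesAll <- function(d, inC) {
  key <- paste(c(d, "c", inC), collapse = "x")
  if (!is.null(.idxCache[[key]])) return(.idxCache[[key]])
  idx <- im2colIndices(d)
  npd <- prod(d + 2L)
  all <- matrix(0L, nrow(idx), 27L * inC)
  for (c in seq_len(inC))
    all[, ((c - 1L) * 27L + 1L):(c * 27L)] <- idx + (c - 1L) * npd
  .idxCache[[key]] <- all
  all
}

convInit <- function(inC, outC, k = 27L) {
  list(W = matrix(rnorm(k * inC * outC, 0, sqrt(2 / (k * inC))), k * inC, outC),
       b = numeric(outC))
}

convForward <- function(x, p) {
  d <- dim(x)[1:3]; inC <- dim(x)[4]
  xp <- padOne(x)
  idxAll <- im2colIndicesAll(d, inC)
  X <- xp[idxAll]
  dim(X) <- dim(idxAll)
  Y <- X %*% p$W
  Y <- sweep(Y, 2, p$b, `+`)
  list(out = array(Y, c(d, ncol(p$W))), X = X, d = d, inC = inC)
}

# Backward-data as a convolution of the output gradient with the spatially
# flipped kernel whose in/out channels are swapped (exact for 3^3 kernels
# with stride 1 and one-voxel zero padding).
flipKernel <- function(W, inC, outC) {
  Wa <- array(W, c(27L, inC, outC))
  Wa <- Wa[27:1, , , drop = FALSE]
  matrix(aperm(Wa, c(1, 3, 2)), 27L * outC, inC)
}

convBackward <- function(dOut, cache, p) {
  d <- cache$d; inC <- cache$inC
  n <- prod(d)
  outC <- dim(dOut)[4]
  dY <- matrix(dOut, n, outC)
  dW <- crossprod(cache$X, dY)
  db <- colSums(dY)
  dx <- convForward(dOut, list(W = flipKernel(p$W, inC, outC),
                               b = numeric(inC)))$out
  list(dx = dx, dW = dW, db = db)
}

bnInit <- function(nC) {
  list(gamma = rep(1, nC), beta = numeric(nC),
       runMean = numeric(nC), runVar = rep(1, nC))
}

# Batch norm over a batch (list of (d,h,w,C) arrays), jointly per channel.
# Per-channel statistics use recycled column arithmetic on one joint matrix.
bnForward <- function(xs, p, train = TRUE, momentum = 0.1, eps = 1e-5) {
  nC <- dim(xs[[1]])[4]
  rowsPer <- vapply(xs, function(x) prod(dim(x)[1:3]), numeric(1))
  all <- do.call(rbind, lapply(xs, function(x) matrix(x, ncol = nC)))
  N <- nrow(all)
  if (train) {
    mu <- colMeans(all)
    va <- colMeans(all^2) - mu^2
    p$runMean <- (1 - momentum) * p$runMean + momentum * mu
    p$runVar <- (1 - momentum) * p$runVar + momentum * va
  } else {
    mu <- p$runMean; va <- p$runVar
  }
  inv <- 1 / sqrt(va + eps)
  xhall <- (all - rep(mu, each = N)) * rep(inv, each = N)
  yall <- xhall * rep(p$gamma, each = N) + rep(p$beta, each = N)
  ends <- cumsum(rowsPer); starts <- c(1, head(ends, -1) + 1)
  ys <- mapply(function(s, e, ref) array(yall[s:e, ], dim(ref)),
               starts, ends, xs, SIMPLIFY = FALSE)
  list(out = ys, xhall = xhall, inv = inv, starts = starts, ends = ends, p = p)
}

bnBackward <- function(dys, cache, p) {
  nC <- length(p$gamma)
  dall <- do.call(rbind, lapply(dys, function(x) matrix(x, ncol = nC)))
  xhall <- cache$xhall
  N <- nrow(dall)
  dgamma <- colSums(dall * xhall)
  dbeta <- colSums(dall)
  dxhat <- dall * rep(p$gamma, each = N)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhall)
  dxall <- (dxhat - rep(s1 / N, each = N) - xhall * rep(s2 / N, each = N)) *
    rep(cache$inv, each = N)
  dxs <- mapply(function(s, e, ref) array(dxall[s:e, ], dim(ref)),
                cache$starts, cache$ends, dys, SIMPLIFY = FALSE)
  list(dxs = dxs, dgamma = dgamma, dbeta = dbeta)
}

reluForward <- function(x) list(out = pmax(x, 0), mask = x > 0)
reluBackward <- function(dOut, cache) dOut * cache$mask

poolIndices <- function(d) {
  key <- paste("pool", paste(d, collapse = "x"))
  if (!is.null(.idxCache[[key]])) return(.idxCache[[key]])
  dh <- d %/% 2L
  base <- as.vector(outer(outer(seq(1L, d[1], 2L),
                                (seq(1L, d[2], 2L) - 1L) * d[1], `+`),
                          (seq(1L, d[3], 2L) - 1L) * d[1] * d[2], `+`))
  idx <- matrix(0L, length(base), 8L)
  t <- 1L
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
    idx[, t] <- base + ox + oy * d[1] + oz * d[1] * d[2]
    t <- t + 1L
  }
  .idxCache[[key]] <- idx
  idx
}

maxPoolForward <- function(x) {
  d <- dim(x)[1:3]; nC <- dim(x)[4]
  idx <- poolIndices(d)
  dh <- d %/% 2L
  out <- array(0, c(dh, nC))
  arg <- matrix(0L, nrow(idx), nC)
  for (c in seq_len(nC)) {
    ch <- x[, , , c]
    vals <- matrix(ch[idx], nrow(idx), 8L)
    w <- max.col(vals, ties.method = "first")
    arg[, c] <- idx[cbind(seq_len(nrow(idx)), w)]
    out[, , , c] <- array(vals[cbind(seq_len(nrow(idx)), w)], dh)
  }
  list(out = out, arg = arg, d = d)
}

maxPoolBackward <- function(dOut, cache) {
  d <- cache$d; nC <- dim(dOut)[4]
  dx <- array(0, c(d, nC))
  for (c in seq_len(nC)) {
    ch <- numeric(prod(d))
    ch[cache$arg[, c]] <- as.vector(dOut[, , , c])
    dx[, , , c] <- array(ch, d)
  }
  dx
}

upsampleForward <- function(x) {
  d <- dim(x)[1:3]; nC <- dim(x)[4]
  ix <- rep(seq_len(d[1]), each = 2)
  iy <- rep(seq_len(d[2]), each = 2)
  iz <- rep(seq_len(d[3]), each = 2)
  list(out = x[ix, iy, iz, , drop = FALSE], d = d)
}

upsampleBackward <- function(dOut, cache) {
  d <- cache$d; nC <- dim(dOut)[4]
  d2 <- d * 2L
  idx <- poolIndices(d2)
  dx <- array(0, c(d, nC))
  for (c in seq_len(nC)) {
    ch <- dOut[, , , c]
    dx[, , , c] <- array(rowSums(matrix(ch[idx], nrow(idx), 8L)), d)
  }
  dx
}

denseInit <- function(nIn, nOut) {
  list(W = matrix(rnorm(nIn * nOut, 0, sqrt(2 / nIn)), nIn, nOut),
       b = numeric(nOut))
}

denseForward <- function(x, p) {
  # x: matrix (batch, nIn)
  list(out = sweep(x %*% p$W, 2, p$b, `+`), x = x)
}

denseBackward <- function(dOut, cache, p) {
  list(dx = dOut %*% t(p$W), dW = crossprod(cache$x, dOut), db = colSums(dOut))
}

dropoutForward <- function(x, rate, train = TRUE) {
  if (!train || rate <= 0) return(list(out = x, mask = NULL))
  mask <- array(rbinom(length(x), 1, 1 - rate), dim(x)) / (1 - rate)
  list(out = x * mask, mask = mask)
}

dropoutBackward <- function(dOut, cache) {
  if (is.null(cache$mask)) dOut else dOut * cache$mask
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Adam with L2 weight decay; params/grads are flat named lists of numerics.
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, weightDecay = 1e-6,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    g <- grads[[k]] + weightDecay * params[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Plateau-reduce learning-rate scheduler (maximization form).
plateauScheduler <- function(lr, patience = 10L, cooldown = 10L, factor = 0.1) {
  env <- new.env(parent = emptyenv())
  env$lr <- lr; env$best <- -Inf; env$bad <- 0L; env$cool <- 0L
  env$patience <- patience; env$cooldown <- cooldown; env$factor <- factor
  env
}

schedulerStep <- function(sch, metric) {
  if (metric > sch$best + 1e-12) {
    sch$best <- metric; sch$bad <- 0L
  } else if (sch$cool > 0L) {
    sch$cool <- sch$cool - 1L
  } else {
    sch$bad <- sch$bad + 1L
    if (sch$bad > sch$patience) {
      sch$lr <- sch$lr * sch$factor
      sch$bad <- 0L; sch$cool <- sch$cooldown
    }
  }
  sch$lr
}
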