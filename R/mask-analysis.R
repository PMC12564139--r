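#' Dice similarity coefficient between two masks
#'
#' `DSC = 2|A intersect B| / (|A| + |B|)`, ranging from 0 (no overlap) to 1
#' (perfect overlap). When both masks are empty the DSC is defined as 1, so
#' an empty-versus-empty comparison is not penalized.
#'
#' @param a,b [CTMask-class] objects (or plain 0/1 arrays) of one shape.
#' @return The DSC in `[0, 1]`.
#' @examples
#' m <- array(0, c(4, 4, 4)); m[2:3, 2:3, 2:3] <- 1
#' diceCoefficient(ctMask(m), ctMask(m))
#' @export
diceCoefficient <- function(a, b) {
  va <- if (is(a, "CTMask")) a@voxels else a
  vb <- if (is(b, "CTMask")) b@voxels else b
  if (!identical(dim(va), dim(vb)))
    stop("mask shapes differ", call. = FALSE)
  sa <- sum(va); sb <- sum(vb)
  if (sa + sb == 0) return(1)
  2 * sum(va * vb) / (sa + sb)
}

#' Plan a DSC-targeted mask perturbation
#'
#' @param targetDsc desired Dice coefficient against the original mask,
#'   in `(0, 1]`.
#' @param tolerance accepted deviation from the target (default 0.005).
#' @param mode `"mixed"` (balanced deletions and additions, default),
#'   `"delete-only"` or `"add-only"`.
#' @param seed integer seed controlling which boundary voxels are flipped.
#' @return A list of class `"PerturbationPlan"`.
#' @seealso [perturbToDSC()]
#' @export
perturbationPlan <- function(targetDsc, tolerance = 0.005,
                             mode = c("mixed", "delete-only", "add-only"),
                             seed = 1L) {
  assertScalarNumeric(targetDsc, "targetDsc")
  if (targetDsc <= 0 || targetDsc > 1)
    stop("targetDsc must lie in (0, 1]", call. = FALSE)
  assertScalarNumeric(tolerance, "tolerance", positive = TRUE)
  structure(list(targetDsc = targetDsc, tolerance = tolerance,
                 mode = match.arg(mode), seed = as.integer(seed)),
            class = "PerturbationPlan")
}

# deletions k and additions m give DSC = 2(a - k) / (2a - k + m)
dscAfter <- function(a, k, m) 2 * (a - k) / (2 * a - k + m)

#' Degrade a mask to a target Dice coefficient
#'
#' Emulates imperfect segmentation by flipping voxels at the mask boundary
#' until the Dice coefficient against the original equals the target within
#' tolerance. The required numbers of deletions `k` and additions `m` follow
#' from the closed form `DSC = 2(|A|-k) / (2|A|-k+m)`; deletions are drawn at
#' random from successive erosion boundary layers and additions from
#' successive dilation layers, so the perturbed mask stays boundary-local
#' (within a 2-layer dilation of the original for the DSC range this package
#' studies). Boundary-local flips mimic plausible segmentation error, as
#' opposed to scattered salt-and-pepper flips which would be adversarial for
#' texture features.
#'
#' @param mask a non-empty [CTMask-class].
#' @param plan a [perturbationPlan()].
#' @return A [CTMask-class] with attributes `achievedDsc`, `nDeleted`,
#'   `nAdded`.
#' @export
perturbToDSC <- function(mask, plan) {
  stopifnot(is(mask, "CTMask"), inherits(plan, "PerturbationPlan"))
  a <- sum(mask@voxels)
  if (a == 0) stop("cannot perturb an empty mask", call. = FALSE)
  t <- plan$targetDsc
  if (t == 1) {
    out <- mask
    attr(out, "achievedDsc") <- 1
    attr(out, "nDeleted") <- 0L
    attr(out, "nAdded") <- 0L
    return(out)
  }
  # integer (k, m) closest to the target under the mode's closed form
  if (plan$mode == "delete-only") {
    k0 <- 2 * a * (1 - t) / (2 - t)
    cand <- expand.grid(k = pmax(0, pmin(a - 1, floor(k0) + (-1:2))), m = 0)
  } else if (plan$mode == "add-only") {
    m0 <- 2 * a * (1 - t) / t
    cand <- expand.grid(k = 0, m = pmax(0, floor(m0) + (-1:2)))
  } else {
    k0 <- round(a * (1 - t))
    cand <- expand.grid(k = pmax(0, pmin(a - 1, k0 + (-2:2))), m = 0:3)
    cand$m <- pmax(0, round(2 * (a - cand$k) / t - (2 * a - cand$k))) + cand$m - 1
    cand <- cand[cand$m >= 0, ]
  }
  err <- abs(dscAfter(a, cand$k, cand$m) - t)
  best <- cand[which.min(err), ]
  if (min(err) > plan$tolerance)
    stop(sprintf(
      "target DSC %.3f unachievable in mode '%s' within tolerance (achievable to %.4f)",
      t, plan$mode, min(err)), call. = FALSE)
  k <- best$k; m <- best$m

  withSeed(plan$seed, {
    cur <- mask@voxels
    # deletions: peel random voxels from successive erosion boundaries
    left <- k
    while (left > 0) {
      boundary <- which(cur == 1 & binaryErode(cur) == 0)
      if (length(boundary) == 0) boundary <- which(cur == 1)
      take <- sample(boundary, min(left, length(boundary)))
      cur[take] <- 0
      left <- left - length(take)
    }
    # additions: grow random voxels in successive dilation shells of the
    # original mask, never re-adding deleted voxels
    layer <- 0L
    base <- mask@voxels
    left <- m
    while (left > 0) {
      layer <- layer + 1L
      if (layer > 2L)
        stop("additions exceed the 2-layer boundary-locality budget; ",
             "target DSC too low for add/mixed mode on this mask", call. = FALSE)
      shell <- which(binaryDilate(base, layer) == 1 & binaryDilate(base, layer - 1L) == 0 &
                     cur == 0)
      if (length(shell) == 0) next
      take <- sample(shell, min(left, length(shell)))
      cur[take] <- 1
      left <- left - length(take)
    }
    out <- ctMask(cur, spacing = mask@spacing, origin = mask@origin)
    attr(out, "achievedDsc") <- diceCoefficient(mask, out)
    attr(out, "nDeleted") <- as.integer(k)
    attr(out, "nAdded") <- as.integer(m)
    out
  })
}
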