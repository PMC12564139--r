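#' Plan a train/validation/test split
#'
#' The sizing rule is floor for training, round for validation, remainder
#' for test, so a 366-case cohort at the default 0.70/0.10/0.20 fractions
#' yields 256/37/73.
#'
#' @param fractions numeric(3) train/val/test fractions summing to 1
#'   (default `c(0.70, 0.10, 0.20)`).
#' @param stratified logical; apply the sizing rule within each class so
#'   every split holds both classes (default FALSE, matching global counts).
#' @param seed assignment seed.
#' @return A list of class `"SplitPlan"`.
#' @export
splitPlan <- function(fractions = c(train = 0.70, val = 0.10, test = 0.20),
                      stratified = FALSE, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)
  structure(list(fractions = fractions, stratified = stratified,
                 seed = as.integer(seed)),
            class = "SplitPlan")
}

#' Randomly split case ids into train/validation/test sets
#'
#' Sizes follow the plan's floor/round/remainder rule; membership is a
#' seeded permutation, so the same seed reproduces the same assignment, not
#' just the same sizes.
#'
#' @param caseIds vector of case identifiers (n >= 3).
#' @param plan a [splitPlan()].
#' @param labels optional logical labels, required for stratified plans.
#' @return List with `train`, `val`, `test` — disjoint, exhaustive subsets
#'   of `caseIds`.
#' @examples
#' lengths(splitDataset(1:366, splitPlan(seed = 1)))
#' @export
splitDataset <- function(caseIds, plan = splitPlan(), labels = NULL) {
  n <- length(caseIds)
  if (n < 3) stop("need at least 3 cases to split", call. = FALSE)
  if (isTRUE(plan$stratified)) {
    if (is.null(labels)) stop("stratified split requires labels", call. = FALSE)
    sub <- lapply(c(FALSE, TRUE), function(cl) {
      ids <- caseIds[labels == cl]
      splitDataset(ids, splitPlan(plan$fractions, stratified = FALSE,
                                  seed = deriveSeed(plan$seed, as.integer(cl))))
    })
    return(list(train = c(sub[[1]]$train, sub[[2]]$train),
                val = c(sub[[1]]$val, sub[[2]]$val),
                test = c(sub[[1]]$test, sub[[2]]$test)))
  }
  nTrain <- floor(n * plan$fractions[[1]])
  nVal <- round(n * plan$fractions[[2]])
  nTest <- n - nTrain - nVal
  if (nTrain < 1 || nVal < 1 || nTest < 1)
    stop(sprintf("split produces an empty subset (sizes %d/%d/%d)",
                 nTrain, nVal, nTest), call. = FALSE)
  perm <- withSeed(plan$seed, sample(n))
  list(train = caseIds[perm[seq_len(nTrain)]],
       val = caseIds[perm[nTrain + seq_len(nVal)]],
       test = caseIds[perm[nTrain + nVal + seq_len(nTest)]])
}

# Windowed-and-masked feature extraction for one case; the mask may be the
# oracle dens mask, a DSC-perturbed copy, or a segmenter output.
caseFeatures <- function(case, mask, wspec, disc) {
  vol <- caseVolume(case)
  wv <- applyWindowing(vol, wspec, mask = mask)
  # radiomics on the windowed [0,1] volume rescaled x1000 so bin widths are
  # comparable across windowing methods
  scaled <- ctVolume(wv@voxels * 1000, spacing = wv@spacing, origin = wv@origin)
  extractFeatures(scaled, mask, disc)
}

resolveMask <- function(case, segSource, segModel, perturbTarget, seed, i) {
  switch(segSource,
    "oracle-mask" = caseDensMask(case),
    "perturbed-mask" = perturbToDSC(
      caseDensMask(case),
      perturbationPlan(perturbTarget, seed = deriveSeed(seed, i))),
    "trained-model" = predictMask(segModel, caseVolume(case)))
}

#' Run the two-stage segmentation + radiomics + classifier pipeline
#'
#' Per case: obtain a dens mask (ground-truth oracle, DSC-perturbed oracle,
#' or trained segmenter output), window the volume (ROI windowing uses that
#' same mask), extract radiomic features, then fit the classifier on the
#' training split and evaluate on the held-out test split. Cases whose mask
#' comes back empty are excluded with a warning and counted in the result.
#'
#' @param cohort list of [PhantomCase-class].
#' @param wspec a [windowSpec()].
#' @param clfSpec a [classifierSpec()].
#' @param plan a [splitPlan()].
#' @param segSource `"oracle-mask"` (default), `"perturbed-mask"` or
#'   `"trained-model"`.
#' @param segModel a `"densSegmenter"`, required for `"trained-model"`.
#' @param perturbTarget target DSC for `"perturbed-mask"`.
#' @param disc a [discretizationSpec()].
#' @param includeValidation logical; add the validation split to classifier
#'   training (default FALSE — the validation split is reserved for neural
#'   checkpoint selection).
#' @param seed pipeline seed (mask perturbation and classifier seeds derive
#'   from it).
#' @return An `"EvalResult"` with extra fields `split`, `nExcluded` and
#'   `meta` (seed, windowing method, classifier, seg source).
#' @export
runM2Pipeline <- function(cohort, wspec = windowSpec("roi"),
                          clfSpec = classifierSpec("knn"),
                          plan = splitPlan(),
                          segSource = c("oracle-mask", "perturbed-mask",
                                        "trained-model"),
                          segModel = NULL, perturbTarget = NULL,
                          disc = discretizationSpec(),
                          includeValidation = FALSE, seed = 1L) {
  segSource <- match.arg(segSource)
  if (segSource == "trained-model" && is.null(segModel))
    stop("segSource 'trained-model' requires segModel", call. = FALSE)
  if (segSource == "perturbed-mask" && is.null(perturbTarget))
    stop("segSource 'perturbed-mask' requires perturbTarget", call. = FALSE)
  n <- length(cohort)
  labels <- cohortLabels(cohort)
  feats <- matrix(NA_real_, n, length(featureSchema()),
                  dimnames = list(NULL, featureSchema()))
  okCase <- rep(TRUE, n)
  for (i in seq_len(n)) {
    mask <- resolveMask(cohort[[i]], segSource, segModel, perturbTarget, seed, i)
    if (sum(mask@voxels) == 0) {
      okCase[i] <- FALSE
      next
    }
    feats[i, ] <- caseFeatures(cohort[[i]], mask, wspec, disc)
  }
  nExcluded <- sum(!okCase)
  if (nExcluded > 0)
    warning(sprintf("%d case(s) excluded due to empty predicted masks",
                    nExcluded))
  sp <- splitDataset(seq_len(n), plan, labels = labels)
  trainIdx <- if (includeValidation) c(sp$train, sp$val) else sp$train
  trainIdx <- intersect(trainIdx, which(okCase))
  testIdx <- intersect(sp$test, which(okCase))
  clfSpec$seed <- deriveSeed(seed, 999983L)
  model <- fitClassifier(feats[trainIdx, , drop = FALSE], labels[trainIdx],
                         clfSpec)
  res <- evaluateModel(model, feats[testIdx, , drop = FALSE], labels[testIdx])
  res$split <- sp
  res$nExcluded <- nExcluded
  res$meta <- list(seed = seed, window = wspec$method,
                   classifier = clfSpec$algorithm, segSource = segSource,
                   perturbTarget = perturbTarget)
  res
}

#' Run the direct CNN+FNN classification pipeline
#'
#' Windows every case volume, trains the [m1Config()] network on the
#' training split with validation-based checkpoint selection, and evaluates
#' on the test split by thresholding the fracture probability at 0.5.
#'
#' @inheritParams runM2Pipeline
#' @param net an [m1Config()].
#' @param cfg a [trainingConfig()].
#' @param maskSource mask used for ROI windowing: `"oracle"` (ground truth)
#'   or a `"densSegmenter"` model. ROI windowing makes the direct classifier
#'   a two-stage variant; other methods need no mask.
#' @return An `"EvalResult"` with extra fields `split`, `probs` and `meta`.
#' @export
runM1Pipeline <- function(cohort, wspec = windowSpec("none"),
                          net = m1Config(), cfg = trainingConfig(),
                          plan = splitPlan(), maskSource = "oracle",
                          seed = 1L) {
  labels <- cohortLabels(cohort)
  prepped <- lapply(seq_along(cohort), function(i) {
    mask <- if (wspec$method == "roi") {
      if (identical(maskSource, "oracle")) caseDensMask(cohort[[i]])
      else predictMask(maskSource, caseVolume(cohort[[i]]))
    } else NULL
    list(volume = applyWindowing(caseVolume(cohort[[i]]), wspec, mask = mask),
         densMask = caseDensMask(cohort[[i]]),
         fractureMask = caseFracMask(cohort[[i]]),
         label = labels[i])
  })
  sp <- splitDataset(seq_along(cohort), plan, labels = labels)
  cfg$seed <- deriveSeed(seed, 31L)
  model <- trainM1(prepped[sp$train], prepped[sp$val], cfg, net)
  probs <- predictM1(model, prepped[sp$test])
  pred <- probs[, 2] > 0.5
  y <- labels[sp$test]
  conf <- c(tp = sum(pred & y), fp = sum(pred & !y),
            tn = sum(!pred & !y), fn = sum(!pred & y))
  structure(list(confusion = conf,
                 accuracy = (conf[["tp"]] + conf[["tn"]]) / sum(conf),
                 balancedAccuracy = balancedAccuracy(conf),
                 predictions = pred, probs = probs, split = sp,
                 model = model,
                 meta = list(seed = seed, window = wspec$method)),
            class = "EvalResult")
}

#' Classification stability across controlled segmentation quality
#'
#' For every combination of DSC level, windowing method and classifier,
#' degrades each case's oracle dens mask to the cell's target DSC with
#' [perturbToDSC()] and runs the full two-stage pipeline, recording accuracy
#' and balanced accuracy per seed. Perturbing oracle masks keeps the DSC
#' axis exactly controlled. Failed cells are recorded and flagged rather
#' than aborting the grid.
#'
#' @param cohort list of [PhantomCase-class].
#' @param dscLevels numeric vector of target DSC values in `(0, 1]`
#'   (default `seq(0.82, 0.94, by = 0.02)`).
#' @param windowSpecs named list of [windowSpec()]s.
#' @param classifierSpecs named list of [classifierSpec()]s.
#' @param plan a [splitPlan()].
#' @param seeds integer vector of replicate seeds.
#' @param disc a [discretizationSpec()].
#' @return A `"StabilityGrid"`: data frame with columns `dsc`, `window`,
#'   `classifier`, `seed`, `accuracy`, `balancedAccuracy`, plus attributes
#'   `complete` and `failures`.
#' @export
stabilityAnalysis <- function(cohort,
                              dscLevels = seq(0.82, 0.94, by = 0.02),
                              windowSpecs = list(roi = windowSpec("roi")),
                              classifierSpecs = list(knn = classifierSpec("knn")),
                              plan = splitPlan(), seeds = 1L,
                              disc = discretizationSpec()) {
  if (any(dscLevels <= 0 | dscLevels > 1))
    stop("dscLevels must lie in (0, 1]", call. = FALSE)
  rows <- NULL; failures <- NULL
  for (lev in dscLevels) for (wn in names(windowSpecs))
    for (cn in names(classifierSpecs)) for (sd in seeds) {
      res <- tryCatch(
        runM2Pipeline(cohort, wspec = windowSpecs[[wn]],
                      clfSpec = classifierSpecs[[cn]], plan = plan,
                      segSource = if (lev == 1) "oracle-mask" else "perturbed-mask",
                      perturbTarget = if (lev == 1) NULL else lev,
                      disc = disc, seed = sd),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures <- rbind(failures,
                          data.frame(dsc = lev, window = wn, classifier = cn,
                                     seed = sd, message = conditionMessage(res)))
      } else {
        rows <- rbind(rows, data.frame(dsc = lev, window = wn, classifier = cn,
                                       seed = sd, accuracy = res$accuracy,
                                       balancedAccuracy = res$balancedAccuracy))
      }
    }
  structure(rows, complete = is.null(failures), failures = failures,
            class = c("StabilityGrid", "data.frame"))
}

#' Render a stability grid as a heatmap
#'
#' Draws one panel per metric with classifiers as rows and (windowing
#' method, DSC level) combinations as columns, darker cells indicating
#' higher accuracy, and writes it to a PNG.
#'
#' @param grid a `"StabilityGrid"` from [stabilityAnalysis()].
#' @param file output PNG path.
#' @param metric `"accuracy"` or `"balancedAccuracy"`.
#' @return `file`, invisibly.
#' @export
plotStabilityGrid <- function(grid, file, metric = c("accuracy",
                                                     "balancedAccuracy")) {
  metric <- match.arg(metric)
  agg <- stats::aggregate(grid[[metric]],
                          by = list(dsc = grid$dsc, window = grid$window,
                                    classifier = grid$classifier), FUN = mean)
  cols <- interaction(agg$window, sprintf("DSC %.2f", agg$dsc), sep = " @ ")
  M <- tapply(agg$x, list(agg$classifier, cols), mean)
  grDevices::png(file, width = 200 + 60 * ncol(M), height = 120 + 40 * nrow(M))
  on.exit(grDevices::dev.off(), add = TRUE)
  pheatmap::pheatmap(M, cluster_rows = FALSE, cluster_cols = FALSE,
                     display_numbers = TRUE, number_format = "%.3f",
                     main = paste("M2", metric),
                     breaks = seq(0, 1, length.out = 51),
                     color = grDevices::colorRampPalette(c("white", "grey20"))(50))
  invisible(file)
}
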