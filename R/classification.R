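#' Specify a stage-2 machine-learning classifier
#'
#' Covers the six algorithm families used for radiomics-based fracture
#' classification: decision trees, extra trees, gradient boosting machines,
#' k-nearest neighbours, Gaussian Naive Bayes and random forests.
#' Defaults: KNN uses k = 5 with Euclidean distance on standardized
#' features (an odd k, so two-class vote ties cannot occur); tree ensembles
#' use 100 trees; feature standardization is enabled automatically for the
#' distance-based KNN and disabled otherwise.
#'
#' @param algorithm one of `"decision_tree"`, `"extra_trees"`,
#'   `"gradient_boosting"`, `"knn"`, `"gaussian_nb"`, `"random_forest"`.
#' @param hyper named list of algorithm-specific hyperparameters (`k`,
#'   `nTrees`, `maxDepth`, `eta`, `nRounds`).
#' @param classWeighting logical; weight cases by inverse class prevalence
#'   where the algorithm supports it (default TRUE).
#' @param standardize logical or `NULL` (auto: TRUE for `knn`).
#' @param seed integer seed.
#' @return A list of class `"ClassifierSpec"`.
#' @export
classifierSpec <- function(algorithm = c("decision_tree", "extra_trees",
                                         "gradient_boosting", "knn",
                                         "gaussian_nb", "random_forest"),
                           hyper = list(), classWeighting = TRUE,
                           standardize = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  defaults <- list(k = 5L, nTrees = 100L, maxDepth = 3L, eta = 0.3,
                   nRounds = 50L)
  hyper <- utils::modifyList(defaults, hyper)
  if (hyper$k < 1) stop("knn k must be >= 1", call. = FALSE)
  if (is.null(standardize)) standardize <- algorithm == "knn"
  structure(list(algorithm = algorithm, hyper = hyper,
                 classWeighting = classWeighting, standardize = standardize,
                 seed = as.integer(seed)),
            class = "ClassifierSpec")
}

#' Fit a classifier on a radiomic feature table
#'
#' Validates the feature matrix (finite values, both classes present), drops
#' features with zero variance on the training data, records
#' training-set standardization statistics, applies inverse-prevalence case
#' weights where the backend supports them, and fits the requested
#' algorithm. All stochastic backends are seeded, so the same data and spec
#' reproduce the same model.
#'
#' @param features numeric matrix or data frame (cases x features).
#' @param labels logical (or 0/1) fracture labels.
#' @param spec a [classifierSpec()].
#' @return An object of class `"densClassifier"`.
#' @export
fitClassifier <- function(features, labels, spec = classifierSpec("knn")) {
  stopifnot(inherits(spec, "ClassifierSpec"))
  X <- as.matrix(features)
  if (!all(is.finite(X)))
    stop("features contain missing or non-finite values", call. = FALSE)
  y <- as.logical(labels)
  if (length(unique(y)) < 2)
    stop("training labels contain a single class", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  keep <- which(sds > 0)
  if (length(keep) == 0) stop("all features are constant", call. = FALSE)
  Xk <- X[, keep, drop = FALSE]
  center <- colMeans(Xk); scale <- sds[keep]
  if (spec$standardize) Xk <- scale(Xk, center = center, scale = scale)
  yf <- factor(y, levels = c(FALSE, TRUE), labels = c("noFracture", "fracture"))
  cw <- computeClassWeights(c(sum(!y), sum(y)))
  casew <- if (spec$classWeighting) cw[as.integer(y) + 1L] else rep(1, length(y))
  df <- data.frame(Xk, check.names = FALSE)
  df$.label <- yf
  fit <- withSeed(spec$seed, switch(spec$algorithm,
    decision_tree = rpart::rpart(.label ~ ., data = df, weights = casew,
                                 method = "class",
                                 control = rpart::rpart.control(
                                   xval = 0, minsplit = 4, minbucket = 2,
                                   cp = 0.001)),
    extra_trees = ranger::ranger(
      x = Xk, y = yf, num.trees = spec$hyper$nTrees, splitrule = "extratrees",
      case.weights = casew, seed = spec$seed, num.threads = 1),
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = spec$hyper$maxDepth, eta = spec$hyper$eta,
                    nthread = 1, seed = spec$seed),
      data = xgboost::xgb.DMatrix(Xk, label = as.numeric(y), weight = casew,
                                  nthread = 1),
      nrounds = spec$hyper$nRounds, verbose = 0),
    knn = list(train = Xk, cl = yf, k = as.integer(spec$hyper$k)),
    gaussian_nb = e1071::naiveBayes(x = Xk, y = yf),
    random_forest = randomForest::randomForest(
      x = Xk, y = yf, ntree = spec$hyper$nTrees,
      classwt = if (spec$classWeighting) cw else NULL)
  ))
  structure(list(spec = spec, fit = fit, schema = colnames(X),
                 keep = keep, center = center, scale = scale,
                 levels = levels(yf)),
            class = "densClassifier")
}

#' Predict fracture labels for new cases
#' @param object a `"densClassifier"`.
#' @param newdata feature matrix with the training schema's columns.
#' @param ... unused.
#' @return Logical vector of predicted fracture labels.
#' @export
predict.densClassifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!all(object$schema %in% colnames(X)))
    stop("feature schema mismatch: missing columns", call. = FALSE)
  X <- X[, object$schema, drop = FALSE]
  Xk <- X[, object$keep, drop = FALSE]
  if (object$spec$standardize)
    Xk <- scale(Xk, center = object$center, scale = object$scale)
  spec <- object$spec
  pred <- switch(spec$algorithm,
    decision_tree = predict(object$fit,
                            newdata = data.frame(Xk, check.names = FALSE),
                            type = "class"),
    extra_trees = predict(object$fit, data = Xk,
                          num.threads = 1)$predictions,
    gradient_boosting = factor(
      predict(object$fit, xgboost::xgb.DMatrix(Xk, nthread = 1)) > 0.5,
      levels = c(FALSE, TRUE), labels = object$levels),
    knn = withSeed(spec$seed,
                   class::knn(object$fit$train, Xk, object$fit$cl,
                              k = object$fit$k)),
    gaussian_nb = predict(object$fit, newdata = Xk),
    random_forest = predict(object$fit, newdata = Xk)
  )
  pred == "fracture"
}

#' Balanced accuracy from confusion counts
#'
#' The mean of sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)`;
#' undefined (an error) when either class is absent.
#'
#' @param confusion named numeric with elements `tp`, `fp`, `tn`, `fn`.
#' @return Balanced accuracy in `[0, 1]`.
#' @examples
#' balancedAccuracy(c(tp = 9, fn = 1, tn = 5, fp = 5))
#' @export
balancedAccuracy <- function(confusion) {
  tp <- confusion[["tp"]]; fp <- confusion[["fp"]]
  tn <- confusion[["tn"]]; fn <- confusion[["fn"]]
  if (tp + fn == 0 || tn + fp == 0)
    stop("balanced accuracy undefined: a class is absent", call. = FALSE)
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

#' Evaluate a fitted classifier
#'
#' Computes the confusion counts, accuracy and balanced accuracy of the
#' model's predictions on a labelled feature table. Pure: repeated calls
#' give identical results.
#'
#' @param model a `"densClassifier"`.
#' @param features feature matrix.
#' @param labels true logical labels.
#' @return An object of class `"EvalResult"`: list with `confusion`
#'   (tp/fp/tn/fn), `accuracy`, `balancedAccuracy` and `predictions`.
#' @export
evaluateModel <- function(model, features, labels) {
  pred <- predict(model, features)
  y <- as.logical(labels)
  conf <- c(tp = sum(pred & y), fp = sum(pred & !y),
            tn = sum(!pred & !y), fn = sum(!pred & y))
  structure(list(confusion = conf,
                 accuracy = (conf[["tp"]] + conf[["tn"]]) / sum(conf),
                 balancedAccuracy = balancedAccuracy(conf),
                 predictions = pred),
            class = "EvalResult")
}

#' @export
print.EvalResult <- function(x, ...) {
  cat(sprintf("EvalResult: accuracy %.3f, balanced accuracy %.3f (n = %d)\n",
              x$accuracy, x$balancedAccuracy, sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}
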