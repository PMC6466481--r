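#' Build a classifier configuration
#'
#' @param kind classifier identifier; `"rbf-svm"` is built in, others can
#'   be added with [registerClassifier()].
#' @param penaltyGrid candidate SVM penalty parameters C.
#' @param bandwidthGrid candidate kernel bandwidths q. The RBF kernel is
#'   \eqn{\exp(-\|u-v\|^2 / (2q^2))}, i.e. gamma = 1/(2 q^2).
#' @param cvFolds stratified cross-validation folds (default 10).
#' @param seed seed for the fold assignment.
#' @return a [ClassifierConfig-class].
#' @export
classifierConfig <- function(kind = "rbf-svm",
                             penaltyGrid = c(1, 2, 4, 8, 16, 32, 64, 128, 256),
                             bandwidthGrid = c(0.1, 0.2, 0.3, 0.5, 1, 2, 4, 8),
                             cvFolds = 10L, seed = 1L) {
  methods::new("ClassifierConfig", kind = kind,
               penaltyGrid = sort(penaltyGrid),
               bandwidthGrid = sort(bandwidthGrid),
               cvFolds = as.integer(cvFolds), seed = as.integer(seed))
}

setMethod("show", "ClassifierConfig", function(object) {
  cat(sprintf("ClassifierConfig '%s': C in {%s}, q in {%s}, %d-fold CV, seed %d\n",
              object@kind, paste(object@penaltyGrid, collapse = ","),
              paste(object@bandwidthGrid, collapse = ","),
              object@cvFolds, object@seed))
})

.classifierEnv <- new.env(parent = emptyenv())

#' Register a classifier for the wrapper stage
#'
#' Plug-in interface: a classifier is a `fit(x, y, params)` function
#' returning a model and a `predict(model, x)` function returning class
#' labels (factor levels "1"/"2"). `usesGrid = FALSE` marks classifiers
#' that ignore the (C, q) grid, so the grid search collapses to a single
#' evaluation.
#'
#' @param kind identifier.
#' @param fit,predict functions as above.
#' @param usesGrid whether (C, q) affect the fit.
#' @export
registerClassifier <- function(kind, fit, predict, usesGrid = TRUE) {
  .classifierEnv[[kind]] <- list(fit = fit, predict = predict,
                                 usesGrid = usesGrid)
  invisible(kind)
}

.getClassifier <- function(kind) {
  cl <- .classifierEnv[[kind]]
  if (is.null(cl)) stop("unknown classifier kind: ", kind)
  cl
}

.registerBuiltins <- function() {
  registerClassifier("rbf-svm",
    fit = function(x, y, params)
      e1071::svm(x, y, type = "C-classification", kernel = "radial",
                 cost = params$C, gamma = 1 / (2 * params$q^2),
                 scale = FALSE),
    predict = function(model, x) predict(model, x))
  registerClassifier("naive-bayes",
    fit = function(x, y, params)
      e1071::naiveBayes(as.data.frame(x), y),
    predict = function(model, x) predict(model, as.data.frame(x)),
    usesGrid = FALSE)
  if (requireNamespace("rpart", quietly = TRUE))
    registerClassifier("cart",
      fit = function(x, y, params) {
        df <- as.data.frame(x); df$.y <- y
        rpart::rpart(.y ~ ., data = df, method = "class")
      },
      predict = function(model, x)
        predict(model, as.data.frame(x), type = "class"),
      usesGrid = FALSE)
}

# Pooled cross-validated predictions for fixed hyperparameters. Features
# are standardized inside each training fold only (mean/SD of the training
# subjects; an SD of zero falls back to 1), and the fold's test subjects
# are mapped with the training statistics.
.cvPredict <- function(x, y, fold, kind, params) {
  cl <- .getClassifier(kind)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    xs <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
    fit <- cl$fit(xs[tr, , drop = FALSE], y[tr], params)
    pred[!tr] <- cl$predict(fit, xs[!tr, , drop = FALSE])
  }
  pred
}

#' Tune the classifier on a feature subset by cross-validated accuracy
#'
#' Exhaustive grid search over penalty x bandwidth; for each combination
#' the pooled accuracy over the stratified folds is computed, and the best
#' combination is returned (ties resolved toward the smaller penalty, then
#' the smaller bandwidth). Deterministic for a given config.
#'
#' @param table a [FeatureTable-class].
#' @param featureSubset character vector of feature names.
#' @param config a [classifierConfig()].
#' @return list with `accuracy` (percent, full precision), `C`, `q`.
#' @export
tuneAndScore <- function(table, featureSubset, config = classifierConfig()) {
  if (length(featureSubset) < 1L) stop("feature subset must be non-empty")
  unknown <- setdiff(featureSubset, rownames(table))
  if (length(unknown)) stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  x <- featureValues(table)[, featureSubset, drop = FALSE]
  y <- factor(classLabels(table), levels = c(1L, 2L))
  fold <- stratifiedKFold(classLabels(table), config@cvFolds, config@seed)
  grid <- if (.getClassifier(config@kind)$usesGrid)
    expand.grid(q = config@bandwidthGrid, C = config@penaltyGrid)[, 2:1]
  else data.frame(C = NA_real_, q = NA_real_)
  best <- list(accuracy = -Inf, C = NA_real_, q = NA_real_)
  for (g in seq_len(nrow(grid))) {
    params <- list(C = grid$C[g], q = grid$q[g])
    pred <- .cvPredict(x, y, fold, config@kind, params)
    acc <- 100 * mean(pred == y)
    if (acc > best$accuracy + 1e-12) # strict: first (smallest C, q) wins ties
      best <- list(accuracy = acc, C = params$C, q = params$q)
  }
  best
}

#' Prefix-accuracy curve of a filter ranking
#'
#' Evaluates [tuneAndScore()] on the top-i features of the ranking for
#' i = 1..p (incremental forward evaluation in descending rank order) and
#' derives the per-feature accuracy contributions with
#' [contributionsFromCurve()]. The curve need not be monotone; each prefix
#' is re-tuned over the full hyperparameter grid.
#'
#' @param table a [FeatureTable-class].
#' @param ranking character vector covering all features (e.g.
#'   [rankFeatures()] output).
#' @param config a [classifierConfig()].
#' @param modelId label stored on the curve.
#' @return a [ContributionCurve-class].
#' @export
prefixAccuracyCurve <- function(table, ranking, config = classifierConfig(),
                                modelId = "custom") {
  if (!setequal(ranking, rownames(table)))
    stop("ranking must cover the feature universe")
  p <- length(ranking)
  acc <- numeric(p)
  tp <- data.frame(C = numeric(p), q = numeric(p))
  for (i in seq_len(p)) {
    ts <- tuneAndScore(table, ranking[seq_len(i)], config)
    acc[i] <- ts$accuracy; tp$C[i] <- ts$C; tp$q[i] <- ts$q
  }
  curve <- methods::new("ContributionCurve", modelId = modelId,
                        orderedFeatures = ranking, prefixAccuracy = acc,
                        tunedParams = tp,
                        rawContribution = stats::setNames(rep(NA_real_, p),
                                                          ranking),
                        contribution = stats::setNames(rep(0, p), ranking))
  cc <- contributionsFromCurve(curve)
  curve@rawContribution <- cc$raw
  curve@contribution <- cc$c
  methods::validObject(curve)
  curve
}

#' Accuracy contributions from a prefix-accuracy curve
#'
#' The raw contribution of the feature added at ranking position i >= 2 is
#' the first difference `prefixAccuracy[i] - prefixAccuracy[i-1]` (accuracy
#' points); the top-ranked feature's raw contribution is undefined (NA).
#' Normalized contributions min-max map the defined raw values to \[0, 1\]
#' and assign the top-ranked feature a contribution of 1 by convention.
#' Both vectors are returned in canonical feature order of `names`.
#'
#' @param curve a [ContributionCurve-class] (only `prefixAccuracy` and
#'   `orderedFeatures` are used).
#' @return list with `raw` (NA for the top-ranked feature) and `c`, both
#'   named in ranking order.
#' @export
contributionsFromCurve <- function(curve) {
  acc <- curve@prefixAccuracy
  feats <- curve@orderedFeatures
  p <- length(acc)
  if (p == 1L)
    return(list(raw = stats::setNames(NA_real_, feats),
                c = stats::setNames(1, feats)))
  raw <- c(NA_real_, diff(acc))
  cn <- c(1, minmaxNormalize(raw[-1]))
  list(raw = stats::setNames(raw, feats), c = stats::setNames(cn, feats))
}

#' Per-model diagnostic weight: normalized score plus normalized contribution
#'
#' The overall performance of a feature under one filter model is the sum
#' of its normalized filter score and its normalized accuracy contribution
#' (range 0 to 2).
#'
#' @param scores a [FilterScoreVector-class].
#' @param curve a [ContributionCurve-class] over the same features.
#' @return named numeric in canonical feature order.
#' @export
perModelWeight <- function(scores, curve) {
  s <- scores@s
  cc <- curve@contribution[names(s)]
  s + cc
}

#' ContributionCurve accessors
#' @param x a [ContributionCurve-class]
#' @name prefixAccuracyCurve
#' @aliases prefixAccuracy tunedParams rawContribution normalizedContribution
NULL

#' @rdname prefixAccuracyCurve
#' @export
setMethod("prefixAccuracy", "ContributionCurve", function(x)
  stats::setNames(x@prefixAccuracy, x@orderedFeatures))

#' @rdname prefixAccuracyCurve
#' @export
setMethod("tunedParams", "ContributionCurve", function(x) x@tunedParams)

#' @rdname prefixAccuracyCurve
#' @export
setMethod("rawContribution", "ContributionCurve", function(x)
  x@rawContribution)

#' @rdname prefixAccuracyCurve
#' @export
setMethod("normalizedContribution", "ContributionCurve", function(x)
  x@contribution)

#' @rdname rankFeatures
#' @export
setMethod("featureRanking", "ContributionCurve", function(x)
  x@orderedFeatures)

setMethod("show", "ContributionCurve", function(object) {
  p <- length(object@orderedFeatures)
  cat(sprintf("ContributionCurve '%s': %d prefixes, accuracy %.1f%% -> %.1f%%\n",
              object@modelId, p, object@prefixAccuracy[1],
              object@prefixAccuracy[p]))
})
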