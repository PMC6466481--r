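#' Pooled confusion counts
#'
#' @param tp,fp,tn,fn non-negative counts; class 1 (case) is the positive
#'   class, so `tp + fn` is the number of sick and `tn + fp` the number of
#'   well subjects.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(tp, fp, tn, fn)
  methods::new("ConfusionCounts", tp = as.numeric(tp), fp = as.numeric(fp),
               tn = as.numeric(tn), fn = as.numeric(fn))

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), accuracy =
#' (TP + TN) / all, Youden index = sensitivity + specificity - 1. All
#' quantities are kept at full precision; percentages are rounded only for
#' display.
#'
#' @param counts a [ConfusionCounts-class].
#' @param nFeatures,method optional bookkeeping recorded on the report.
#' @return a [MetricsReport-class].
#' @examples
#' diagnosticMetrics(confusionCounts(tp = 329, fp = 77, tn = 317, fn = 69))
#' @export
diagnosticMetrics <- function(counts, nFeatures = NA_integer_,
                              method = NA_character_) {
  sick <- counts@tp + counts@fn
  well <- counts@tn + counts@fp
  if (sick == 0) stop("no sick individuals: sensitivity undefined")
  if (well == 0) stop("no well individuals: specificity undefined")
  sens <- counts@tp / sick
  spec <- counts@tn / well
  methods::new("MetricsReport", sensitivity = sens, specificity = spec,
               accuracy = (counts@tp + counts@tn) / (sick + well),
               youden = sens + spec - 1, nFeatures = as.integer(nFeatures),
               method = method)
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport%s: sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%, Youden %.2f\n",
              if (is.na(object@method)) "" else paste0(" [", object@method, "]"),
              100 * object@sensitivity, 100 * object@specificity,
              100 * object@accuracy, object@youden))
})

#' @rdname diagnosticMetrics
#' @param x a [MetricsReport-class]
#' @export
metricsAsDataFrame <- function(x)
  data.frame(method = x@method, n_features = x@nFeatures,
             sensitivity = x@sensitivity, specificity = x@specificity,
             accuracy = x@accuracy, youden = x@youden,
             stringsAsFactors = FALSE)

#' Cross-validated evaluation of a feature subset
#'
#' Tunes the classifier on the selected features by cross-validated
#' accuracy, then pools the out-of-fold predictions of the tuned
#' classifier into micro (pooled) confusion counts: class 1 (case) is
#' positive. Metrics are computed from the pooled counts, so the reported
#' accuracy equals (TP + TN) / n exactly.
#'
#' @param table a [FeatureTable-class].
#' @param selected feature names, a subset of the feature universe.
#' @param config a [classifierConfig()].
#' @param method label recorded on the report.
#' @return a [MetricsReport-class].
#' @export
evaluateSelection <- function(table, selected, config = classifierConfig(),
                              method = "custom") {
  ts <- tuneAndScore(table, selected, config)
  x <- featureValues(table)[, selected, drop = FALSE]
  y <- factor(classLabels(table), levels = c(1L, 2L))
  fold <- stratifiedKFold(classLabels(table), config@cvFolds, config@seed)
  pred <- .cvPredict(x, y, fold, config@kind, list(C = ts$C, q = ts$q))
  counts <- confusionCounts(tp = sum(pred == "1" & y == "1"),
                            fp = sum(pred == "1" & y == "2"),
                            tn = sum(pred == "2" & y == "2"),
                            fn = sum(pred == "2" & y == "1"))
  diagnosticMetrics(counts, nFeatures = length(selected), method = method)
}

#' Compare feature-selection strategies
#'
#' Evaluates WRHFS against single-filter baselines on one table. Each
#' baseline filter ranks the features, its prefix-accuracy curve is
#' computed, and its optimal feature count is the prefix with the peak
#' cross-validated accuracy (smallest such prefix on ties); WRHFS selects
#' by the strict >50% cumulative-share rule. Every method is then scored
#' by [evaluateSelection()] on its own subset. Note the baselines' feature
#' counts are chosen on the same cross-validation used for reporting,
#' which is optimistically biased.
#'
#' @param table a [FeatureTable-class].
#' @param methods character vector, `"wrhfs"` and/or filter ids.
#' @param config a [classifierConfig()].
#' @param wrhfsModels fixed filter triple for WRHFS; `NULL` runs the
#'   tournament over [filterCatalog()].
#' @param threshold WRHFS cumulative-share threshold.
#' @return data.frame with one row per method: `method`, `n_features`,
#'   `sensitivity`, `specificity`, `accuracy`, `youden` (proportions).
#' @export
compareMethods <- function(table, methods = c("wrhfs", "std", "relief",
                                              "infogain"),
                           config = classifierConfig(), wrhfsModels = NULL,
                           threshold = 0.5) {
  if (length(methods) < 2L) stop("at least 2 methods required")
  artifacts <- .modelArtifacts(table, config)
  rows <- lapply(methods, function(m) {
    if (m == "wrhfs") {
      fit <- runWRHFS(table, config, models = wrhfsModels,
                      threshold = threshold)
      sel <- selectedFeatures(fit)
    } else {
      curve <- artifacts(m)$curve
      best <- which.max(curve@prefixAccuracy)
      sel <- curve@orderedFeatures[seq_len(best)]
    }
    metricsAsDataFrame(evaluateSelection(table, sel, config, method = m))
  })
  do.call(rbind, rows)
}
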