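#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor quantile predict sd
#' @importFrom utils read.csv write.csv
NULL

#' FeatureTable: a complete two-class clinical feature table
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a numeric
#' feature matrix (features in rows, subjects in columns), a binary class
#' label per subject in `colData()$label` (1 = case, 2 = control), and
#' per-feature metadata (`name`, `unit`, `value_kind`) in `rowData()`.
#' The row order of the assay is the canonical feature order used by every
#' downstream score vector and matrix.
#'
#' Validity requires a complete table (no missing entries anywhere; records
#' with missing values must be excluded before construction), exactly the
#' two label values 1 and 2 both present, at least 2 features and 4
#' subjects, and unique feature names.
#'
#' @seealso [featureTable()], [readFeatureTable()], [generateSyntheticCohort()]
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  v <- SummarizedExperiment::assay(object, "values")
  if (!is.numeric(v))
    return("feature values must be numeric")
  if (anyNA(v)) {
    idx <- which(is.na(v), arr.ind = TRUE)[1, ]
    return(sprintf("missing value for feature '%s', sample %d (complete records required)",
                   rownames(v)[idx[1]], idx[2]))
  }
  if (nrow(v) < 2) return("at least 2 features required")
  if (ncol(v) < 4) return("at least 4 samples required")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("feature names must be present and unique")
  lab <- object$label
  if (is.null(lab)) return("colData must contain a 'label' column")
  if (anyNA(lab)) return("labels must not contain missing values")
  if (!all(lab %in% c(1L, 2L)))
    return("labels must take values 1 (case) and 2 (control)")
  if (length(unique(lab)) != 2L)
    return("both label values (1 and 2) must be present")
  TRUE
})

#' Per-filter feature scores and ranking
#'
#' Raw scores of one filter model over the canonical feature order, their
#' min-max normalisation `s` in \[0, 1\], and the descending-score feature
#' ranking (ties broken by canonical feature order).
#'
#' @slot modelId one of `"std"`, `"pearson"`, `"fisher"`, `"infogain"`,
#'   `"relief"`, `"chi2"`
#' @slot rawScores named numeric, canonical feature order
#' @slot s named numeric in \[0, 1\]
#' @slot ranking character, features by descending raw score
#' @export
setClass("FilterScoreVector",
  representation(modelId = "character", rawScores = "numeric",
                 s = "numeric", ranking = "character"))

setValidity("FilterScoreVector", function(object) {
  if (length(object@rawScores) != length(object@s))
    return("rawScores and s must have equal length")
  if (!setequal(object@ranking, names(object@rawScores)))
    return("ranking must be a permutation of the feature names")
  if (any(object@s < -1e-12 | object@s > 1 + 1e-12))
    return("normalized scores must lie in [0, 1]")
  TRUE
})

#' Classifier configuration for the wrapper stage
#'
#' Holds the classifier kind, the exhaustive hyperparameter grids (penalty
#' parameter C and kernel bandwidth q for the RBF SVM), the number of
#' stratified cross-validation folds, and the fold seed. Defaults are the
#' grids observed in the reference study: C in 1..256 (powers of two) and
#' q in {0.1, 0.2, 0.3, 0.5, 1, 2, 4, 8}, with 10-fold cross-validation.
#'
#' @export
setClass("ClassifierConfig",
  representation(kind = "character", penaltyGrid = "numeric",
                 bandwidthGrid = "numeric", cvFolds = "integer",
                 seed = "integer"))

setValidity("ClassifierConfig", function(object) {
  if (length(object@penaltyGrid) < 1 || length(object@bandwidthGrid) < 1)
    return("hyperparameter grids must be non-empty")
  if (object@cvFolds < 2L) return("cvFolds must be at least 2")
  TRUE
})

#' Prefix-accuracy curve and accuracy contributions of one filter ranking
#'
#' For ranking positions i = 1..p, `prefixAccuracy[i]` is the tuned
#' cross-validated accuracy (percent) of the classifier on the top-i
#' features; `tunedParams` records the winning (C, q) per prefix.
#' `rawContribution` holds first differences of the accuracy curve in
#' canonical feature order (NA for the top-ranked feature, whose raw
#' contribution is undefined); `contribution` is its min-max normalisation
#' with the top-ranked feature assigned 1.
#'
#' @export
setClass("ContributionCurve",
  representation(modelId = "character", orderedFeatures = "character",
                 prefixAccuracy = "numeric", tunedParams = "data.frame",
                 rawContribution = "numeric", contribution = "numeric"))

setValidity("ContributionCurve", function(object) {
  p <- length(object@orderedFeatures)
  if (length(object@prefixAccuracy) != p)
    return("one prefix accuracy per ranking position required")
  if (!setequal(names(object@contribution), object@orderedFeatures))
    return("contribution must cover the feature universe")
  cc <- object@contribution
  if (any(cc < -1e-12 | cc > 1 + 1e-12))
    return("normalized contributions must lie in [0, 1]")
  TRUE
})

#' Voting state of the WRHFS assessment stage
#'
#' The three active filter models with their score matrix S (p x 3), the
#' weight-sum vector W (row sums of S), the contribution matrix C (p x 3 of
#' normalized wrapper contributions), the cumulative-contribution matrix D
#' (p x 3), and the effectiveness vector P = W x D (one coefficient per
#' active model).
#'
#' @export
setClass("VotingState",
  representation(activeModels = "character", S = "matrix", W = "numeric",
                 C = "matrix", D = "matrix", P = "numeric"))

setValidity("VotingState", function(object) {
  if (length(object@activeModels) != 3L) return("exactly 3 active models")
  if (ncol(object@S) != 3L || ncol(object@C) != 3L || ncol(object@D) != 3L)
    return("S, C and D must have 3 columns")
  if (length(object@W) != nrow(object@S)) return("W must match S rows")
  if (length(object@P) != 3L) return("P must have one entry per model")
  if (max(abs(object@W - rowSums(object@S))) > 1e-8)
    return("W must equal the row sums of S")
  TRUE
})

#' Final WRHFS feature weighting
#'
#' The fused weight W_r per feature, each feature's share of the total
#' weight, the running cumulative share in descending-weight order, the
#' min-max-normalized weights, and the selected subset: the minimal
#' descending-weight prefix whose cumulative share strictly exceeds the
#' threshold (default 0.5).
#'
#' @export
setClass("FeatureWeighting",
  representation(Wr = "numeric", share = "numeric", order = "character",
                 cumulativeShare = "numeric", weight01 = "numeric",
                 selected = "character", N = "integer",
                 threshold = "numeric"))

setValidity("FeatureWeighting", function(object) {
  if (abs(sum(object@share) - 1) > 1e-8) return("shares must sum to 1")
  cs <- object@cumulativeShare
  if (any(diff(cs) < -1e-12)) return("cumulative share must be non-decreasing")
  if (abs(cs[length(cs)] - 1) > 1e-8) return("cumulative share must end at 1")
  if (object@N != length(object@selected)) return("N must match selected length")
  TRUE
})

#' A fitted WRHFS model
#'
#' Bundles the winning filter models, the final voting state, per-model
#' effectiveness coefficients recorded across the tournament, the tournament
#' history, and the resulting feature weighting.
#'
#' @export
setClass("WRHFSFit",
  representation(models = "character", voting = "VotingState",
                 weighting = "FeatureWeighting", coefficients = "numeric",
                 history = "list"))

#' Synthetic-value risk model
#'
#' Ordered (feature, coefficient) terms of the synthetic value
#' SV = sum(coefficient * feature value), where coefficients are the
#' min-max-normalized WRHFS weights of the selected features (the top
#' feature has coefficient 1); optionally a high-risk SV interval and the
#' banding thresholds on the risk-index scale (no risk <= t1 < low risk
#' <= t2 < high risk).
#'
#' @export
setClass("RiskModel",
  representation(terms = "numeric", hri = "numeric", thresholds = "numeric"))

setValidity("RiskModel", function(object) {
  if (is.null(names(object@terms)) || anyNA(object@terms))
    return("terms must be a named numeric vector without NA")
  if (any(object@terms < 0 | object@terms > 1))
    return("coefficients must lie in [0, 1]")
  if (length(object@thresholds) != 2L || diff(object@thresholds) <= 0)
    return("thresholds must be two increasing values")
  if (length(object@hri) == 2L && !anyNA(object@hri) &&
      diff(object@hri) <= 0)
    return("high-risk interval must have lower < upper")
  TRUE
})

#' Pooled confusion counts
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric", tn = "numeric",
                 fn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  k <- c(object@tp, object@fp, object@tn, object@fn)
  if (length(k) != 4L || anyNA(k) || any(k < 0))
    return("all four counts must be non-negative numbers")
  TRUE
})

#' Diagnostic metrics of a dichotomous risk detector
#'
#' Sensitivity, specificity and accuracy as proportions, the Youden index
#' (sensitivity + specificity - 1), and bookkeeping fields (number of
#' features, method identifier).
#'
#' @export
setClass("MetricsReport",
  representation(sensitivity = "numeric", specificity = "numeric",
                 accuracy = "numeric", youden = "numeric",
                 nFeatures = "integer", method = "character"))
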