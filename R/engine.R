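#' Aggregate weight-sum vector
#'
#' Row sums of the p x 3 matrix whose columns are the three active filter
#' models' normalized score vectors: one aggregated weight per feature.
#'
#' @param S numeric matrix with 3 columns, features in rows (canonical
#'   order).
#' @return named numeric vector.
#' @export
aggregateWeightSum <- function(S) {
  S <- as.matrix(S)
  if (ncol(S) != 3L) stop("S must have exactly 3 columns")
  rowSums(S)
}

#' Cumulative-contribution matrix
#'
#' For each of the three curves, the cumulative sum of the normalized
#' contributions taken in that model's ranking order, written back in
#' canonical feature order: entry (f, m) is the total normalized
#' contribution of all features ranked at or above f by model m. Each
#' column is non-decreasing along its model's ranking, starting at the
#' top-ranked feature's contribution of 1.
#'
#' @param curves list of 3 [ContributionCurve-class] objects sharing one
#'   feature universe.
#' @param featureOrder canonical feature order for the rows; defaults to
#'   the first curve's ranking sorted by name universe (pass the table's
#'   feature names for a canonical layout).
#' @return p x 3 numeric matrix, columns named by model id.
#' @export
buildCumulativeMatrix <- function(curves, featureOrder = NULL) {
  if (length(curves) != 3L) stop("exactly 3 curves required")
  if (is.null(featureOrder)) featureOrder <- curves[[1]]@orderedFeatures
  cols <- lapply(curves, function(cv) {
    cum <- cumsum(cv@contribution[cv@orderedFeatures])
    cum[featureOrder]
  })
  D <- do.call(cbind, cols)
  rownames(D) <- featureOrder
  colnames(D) <- vapply(curves, function(cv) cv@modelId, character(1))
  D
}

#' Effectiveness coefficients of the active filter models
#'
#' The vector-matrix product P = W x D: for each model m,
#' \eqn{P_m = \sum_f W[f] D[f, m]}. The greater the coefficient, the more
#' effective the filter model.
#'
#' @param W weight-sum vector (length p).
#' @param D p x 3 cumulative-contribution matrix.
#' @return numeric length 3, named by D's columns.
#' @export
effectiveness <- function(W, D) {
  D <- as.matrix(D)
  if (length(W) != nrow(D)) stop("W and D have mismatched dimensions")
  stats::setNames(as.numeric(W %*% D), colnames(D))
}

# score vectors, rankings and contribution curves for one filter model,
# memoised per tournament/pipeline run
.modelArtifacts <- function(table, config, cache = new.env()) {
  function(m) {
    if (!is.null(cache[[m]])) return(cache[[m]])
    fsv <- filterScores(table, m)[[1]]
    curve <- prefixAccuracyCurve(table, rankFeatures(fsv), config,
                                 modelId = m)
    cache[[m]] <- list(scores = fsv, curve = curve)
    cache[[m]]
  }
}

.votingState <- function(models, artifacts, featureOrder) {
  sc <- lapply(models, function(m) artifacts(m)$scores@s[featureOrder])
  S <- do.call(cbind, sc)
  dimnames(S) <- list(featureOrder, models)
  W <- aggregateWeightSum(S)
  curves <- lapply(models, function(m) artifacts(m)$curve)
  D <- buildCumulativeMatrix(curves, featureOrder)
  C <- do.call(cbind, lapply(curves, function(cv)
    cv@contribution[featureOrder]))
  dimnames(C) <- dimnames(D)
  # Class= named exactly: a partial match against the C slot would
  # otherwise hijack it
  methods::new(Class = "VotingState", activeModels = models, S = S, W = W,
               C = C, D = D, P = effectiveness(W, D))
}

#' Filter-model tournament
#'
#' Starts from three active filter models (the first three of the
#' candidate list, or a random triple when `seed` is given), computes the
#' effectiveness vector P of the active triple, records each active
#' model's coefficient, replaces the model with the smallest coefficient
#' by the next unused candidate, and repeats until every candidate has
#' been assessed. The three models with the largest recorded coefficients
#' win (ties broken by candidate-list order). A model assessed in several
#' rounds keeps its largest coefficient.
#'
#' @param table a [FeatureTable-class].
#' @param candidateModels ordered candidate list, >= 3 ids from
#'   [filterCatalog()].
#' @param config a [classifierConfig()].
#' @param seed optional seed for the random initial triple; `NULL` (the
#'   default) deterministically starts from the first three candidates.
#' @return list with `winners` (3 ids), `coefficients` (largest recorded
#'   coefficient per assessed model) and `history` (per-round active
#'   models and P).
#' @export
tournament <- function(table, candidateModels = filterCatalog(),
                       config = classifierConfig(), seed = NULL) {
  if (length(candidateModels) < 3L) stop("at least 3 candidate models required")
  featureOrder <- rownames(table)
  artifacts <- .modelArtifacts(table, config)
  active <- if (is.null(seed)) candidateModels[1:3]
            else .withSeed(seed, sample(candidateModels, 3L))
  unused <- setdiff(candidateModels, active)
  coefs <- numeric(0)
  history <- list()
  repeat {
    vs <- .votingState(active, artifacts, featureOrder)
    for (m in active)
      coefs[m] <- max(coefs[m], vs@P[m], na.rm = TRUE)
    history[[length(history) + 1L]] <- list(active = active, P = vs@P)
    if (!length(unused)) break
    worst <- active[which.min(vs@P)]
    active[active == worst] <- unused[1]
    unused <- unused[-1]
  }
  assessed <- candidateModels[candidateModels %in% names(coefs)]
  winners <- assessed[order(-coefs[assessed])][1:3]
  list(winners = winners, coefficients = coefs, history = history)
}

#' Fused feature weighting from effectiveness and contributions
#'
#' The final weight of feature f is \eqn{W_r[f] = \sum_m P_m C[f, m]}: the
#' contribution matrix of the winning models weighted by their
#' effectiveness coefficients. Shares, cumulative shares (descending
#' weight order), min-max-normalized weights and the selected top-N subset
#' are derived with [featureWeighting()].
#'
#' @param P effectiveness vector of the 3 winning models.
#' @param C p x 3 matrix of normalized wrapper contributions, columns in
#'   the same model order as P.
#' @param threshold cumulative-share selection threshold (default 0.5).
#' @return a [FeatureWeighting-class].
#' @export
featureWeights <- function(P, C, threshold = 0.5) {
  C <- as.matrix(C)
  if (ncol(C) != length(P)) stop("P and C have mismatched dimensions")
  Wr <- stats::setNames(as.numeric(C %*% P), rownames(C))
  featureWeighting(Wr, threshold = threshold)
}

#' Build a FeatureWeighting from a weight vector
#'
#' Computes each feature's share of the total weight, the cumulative share
#' in descending-weight order (ties broken by canonical order), the
#' min-max-normalized weights, and the selected subset under the strict
#' >threshold cumulative-share rule.
#'
#' @param Wr named numeric weight vector; must not be all zero.
#' @param threshold selection threshold in (0, 1).
#' @return a [FeatureWeighting-class].
#' @export
featureWeighting <- function(Wr, threshold = 0.5) {
  if (all(Wr == 0)) stop("degenerate weighting: all weights are zero")
  if (is.null(names(Wr))) stop("weights must be named")
  ord <- order(-Wr, seq_along(Wr))
  share <- Wr / sum(Wr)
  cs <- cumsum(share[ord])
  w <- methods::new("FeatureWeighting", Wr = Wr, share = share,
                    order = names(Wr)[ord], cumulativeShare = unname(cs),
                    weight01 = stats::setNames(minmaxNormalize(Wr), names(Wr)),
                    selected = character(0), N = 0L, threshold = threshold)
  w@selected <- selectTopFeatures(w, threshold)
  w@N <- length(w@selected)
  methods::validObject(w)
  w
}

#' Select the top-N features by cumulative contribution share
#'
#' Returns the minimal prefix of the descending-weight feature order whose
#' cumulative share of the total weight strictly exceeds the threshold
#' ("more than 50%" by default).
#'
#' @param weighting a [FeatureWeighting-class].
#' @param threshold share threshold in (0, 1), exclusive.
#' @return ordered character vector of selected feature names.
#' @export
selectTopFeatures <- function(weighting, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  N <- which(weighting@cumulativeShare > threshold)[1]
  weighting@order[seq_len(N)]
}

#' @rdname featureWeights
#' @param x a [FeatureWeighting-class] or [WRHFSFit-class]
#' @aliases featureWeightsOf selectedFeatures
#' @export
setMethod("featureWeightsOf", "FeatureWeighting", function(x) x@Wr)

#' @rdname featureWeights
#' @export
setMethod("selectedFeatures", "FeatureWeighting", function(x) x@selected)

#' @rdname featureWeights
#' @export
setMethod("featureWeightsOf", "WRHFSFit", function(x) x@weighting@Wr)

#' @rdname featureWeights
#' @export
setMethod("selectedFeatures", "WRHFSFit", function(x) x@weighting@selected)

#' Run the full WRHFS pipeline
#'
#' Scores features with the candidate filters, derives each filter's
#' prefix-accuracy contributions with the cross-validated classifier, runs
#' the tournament to keep the three most effective filters (unless
#' `models` fixes them), and fuses scores and contributions into the final
#' feature weighting and top-N selection.
#'
#' @param table a [FeatureTable-class].
#' @param config a [classifierConfig()].
#' @param candidateModels candidate filter ids (>= 3).
#' @param models optional fixed triple of filter ids, skipping the
#'   tournament.
#' @param threshold cumulative-share selection threshold.
#' @param seed optional tournament initialisation seed (see
#'   [tournament()]).
#' @return a [WRHFSFit-class].
#' @export
runWRHFS <- function(table, config = classifierConfig(),
                     candidateModels = filterCatalog(), models = NULL,
                     threshold = 0.5, seed = NULL) {
  featureOrder <- rownames(table)
  artifacts <- .modelArtifacts(table, config)
  if (is.null(models)) {
    tn <- tournament(table, candidateModels, config, seed)
    models <- tn$winners
    coefs <- tn$coefficients
    history <- tn$history
  } else {
    if (length(models) != 3L) stop("exactly 3 fixed models required")
    coefs <- numeric(0)
    history <- list()
  }
  vs <- .votingState(models, artifacts, featureOrder)
  if (!length(coefs)) coefs <- vs@P
  weighting <- featureWeights(vs@P, vs@C, threshold)
  methods::new("WRHFSFit", models = models, voting = vs,
               weighting = weighting, coefficients = coefs,
               history = history)
}

setMethod("show", "VotingState", function(object) {
  cat("VotingState:", paste(object@activeModels, collapse = ", "), "\n")
  cat("P:", paste(sprintf("%s=%.2f", names(object@P), object@P),
                  collapse = ", "), "\n")
})

setMethod("show", "FeatureWeighting", function(object) {
  cat(sprintf("FeatureWeighting: %d features, %d selected (>%d%% cumulative share)\n",
              length(object@Wr), object@N, round(100 * object@threshold)))
  cat("selected:", paste(object@selected, collapse = ", "), "\n")
})

setMethod("show", "WRHFSFit", function(object) {
  cat("WRHFSFit with models:", paste(object@models, collapse = ", "), "\n")
  show(object@weighting)
})
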