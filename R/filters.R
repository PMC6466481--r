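#' The candidate filter catalog
#'
#' Fixed order of the six candidate filter models used by the tournament
#' when no random initialisation seed is given.
#'
#' @return character vector of model ids.
#' @export
filterCatalog <- function()
  c("std", "pearson", "fisher", "infogain", "relief", "chi2")

# population (1/n) standard deviation
.popSD <- function(x) sqrt(mean((x - mean(x))^2))

# subjects x features matrix with every feature min-max scaled to [0, 1];
# scoring on the unit interval makes spread-based scores comparable across
# clinical units and all scorers invariant to affine rescaling of a feature
.scaledValues <- function(table)
  apply(featureValues(table), 2, minmaxNormalize)

.newFSV <- function(modelId, raw) {
  methods::new("FilterScoreVector", modelId = modelId, rawScores = raw,
               s = stats::setNames(minmaxNormalize(raw), names(raw)),
               ranking = names(raw)[order(-raw, seq_along(raw))])
}

#' Filter scorers
#'
#' Each scorer maps a [FeatureTable-class] to a [FilterScoreVector-class]:
#' one raw score per feature (canonical order), its min-max normalisation
#' `s`, and the descending-score ranking with ties broken by canonical
#' feature order.
#'
#' * `scoreStd()`: population standard deviation of each feature after
#'   min-max scaling to \[0, 1\] (so a constant feature scores 0 and a
#'   balanced binary feature 0.5).
#' * `scorePearson()`: absolute Pearson correlation between the feature and
#'   the 1/0-encoded labels; 0 for a constant feature.
#' * `scoreFisher()`: between-class mean scatter over pooled within-class
#'   variance, \eqn{[n_1(\mu_1-\mu)^2 + n_2(\mu_2-\mu)^2] /
#'   [n_1\sigma_1^2 + n_2\sigma_2^2]} with population variances. A feature
#'   with zero within-class variance but separated class means (a perfect
#'   separator) receives ten times the largest finite score so it ranks
#'   first without propagating infinities; 0/0 scores 0.
#' * `scoreInfoGain()`: information gain H(Y) - H(Y|X) in bits, with
#'   continuous features discretized by equal-frequency binning into at
#'   most 10 bins (fewer when the feature has fewer distinct values);
#'   clipped below at 0.
#' * `scoreChi2()`: Pearson chi-squared statistic of the binned-feature by
#'   label contingency table (same discretization as the information gain).
#' * `scoreRelief()`: Relief weights on min-max-scaled features with
#'   Manhattan distance and a single nearest hit/miss. By default every
#'   subject is visited once in order (a deterministic full sweep); the
#'   classic randomized variant draws `nIterations` subjects with
#'   replacement under `seed`. Weights are averaged over iterations.
#'   Requires at least 2 subjects per class.
#'
#' @param table a [FeatureTable-class].
#' @param nIterations number of Relief iterations; `NULL` for the
#'   deterministic full sweep.
#' @param seed seed for the randomized Relief variant.
#' @return a [FilterScoreVector-class].
#' @name filterScorers
NULL

#' @rdname filterScorers
#' @export
scoreStd <- function(table) {
  v <- .scaledValues(table)
  .newFSV("std", apply(v, 2, .popSD))
}

#' @rdname filterScorers
#' @export
scorePearson <- function(table) {
  y <- .y01(classLabels(table))
  raw <- apply(featureValues(table), 2, function(x) {
    if (.popSD(x) == 0 || .popSD(y) == 0) return(0)
    abs(stats::cor(x, y))
  })
  .newFSV("pearson", raw)
}

#' @rdname filterScorers
#' @export
scoreFisher <- function(table) {
  v <- .scaledValues(table)
  y <- classLabels(table)
  i1 <- y == 1L; i2 <- y == 2L
  n1 <- sum(i1); n2 <- sum(i2)
  raw <- apply(v, 2, function(x) {
    mu <- mean(x); mu1 <- mean(x[i1]); mu2 <- mean(x[i2])
    num <- n1 * (mu1 - mu)^2 + n2 * (mu2 - mu)^2
    den <- n1 * mean((x[i1] - mu1)^2) + n2 * mean((x[i2] - mu2)^2)
    if (den == 0) if (num == 0) 0 else Inf else num / den
  })
  if (any(is.infinite(raw))) {
    finite <- raw[is.finite(raw)]
    cap <- if (length(finite) && max(finite) > 0) 10 * max(finite) else 10
    raw[is.infinite(raw)] <- cap
  }
  .newFSV("fisher", raw)
}

# Equal-frequency discretization used by the information-gain and
# chi-squared scorers: at most `bins` quantile bins; features with few
# distinct values are used as-is.
.discretize <- function(x, bins = 10L) {
  ux <- unique(x)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               type = 7))
  if (length(br) < 3L) return(match(x, sort(ux)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

.entropyBits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' @rdname filterScorers
#' @export
scoreInfoGain <- function(table) {
  y <- classLabels(table)
  hy <- .entropyBits(table(y))
  raw <- apply(featureValues(table), 2, function(x) {
    b <- .discretize(x)
    tab <- table(b, y)
    hcond <- sum(rowSums(tab) / length(y) * apply(tab, 1, .entropyBits))
    max(0, hy - hcond)
  })
  .newFSV("infogain", raw)
}

#' @rdname filterScorers
#' @export
scoreChi2 <- function(table) {
  y <- classLabels(table)
  raw <- apply(featureValues(table), 2, function(x) {
    tab <- table(.discretize(x), y)
    if (nrow(tab) < 2L) return(0)
    suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  })
  .newFSV("chi2", raw)
}

#' @rdname filterScorers
#' @export
scoreRelief <- function(table, nIterations = NULL, seed = 1L) {
  v <- .scaledValues(table)
  y <- classLabels(table)
  if (min(table(y)) < 2L)
    stop("Relief requires at least 2 subjects per class (no nearest hit otherwise)")
  n <- nrow(v)
  visits <- if (is.null(nIterations)) seq_len(n)
            else .withSeed(seed, sample.int(n, as.integer(nIterations),
                                            replace = TRUE))
  w <- numeric(ncol(v))
  for (i in visits) {
    d <- rowSums(abs(sweep(v, 2, v[i, ], "-")))
    d[i] <- Inf
    same <- y == y[i]
    hit <- which(same)[which.min(d[same])]
    miss <- which(!same)[which.min(d[!same])]
    w <- w + abs(v[i, ] - v[miss, ]) - abs(v[i, ] - v[hit, ])
  }
  .newFSV("relief", stats::setNames(w / length(visits), colnames(v)))
}

#' Compute several filter score vectors at once
#'
#' @param table a [FeatureTable-class].
#' @param models model ids from [filterCatalog()].
#' @param reliefIterations,reliefSeed passed to [scoreRelief()].
#' @return named list of [FilterScoreVector-class] objects.
#' @export
filterScores <- function(table, models = filterCatalog(),
                         reliefIterations = NULL, reliefSeed = 1L) {
  bad <- setdiff(models, filterCatalog())
  if (length(bad)) stop("unknown filter model(s): ", paste(bad, collapse = ", "))
  fns <- list(std = scoreStd, pearson = scorePearson, fisher = scoreFisher,
              infogain = scoreInfoGain, chi2 = scoreChi2)
  out <- lapply(models, function(m) {
    if (m == "relief") scoreRelief(table, reliefIterations, reliefSeed)
    else fns[[m]](table)
  })
  stats::setNames(out, models)
}

#' Feature ranking of a score vector
#'
#' Orders features by descending raw score; ties are broken by canonical
#' feature order, giving a total order over all features.
#'
#' @param scores a [FilterScoreVector-class].
#' @return character vector of feature names.
#' @export
rankFeatures <- function(scores) scores@ranking

#' FilterScoreVector accessors
#' @param x a [FilterScoreVector-class]
#' @name filterScores
#' @aliases rawScores normalizedScores featureRanking
NULL

#' @rdname filterScores
#' @export
setMethod("rawScores", "FilterScoreVector", function(x) x@rawScores)

#' @rdname filterScores
#' @export
setMethod("normalizedScores", "FilterScoreVector", function(x) x@s)

#' @rdname rankFeatures
#' @param x a [FilterScoreVector-class] or [ContributionCurve-class]
#' @export
setMethod("featureRanking", "FilterScoreVector", function(x) x@ranking)

setMethod("show", "FilterScoreVector", function(object) {
  cat(sprintf("FilterScoreVector '%s': %d features\n", object@modelId,
              length(object@rawScores)))
  cat("top:", paste(utils::head(object@ranking, 5), collapse = " > "), "\n")
})
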