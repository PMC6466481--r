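#' Build a synthetic-value risk model
#'
#' The synthetic value SV of a subject is the linear combination of the
#' selected features' raw clinical values with their min-max-normalized
#' WRHFS weights; the top-weighted feature enters with coefficient 1.
#' Risk-index thresholds band the index into no risk (<= 1.5), low risk
#' (<= 2) and high risk (> 2).
#'
#' @param weighting a [FeatureWeighting-class] (or [WRHFSFit-class]); the
#'   selected features' normalized weights become the SV coefficients.
#' @param terms alternatively, a named coefficient vector in \[0, 1\].
#' @param hri optional high-risk SV interval `c(lower, upper)`.
#' @param thresholds risk-index banding thresholds, default `c(1.5, 2)`.
#' @return a [RiskModel-class].
#' @export
riskModel <- function(weighting = NULL, terms = NULL,
                      hri = c(NA_real_, NA_real_), thresholds = c(1.5, 2)) {
  if (is.null(terms)) {
    if (methods::is(weighting, "WRHFSFit")) weighting <- weighting@weighting
    if (!methods::is(weighting, "FeatureWeighting"))
      stop("provide a FeatureWeighting or explicit terms")
    terms <- weighting@weight01[weighting@selected]
  }
  methods::new("RiskModel", terms = terms, hri = as.numeric(hri),
               thresholds = thresholds)
}

#' The published ischemic-stroke risk model
#'
#' The 9-term synthetic-value model reported by the reference stroke
#' study: SV = AGE + 0.42 a-HBD + 0.38 SCr + 0.30 LDH + 0.30 Height +
#' 0.27 TBIL + 0.22 CK + 0.20 Apo-B + 0.19 CK-MB, with the high-risk SV
#' interval (1675, 2175). The coefficients equal the normalized weights of
#' the 9 selected features in the shipped reference weighting table.
#'
#' @return a [RiskModel-class].
#' @export
strokeRiskModel <- function() {
  fx <- wrhfsFixtures()$finalWeights
  sel <- fx[seq_len(9), ]
  riskModel(terms = stats::setNames(sel$weight01, sel$feature),
            hri = c(1675, 2175))
}

#' Synthetic value of one or more subjects
#'
#' SV = sum over model terms of coefficient x feature value, with features
#' in their raw clinical units. Linear in the feature values.
#'
#' @param sample named numeric vector of feature values, or a matrix /
#'   data.frame / [FeatureTable-class] with named feature columns; every
#'   model term must be present.
#' @param model a [RiskModel-class].
#' @return numeric SV, one per subject.
#' @export
syntheticValue <- function(sample, model) {
  if (methods::is(sample, "FeatureTable")) sample <- featureValues(sample)
  if (is.null(dim(sample))) sample <- matrix(sample, 1,
    dimnames = list(NULL, names(sample)))
  sample <- as.matrix(sample)
  missing <- setdiff(names(model@terms), colnames(sample))
  if (length(missing))
    stop("missing model feature(s): ", paste(missing, collapse = ", "))
  as.numeric(sample[, names(model@terms), drop = FALSE] %*% model@terms)
}

#' Band a risk index into no / low / high risk
#'
#' Values at or below the first threshold mean no risk, values above it
#' but at or below the second mean low risk, and values above the second
#' mean high risk (boundaries belong to the lower band).
#'
#' @param index numeric risk-index values (finite).
#' @param thresholds two increasing thresholds, default `c(1.5, 2)`.
#' @return factor with levels `none`, `low`, `high`.
#' @export
riskRank <- function(index, thresholds = c(1.5, 2)) {
  stopifnot(all(is.finite(index)), length(thresholds) == 2L,
            diff(thresholds) > 0)
  cut(index, breaks = c(-Inf, thresholds, Inf),
      labels = c("none", "low", "high"), right = TRUE)
}

#' Empirical age-by-SV risk surface
#'
#' Computes each subject's synthetic value, then estimates the class-1
#' (case) frequency on an age x SV grid by Nadaraya-Watson
#' kernel smoothing (Gaussian product kernel), so empty grid cells borrow
#' strength from their neighbours. The smoothed frequency in \[0, 1\] is
#' mapped onto the risk-index scale as `index = 1 + 2 * frequency`, a
#' documented convention under which the banding thresholds 1.5 and 2
#' correspond to case frequencies of 25% and 50%. Deterministic.
#'
#' @param table a labeled [FeatureTable-class].
#' @param model a [RiskModel-class].
#' @param ageFeature name of the age feature.
#' @param ageRange age interval covered by the grid (subjects outside it
#'   are dropped), default 45-90 years.
#' @param nAgeBins,nSvBins grid resolution (defaults 46 x 50).
#' @param bandwidths Gaussian kernel bandwidths `c(age, sv)`; defaults to
#'   one tenth of each axis range.
#' @return data.frame with `age`, `sv`, `frequency`, `riskIndex`, `band`
#'   (one row per grid cell).
#' @export
riskSurface <- function(table, model, ageFeature = "AGE",
                        ageRange = c(45, 90), nAgeBins = 46L, nSvBins = 50L,
                        bandwidths = NULL) {
  v <- featureValues(table)
  if (!ageFeature %in% colnames(v)) stop("age feature not found: ", ageFeature)
  age <- v[, ageFeature]
  keep <- age >= ageRange[1] & age <= ageRange[2]
  if (!any(keep)) stop("no subjects within the age range; empty grid")
  age <- age[keep]
  sv <- syntheticValue(v[keep, , drop = FALSE], model)
  y <- .y01(classLabels(table))[keep]
  svRange <- range(sv)
  if (svRange[1] == svRange[2]) svRange <- svRange + c(-0.5, 0.5)
  if (is.null(bandwidths))
    bandwidths <- c(diff(ageRange) / 10, diff(svRange) / 10)
  ageGrid <- seq(ageRange[1], ageRange[2], length.out = nAgeBins)
  svGrid <- seq(svRange[1], svRange[2], length.out = nSvBins)
  grid <- expand.grid(age = ageGrid, sv = svGrid)
  freq <- vapply(seq_len(nrow(grid)), function(i) {
    w <- exp(-0.5 * (((age - grid$age[i]) / bandwidths[1])^2 +
                     ((sv - grid$sv[i]) / bandwidths[2])^2))
    sum(w * y) / sum(w)
  }, numeric(1))
  grid$frequency <- freq
  grid$riskIndex <- 1 + 2 * freq
  grid$band <- riskRank(grid$riskIndex, model@thresholds)
  grid
}

setMethod("show", "RiskModel", function(object) {
  cat("RiskModel: SV =",
      paste(sprintf("%.2g x %s", object@terms, names(object@terms)),
            collapse = " + "), "\n")
  if (!anyNA(object@hri))
    cat(sprintf("high-risk SV interval: (%g, %g)\n", object@hri[1],
                object@hri[2]))
})
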