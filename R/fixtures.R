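.fixtureEnv <- new.env(parent = emptyenv())

#' Reference tables of the original WRHFS stroke study
#'
#' Loads the printed reference tables from the original ischemic-stroke
#' application of WRHFS (792 subjects, 28 features: 24 blood-test items
#' plus gender, age, height and BMI), shipped as plain CSV fixtures:
#'
#' * `effectiveness`: the effectiveness coefficient of each of the six
#'   candidate filter models.
#' * `sdCurve`: the standard-deviation filter's full wrapper record --
#'   per-feature scaled SD, tuned SVM penalty C and kernel bandwidth q,
#'   prefix accuracy (percent), raw and normalized accuracy contribution
#'   (the top-ranked feature's raw contribution is undefined), and the
#'   weight column as printed.
#' * `modelScores`: the normalized score vectors of the three winning
#'   filters (standard deviation, Relief, information gain) with their
#'   row-sum weight column, in canonical feature order.
#' * `contributionMatrices`: the published contribution and
#'   cumulative-contribution blocks for the three winning filters.
#' * `finalWeights`: the fused WRHFS feature weighting with shares,
#'   cumulative shares and min-max-normalized weights, in descending
#'   weight order.
#' * `selectionMetrics`: classification performance (confusion counts,
#'   sensitivity, specificity, accuracy, Youden index) of the SVM under
#'   WRHFS and the three single-filter baselines at their optimal feature
#'   counts.
#' * `featureCatalog`: name, full name, unit and value kind of the 28
#'   features.
#'
#' The tables are loaded read-only and byte-identical to the printed
#' values; [verifyFixtures()] checks their internal consistency.
#'
#' @return named list of data.frames (cached after the first call).
#' @export
wrhfsFixtures <- function() {
  if (!is.null(.fixtureEnv$fx)) return(.fixtureEnv$fx)
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "wrhfs", mustWork = TRUE),
    check.names = FALSE, stringsAsFactors = FALSE)
  fx <- list(effectiveness = rd("filter_effectiveness.csv"),
             sdCurve = rd("sd_prefix_curve.csv"),
             modelScores = rd("model_scores.csv"),
             contributionMatrices = rd("contribution_matrices.csv"),
             finalWeights = rd("final_weights.csv"),
             selectionMetrics = rd("selection_metrics.csv"),
             featureCatalog = rd("feature_catalog.csv"))
  .fixtureEnv$fx <- fx
  fx
}

#' Verify the internal consistency of the shipped reference tables
#'
#' Recomputes, from the fixture tables alone, the quantities that tie the
#' published pipeline together and checks them against the printed values:
#'
#' 1. the weight-sum column equals the row sums of the three normalized
#'    score columns to 4 decimal places;
#' 2. the effectiveness coefficients of the three winning filters equal the
#'    dot products of the weight-sum vector with the three cumulative
#'    contribution columns, after rounding to integers;
#' 3. the cumulative sum of the standard-deviation filter's normalized
#'    contributions (taken in its ranking order) matches the published
#'    cumulative column within 0.03 at every feature (the inputs are
#'    printed at 2 decimal places);
#' 4. min-max normalisation, shares and the strict >50% cumulative-share
#'    rule reproduce the published final weighting columns and the
#'    9-feature selection.
#'
#' @param quiet suppress the per-check messages.
#' @return `TRUE` invisibly; stops at the first failing check.
#' @export
verifyFixtures <- function(quiet = FALSE) {
  fx <- wrhfsFixtures()
  say <- function(...) if (!quiet) message(sprintf(...))
  ms <- fx$modelScores
  S <- as.matrix(ms[c("std", "relief", "infogain")])
  # the printed column carries last-digit rounding: 5 of 28 rows differ
  # from their own row sums by exactly 1e-4, so "agreement to 4 dp" means
  # within one unit in the fourth decimal place
  if (max(abs(rowSums(S) - ms$weight_sum)) > 1e-4 + 1e-12)
    stop("weight-sum column does not equal the score row sums")
  say("weight sums match score row sums (4 dp)")

  cm <- fx$contributionMatrices
  stopifnot(identical(cm$feature, ms$feature))
  D <- as.matrix(cm[c("std_cumulative", "relief_cumulative",
                      "infogain_cumulative")])
  P <- round(as.numeric(ms$weight_sum %*% D))
  want <- fx$effectiveness
  ref <- want$coefficient[match(c("std", "relief", "infogain"), want$method)]
  if (!all(P == ref))
    stop("effectiveness coefficients do not reproduce the published values")
  say("effectiveness coefficients reproduce %s", paste(P, collapse = "/"))

  sd5 <- fx$sdCurve
  contr <- sd5$contribution01
  cum <- cumsum(contr)
  pub <- cm$std_cumulative[match(sd5$feature, cm$feature)]
  if (max(abs(cum - pub)) > 0.03)
    stop("cumulative contributions diverge from the published column")
  say("cumulative standard-deviation contributions match within 0.03")

  w8 <- fx$finalWeights
  w01 <- minmaxNormalize(w8$weight)
  if (max(abs(w01 - w8$weight01)) > 0.005 + 1e-9)
    stop("normalized weights do not reproduce the published column")
  share <- w8$weight / sum(w8$weight)
  if (abs(share[1] - w8$share[1]) > 0.005 + 1e-9)
    stop("weight shares do not reproduce the published column")
  N <- which(cumsum(share) > 0.5)[1]
  if (N != sum(fx$selectionMetrics$n_features[
        fx$selectionMetrics$method == "WRHFS"]))
    stop("the >50% rule does not select the published number of features")
  say("final weighting columns and the %d-feature selection reproduce", N)
  invisible(TRUE)
}
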