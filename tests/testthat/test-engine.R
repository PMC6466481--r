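# reference-table matrices used across the engine tests
fixtureMatrices <- function() {
  fx <- wrhfsFixtures()
  ms <- fx$modelScores
  cm <- fx$contributionMatrices
  stopifnot(identical(ms$feature, cm$feature))
  list(S = as.matrix(`rownames<-`(ms[c("std", "relief", "infogain")],
                                  ms$feature)),
       Wpub = stats::setNames(ms$weight_sum, ms$feature),
       D = as.matrix(`rownames<-`(cm[c("std_cumulative", "relief_cumulative",
                                       "infogain_cumulative")], cm$feature)),
       w8 = fx$finalWeights)
}

test_that("weight sums are row sums of the score matrix", {
  m <- fixtureMatrices()
  W <- aggregateWeightSum(m$S)
  # published column agrees within one unit in its 4th decimal place
  expect_lt(max(abs(W - m$Wpub)), 1e-4 + 1e-12)
  expect_equal(unname(W["a-HBD"]), 1.9124, tolerance = 1e-12)
  expect_equal(unname(W["LDH"]), 2.0254, tolerance = 1e-12)
  expect_equal(unname(aggregateWeightSum(matrix(0, 2, 3))), c(0, 0))
  expect_error(aggregateWeightSum(matrix(1, 2, 2)), "3 columns")
})

test_that("effectiveness is the W x D product with its linearity properties", {
  m <- fixtureMatrices()
  P <- effectiveness(aggregateWeightSum(m$S), m$D)
  expect_equal(round(unname(P)), c(52, 61, 63))
  expect_equal(unname(effectiveness(rep(0, 28), m$D)), c(0, 0, 0))
  expect_equal(effectiveness(2 * aggregateWeightSum(m$S), m$D), 2 * P)
  expect_error(effectiveness(1:3, m$D), "mismatch")
})

test_that("cumulative matrices accumulate contributions in ranking order", {
  feats <- c("a", "b", "c", "d")
  mk <- function(id, ord, contr)
    methods::new("ContributionCurve", modelId = id, orderedFeatures = ord,
                 prefixAccuracy = rep(60, 4),
                 tunedParams = data.frame(C = rep(NA, 4), q = NA),
                 rawContribution = stats::setNames(rep(NA_real_, 4), ord),
                 contribution = stats::setNames(contr, ord))
  c1 <- mk("m1", c("b", "a", "d", "c"), c(1, 0.5, 0, 0.25))
  c2 <- mk("m2", feats, c(1, 0, 0, 1))
  c3 <- mk("m3", rev(feats), c(1, 1, 1, 1))
  D <- buildCumulativeMatrix(list(c1, c2, c3), feats)
  expect_equal(unname(D[, "m1"]), c(1.5, 1, 1.75, 1.5)) # a,b,c,d
  expect_equal(unname(D[, "m2"]), c(1, 1, 1, 2))
  expect_equal(unname(D[, "m3"]), c(4, 3, 2, 1))
  # columns are non-decreasing along each model's ranking
  expect_true(all(diff(D[c1@orderedFeatures, "m1"]) >= 0))
  # top-ranked feature's cumulative value equals its contribution (1)
  expect_equal(unname(D["b", "m1"]), 1)
  # adjacent zero-contribution features share a cumulative value (ties)
  expect_equal(unname(D["b", "m2"]), unname(D["c", "m2"]))
})

test_that("cumulative sums of the published SD contributions match the printed column", {
  fx <- wrhfsFixtures()
  cum <- cumsum(fx$sdCurve$contribution01) # in the SD model's rank order
  pub <- fx$contributionMatrices$std_cumulative[
    match(fx$sdCurve$feature, fx$contributionMatrices$feature)]
  expect_lt(max(abs(cum - pub)), 0.03) # inputs printed at 2 dp
  tie <- abs(pub[fx$sdCurve$feature %in% c("Height", "a-HBD")] - 1.6654)
  expect_true(all(tie < 1e-12)) # the published Height/a-HBD tie
})

test_that("fused weights are the P-weighted contribution sums with consistent shares", {
  C <- matrix(c(1, 1, 1,
                0.5, 0, 0.2,
                0, 0.5, 0.1,
                0.2, 0.1, 0), 4, 3, byrow = TRUE,
              dimnames = list(c("w", "x", "y", "z"), c("m1", "m2", "m3")))
  P <- c(m1 = 52, m2 = 61, m3 = 63)
  fw <- featureWeights(P, C)
  expect_equal(unname(featureWeightsOf(fw)["w"]), 176) # all-ones row
  expect_equal(sum(fw@share), 1)
  expect_equal(fw@cumulativeShare[length(fw@cumulativeShare)], 1)
  # linearity: doubling P doubles every weight
  expect_equal(featureWeightsOf(featureWeights(2 * P, C)),
               2 * featureWeightsOf(fw))
  # consistent column permutation leaves the weights unchanged
  perm <- c(3, 1, 2)
  expect_equal(featureWeightsOf(featureWeights(P[perm], C[, perm])),
               featureWeightsOf(fw))
  expect_error(featureWeights(c(0, 0, 0), matrix(0, 4, 3)), "degenerate")
})

test_that("the >50% rule reproduces the published selection and edge cases", {
  m <- fixtureMatrices()
  fw <- featureWeighting(stats::setNames(m$w8$weight, m$w8$feature))
  expect_equal(fw@N, 9L)
  expect_identical(selectedFeatures(fw),
                   c("AGE", "a-HBD", "SCr", "LDH", "Height", "TBIL", "CK",
                     "Apo-B", "CK-MB"))
  expect_lt(abs(fw@share["AGE"] - 0.13), 0.005)
  expect_lt(abs(fw@weight01["SCr"] - 0.38), 0.005)
  expect_lt(abs(fw@weight01["a-HBD"] - 0.42), 0.005)
  # uniform weights over 4 features: 0.5 strictly exceeded at the 3rd
  u <- featureWeighting(c(a = 1, b = 1, c = 1, d = 1))
  expect_identical(selectedFeatures(u), c("a", "b", "c"))
  expect_error(selectTopFeatures(u, 1.5), "threshold")
})

test_that("the tournament assesses every candidate and keeps the best three", {
  ft <- plantedCohort(n = 120, nInf = 2, nNoise = 2, d = 2.5, seed = 31)
  cfg <- classifierConfig(penaltyGrid = 1, bandwidthGrid = 2, cvFolds = 3,
                          seed = 31)
  tn <- tournament(ft, filterCatalog(), cfg)
  expect_length(tn$winners, 3L)
  expect_setequal(names(tn$coefficients), filterCatalog()) # all assessed
  expect_identical(sort(tn$coefficients[tn$winners], decreasing = TRUE),
                   sort(tn$coefficients, decreasing = TRUE)[1:3])
  # three candidates: a single round returns all of them
  tn3 <- tournament(ft, c("pearson", "fisher", "chi2"), cfg)
  expect_setequal(tn3$winners, c("pearson", "fisher", "chi2"))
  expect_length(tn3$history, 1L)
  expect_error(tournament(ft, c("std", "relief"), cfg), "3 candidate")
  # deterministic rerun
  expect_identical(tn$winners, tournament(ft, filterCatalog(), cfg)$winners)
})

test_that("the full pipeline recovers strong planted features", {
  ft <- plantedCohort(n = 200, nInf = 2, nNoise = 4, d = 2.5, seed = 17)
  fit <- runWRHFS(ft, fastConfig(17), models = c("std", "relief", "infogain"))
  expect_s4_class(fit, "WRHFSFit")
  expect_true(all(selectedFeatures(fit) %in% informativeFeatures(ft)))
  top2 <- names(sort(featureWeightsOf(fit), decreasing = TRUE))[1:2]
  expect_setequal(top2, informativeFeatures(ft))
  vs <- fit@voting
  expect_equal(vs@W, rowSums(vs@S))
  expect_true(all(vs@P > 0))
})
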