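test_that("standard-deviation scores follow the closed forms on scaled features", {
  ft <- featureTable(cbind(const = rep(3, 10),
                           bal = rep(c(0, 1), 5),
                           skew = c(rep(0, 9), 1)),
                     labels = rep(c(1, 2), 5))
  raw <- rawScores(scoreStd(ft))
  expect_equal(unname(raw), c(0, 0.5, 0.3)) # 0, sqrt(.25), sqrt(.1*.9)
  expect_equal(unname(normalizedScores(scoreStd(ft))["const"]), 0)
})

test_that("Pearson scorer is absolute and matches a hand computation", {
  y <- c(1, 1, 2, 2) # cases first; encoded 1,1,0,0
  ft <- featureTable(cbind(same = c(1, 1, 0, 0), neg = c(0, 0, 1, 1),
                           x = c(1, 2, 3, 4)), labels = y)
  raw <- rawScores(scorePearson(ft))
  expect_equal(unname(raw[c("same", "neg")]), c(1, 1))
  expect_equal(unname(raw["x"]), 0.8944, tolerance = 1e-4)
})

test_that("Fisher score matches the two-class formula and its scaling law", {
  ft <- featureTable(cbind(f = c(0, 1, 2, 3), g = c(5, 6, 5, 6)),
                     labels = c(1, 1, 2, 2))
  raw <- rawScores(scoreFisher(ft))
  # class means 0.5/2.5, variances 0.25 each -> (2+2)/(0.5+0.5) = 4
  expect_equal(unname(raw["f"]), 4)
  expect_equal(unname(raw["g"]), 0) # identical class-conditional distributions
  # doubling the gap between class means at fixed variances quadruples it
  ft2 <- featureTable(cbind(f = c(0, 1, 4, 5), g = c(5, 6, 5, 6)),
                      labels = c(1, 1, 2, 2))
  expect_equal(unname(rawScores(scoreFisher(ft2))["f"]), 16)
  # perfect separator: zero within-class variance, distinct means
  ft3 <- featureTable(cbind(f = c(0, 0, 1, 1), g = c(0, 1, 2, 3)),
                      labels = c(1, 1, 2, 2))
  r3 <- rawScores(scoreFisher(ft3))
  expect_true(is.finite(r3["f"]) && r3["f"] > r3["g"])
  expect_identical(names(which.max(r3)), "f")
})

test_that("information gain matches entropy arithmetic", {
  # label-copy feature on a balanced cohort: IG = H(Y) = 1 bit
  y <- rep(c(1, 2), 10)
  ft <- featureTable(cbind(copy = as.numeric(y == 1), junk = rep(1, 20)),
                     labels = y)
  raw <- rawScores(scoreInfoGain(ft))
  expect_equal(unname(raw["copy"]), 1)
  expect_equal(unname(raw["junk"]), 0)
  # 2x2 counts [[8,2],[2,8]]: IG = 1 - H(0.2) = 0.2781 bits
  x <- c(rep(0, 10), rep(1, 10))
  y2 <- c(rep(1, 8), rep(2, 2), rep(1, 2), rep(2, 8))
  ft2 <- featureTable(cbind(f = x, pad = seq_len(20)), labels = y2)
  expect_equal(unname(rawScores(scoreInfoGain(ft2))["f"]),
               1 - .entropy2(0.2), tolerance = 1e-10)
  # independent feature on a large null cohort scores near zero
  ft0 <- plantedCohort(n = 2000, nInf = 0, nNoise = 2, d = 0, seed = 9)
  expect_true(all(rawScores(scoreInfoGain(ft0)) < 0.05))
})

test_that("chi-squared scorer matches the contingency closed form", {
  x <- c(rep(0, 10), rep(1, 10))
  y <- c(rep(1, 10), rep(2, 10))
  ft <- featureTable(cbind(f = x, pad = seq_len(20)), labels = y)
  expect_equal(unname(rawScores(scoreChi2(ft))["f"]), 20) # [[10,0],[0,10]]
  # doubling all counts doubles the statistic
  ft2 <- featureTable(cbind(f = rep(x, 2), pad = seq_len(40)),
                      labels = rep(y, 2))
  expect_equal(unname(rawScores(scoreChi2(ft2))["f"]), 40)
  # proportional table -> 0
  ftp <- featureTable(cbind(f = rep(c(0, 1), each = 10), pad = 1:20),
                      labels = rep(c(1, 2, 1, 2), 5))
  expect_equal(unname(rawScores(scoreChi2(ftp))["f"]), 0)
})

test_that("Relief agrees with a brute-force all-pairs oracle", {
  ft <- toyTable()
  expect_equal(rawScores(scoreRelief(ft)), reliefOracle(ft))
  for (seed in 1:3) {
    ftr <- plantedCohort(n = 10, nInf = 2, nNoise = 2, d = 1, seed = seed)
    expect_equal(rawScores(scoreRelief(ftr)), reliefOracle(ftr))
  }
  # fully separated feature dominates; constant feature is weightless
  ftx <- featureTable(cbind(sep = c(0, 0, 0, 1, 1, 1),
                            const = rep(2, 6),
                            noise = c(0.2, 0.9, 0.4, 0.8, 0.1, 0.5)),
                      labels = c(1, 1, 1, 2, 2, 2))
  w <- rawScores(scoreRelief(ftx))
  expect_identical(names(which.max(w)), "sep")
  expect_equal(unname(w["const"]), 0)
  expect_error(scoreRelief(featureTable(cbind(a = 1:4, b = 4:1),
                                        c(1, 2, 2, 2))), "2 subjects per class")
})

test_that("rankings are descending with canonical tie-breaks", {
  fsv <- scorePearson(featureTable(cbind(a = c(1, 2, 2, 1), # |r| = 0
                                         b = c(1, 1, 0, 0),
                                         c = c(0, 0, 1, 1)),
                                   labels = c(1, 1, 2, 2)))
  expect_identical(rankFeatures(fsv), c("b", "c", "a")) # b/c tie -> file order
  raw <- c(x = 0.3, y = 0.9, z = 0.1)
  fake <- methods::new("FilterScoreVector", modelId = "std", rawScores = raw,
                       s = minmaxNormalize(raw),
                       ranking = names(raw)[order(-raw, 1:3)])
  expect_identical(rankFeatures(fake), c("y", "x", "z"))
})

test_that("scorers are invariant to sample order and to affine feature rescaling", {
  ft <- plantedCohort(n = 60, nInf = 2, nNoise = 2, d = 1.5, seed = 5)
  v <- featureValues(ft)
  perm <- withr::with_seed(2, sample(nrow(v)))
  ftp <- featureTable(v[perm, ], classLabels(ft)[perm])
  ftAff <- featureTable(sweep(sweep(v, 2, c(3, 0.1, 7, 2), "*"),
                              2, c(-5, 40, 0, 1), "+"),
                        classLabels(ft))
  for (scorer in list(scoreStd, scorePearson, scoreFisher, scoreRelief)) {
    ref <- rawScores(scorer(ft))
    expect_equal(rawScores(scorer(ftp)), ref, tolerance = 1e-10)
    expect_equal(rawScores(scorer(ftAff)), ref, tolerance = 1e-10)
  }
  for (scorer in list(scoreInfoGain, scoreChi2))
    expect_equal(rawScores(scorer(ftp)), rawScores(scorer(ft)),
                 tolerance = 1e-10)
})

test_that("every scorer separates planted from noise features on strong-signal cohorts", {
  # d = 3 so that even the label-blind spread scorer sees the
  # mixture-variance inflation clearly
  hits <- sapply(1:20, function(seed) {
    ft <- plantedCohort(n = 600, nInf = 3, nNoise = 5, d = 3, seed = seed)
    inf <- informativeFeatures(ft)
    sapply(filterScores(ft), function(fsv)
      all(rankFeatures(fsv)[seq_along(inf)] %in% inf))
  })
  expect_true(all(rowMeans(hits) >= 0.95))
})

test_that("information gain and chi-square both vanish on label-permuted data", {
  ft <- permuteLabels(plantedCohort(n = 1500, nInf = 2, nNoise = 2, d = 2,
                                    seed = 3), seed = 8)
  expect_true(all(rawScores(scoreInfoGain(ft)) < 0.02))
  # chi2 null mean is df ~ (bins-1); normalized scores stay unremarkable
  expect_true(all(rawScores(scoreChi2(ft)) <
                  qchisq(0.999, df = 9 * 1)))
})
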