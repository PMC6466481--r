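# small in-code fixtures shared across the suite

# a fully hand-specified 6-subject, 2-feature table (3 cases, 3 controls)
toyTable <- function() {
  featureTable(cbind(f1 = c(0.0, 0.1, 0.2, 1.0, 1.1, 1.2),
                     f2 = c(5, 3, 4, 4, 3, 5)),
               labels = c(1, 1, 1, 2, 2, 2))
}

# planted-signal cohort with clinical-scale features
plantedCohort <- function(n = 200, nInf = 2, nNoise = 3, d = 2, seed = 1)
  generateSyntheticCohort(syntheticSpec(nSamples = n, nInformative = nInf,
                                        nNoise = nNoise, effectSize = d,
                                        seed = seed))

# a cheap classifier configuration for simulation-scale tests
fastConfig <- function(seed = 1, folds = 3)
  classifierConfig(penaltyGrid = c(1, 16), bandwidthGrid = 2,
                   cvFolds = folds, seed = seed)

# label-permuted copy of a table (breaks every feature-label association)
permuteLabels <- function(ft, seed = 1) {
  lab <- classLabels(ft)
  perm <- withr::with_seed(seed, sample(lab))
  featureTable(featureValues(ft), perm, featureMeta = featureMeta(ft))
}

# binary entropy in bits
.entropy2 <- function(p) -(p * log2(p) + (1 - p) * log2(1 - p))

# brute-force Relief oracle: full sweep, nearest hit/miss by exhaustive
# pairwise Manhattan distance on min-max-scaled features
reliefOracle <- function(ft) {
  v <- apply(featureValues(ft), 2, minmaxNormalize)
  y <- classLabels(ft)
  n <- nrow(v)
  w <- numeric(ncol(v))
  for (i in seq_len(n)) {
    best <- c(hit = Inf, miss = Inf)
    hi <- mi <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sum(abs(v[i, ] - v[j, ]))
      if (y[j] == y[i] && d < best["hit"]) { best["hit"] <- d; hi <- j }
      if (y[j] != y[i] && d < best["miss"]) { best["miss"] <- d; mi <- j }
    }
    w <- w + abs(v[i, ] - v[mi, ]) - abs(v[i, ] - v[hi, ])
  }
  stats::setNames(w / n, colnames(v))
}
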