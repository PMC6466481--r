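#' Specification of a synthetic two-class cohort
#'
#' Parameters of the synthetic-cohort generator that emulates the structure
#' of the reference stroke cohort: a roughly balanced two-class sample with
#' a handful of informative clinical features and many pure-noise features,
#' on plausible clinical scales with mixed integer/real value kinds.
#'
#' Defaults mirror the reference cohort's shape: 792 subjects, 28 features
#' of which 9 carry class signal, a near-balanced class split (398 cases /
#' 394 controls gives 0.5025), and a standardized mean difference of 1 for
#' each informative feature.
#'
#' @param nSamples number of subjects.
#' @param nInformative number of features with a class-conditional mean
#'   shift.
#' @param nNoise number of features identically distributed in both
#'   classes. `nInformative + nNoise >= 2`.
#' @param effectSize standardized mean difference (Cohen's d) between the
#'   class-conditional means of each informative feature; >= 0.
#' @param classBalance proportion of class-1 (case) subjects, in (0, 1).
#' @param seed integer seed; generation is reproducible given the seed.
#' @return a list of class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(nSamples = 792L, nInformative = 9L, nNoise = 19L,
                          effectSize = 1, classBalance = 398 / 792,
                          seed = 1L) {
  nSamples <- as.integer(nSamples)
  nInformative <- as.integer(nInformative)
  nNoise <- as.integer(nNoise)
  if (nInformative + nNoise < 2L) stop("at least 2 features required")
  if (nInformative < 0L || nNoise < 0L) stop("feature counts must be >= 0")
  if (effectSize < 0) stop("effectSize must be >= 0")
  if (classBalance <= 0 || classBalance >= 1)
    stop("classBalance must lie in (0, 1)")
  structure(list(nSamples = nSamples, nInformative = nInformative,
                 nNoise = nNoise, effectSize = effectSize,
                 classBalance = classBalance, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic two-class cohort
#'
#' Informative features are drawn class-conditionally Gaussian with means
#' `effectSize` standard deviations apart (cases shifted upward); noise
#' features are drawn from the same Gaussian for both classes. Each feature
#' is then placed on a plausible clinical scale by an affine map with a
#' feature-specific base level and spread, and roughly half the features
#' are rounded to whole numbers to emulate integer-valued laboratory items.
#' The planted informative feature names are recorded in the table's
#' metadata and retrievable with [informativeFeatures()].
#'
#' @param spec a [syntheticSpec()] object.
#' @return a [FeatureTable-class]; features are named `INF1..` (informative)
#'   and `NSE1..` (noise).
#' @examples
#' ft <- generateSyntheticCohort(syntheticSpec(nSamples = 100,
#'   nInformative = 2, nNoise = 3, effectSize = 2, seed = 7))
#' informativeFeatures(ft)
#' @export
generateSyntheticCohort <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  n <- spec$nSamples
  p <- spec$nInformative + spec$nNoise
  n1 <- round(n * spec$classBalance)
  labels <- c(rep(1L, n1), rep(2L, n - n1))
  .withSeed(spec$seed, {
    # latent standard-normal draws; cases shifted by +effectSize on
    # informative features
    z <- matrix(stats::rnorm(n * p), n, p)
    if (spec$nInformative > 0L) {
      shift <- matrix(0, n, spec$nInformative)
      shift[labels == 1L, ] <- spec$effectSize
      z[, seq_len(spec$nInformative)] <-
        z[, seq_len(spec$nInformative), drop = FALSE] + shift
    }
    # clinical-scale affine maps: base level 20-200 units, spread 10-30%
    # of the base level
    base <- stats::runif(p, 20, 200)
    spread <- base * stats::runif(p, 0.10, 0.30)
    v <- sweep(sweep(z, 2, spread, "*"), 2, base, "+")
    kind <- rep_len(c("integer", "real"), p)
    v[, kind == "integer"] <- round(v[, kind == "integer", drop = FALSE])
  })
  nm <- c(if (spec$nInformative > 0L) paste0("INF", seq_len(spec$nInformative)),
          if (spec$nNoise > 0L) paste0("NSE", seq_len(spec$nNoise)))
  colnames(v) <- nm
  meta <- data.frame(name = nm, unit = "", value_kind = kind,
                     stringsAsFactors = FALSE)
  featureTable(v, labels, featureMeta = meta,
               informative = nm[seq_len(spec$nInformative)])
}
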