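#' Construct a FeatureTable
#'
#' Builds the central data object of the package from a subjects-by-features
#' numeric matrix and a binary class label per subject. The column order of
#' `values` becomes the canonical feature order of every downstream vector
#' and matrix. Labels follow the convention 1 = case (at risk), 2 = control;
#' internally, correlation-style computations encode them as 1/0.
#'
#' @param values numeric matrix or data.frame, subjects in rows, features in
#'   columns, with unique column names; no missing entries are allowed
#'   (incomplete records must be dropped beforehand).
#' @param labels vector of class labels, one per subject, values 1 and 2.
#' @param featureMeta optional data.frame with columns `name`, `unit`,
#'   `value_kind` (`"integer"` or `"real"`), one row per feature in
#'   canonical order. Inferred when omitted: a feature whose observed
#'   values are all whole numbers is flagged `"integer"`.
#' @param informative optional character vector naming ground-truth
#'   informative features (used by the synthetic generator).
#' @return a [FeatureTable-class] object.
#' @examples
#' ft <- featureTable(cbind(a = c(1, 2, 3, 4), b = c(0.5, 1, 0, 2)),
#'                    labels = c(1, 1, 2, 2))
#' nFeatures(ft)
#' @export
featureTable <- function(values, labels, featureMeta = NULL,
                         informative = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("feature values must be numeric")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("F", seq_len(ncol(values)))
  labels <- as.integer(labels)
  if (length(labels) != nrow(values))
    stop("one label per row of 'values' required")
  if (is.null(featureMeta)) {
    kind <- ifelse(apply(values, 2, function(x) all(x == round(x))),
                   "integer", "real")
    featureMeta <- data.frame(name = colnames(values), unit = "",
                              value_kind = kind,
                              stringsAsFactors = FALSE)
  }
  stopifnot(nrow(featureMeta) == ncol(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = t(values)),
    rowData = S4Vectors::DataFrame(featureMeta, row.names = colnames(values)),
    colData = S4Vectors::DataFrame(label = labels))
  md <- list()
  if (!is.null(informative)) md$informative <- informative
  S4Vectors::metadata(se) <- md
  methods::new("FeatureTable", se)
}

#' FeatureTable accessors
#'
#' `featureValues()` returns the subjects-by-features numeric matrix (the
#' transpose of the stored assay), `classLabels()` the per-subject labels
#' (1 = case, 2 = control), `featureMeta()` the per-feature metadata,
#' `nFeatures()`/`nSamples()` the dimensions, and `informativeFeatures()`
#' the planted ground-truth feature names of a synthetic cohort (or `NULL`).
#'
#' @param x a [FeatureTable-class]
#' @param ... unused
#' @name featureTable
#' @aliases featureValues classLabels featureMeta nFeatures nSamples
#'   informativeFeatures
NULL

#' @rdname featureTable
#' @export
setMethod("featureValues", "FeatureTable", function(x, ...)
  t(SummarizedExperiment::assay(x, "values")))

#' @rdname featureTable
#' @export
setMethod("classLabels", "FeatureTable", function(x, ...) x$label)

#' @rdname featureTable
#' @export
setMethod("featureMeta", "FeatureTable", function(x, ...)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname featureTable
#' @export
setMethod("nFeatures", "FeatureTable", function(x) nrow(x))

#' @rdname featureTable
#' @export
setMethod("nSamples", "FeatureTable", function(x) ncol(x))

#' @rdname featureTable
#' @export
setMethod("informativeFeatures", "FeatureTable", function(x)
  S4Vectors::metadata(x)$informative)

setMethod("show", "FeatureTable", function(object) {
  lab <- classLabels(object)
  cat(sprintf("FeatureTable: %d subjects x %d features (%d cases, %d controls)\n",
              nSamples(object), nFeatures(object),
              sum(lab == 1L), sum(lab == 2L)))
  cat("features:", paste(utils::head(rownames(object), 8), collapse = ", "),
      if (nFeatures(object) > 8) "...", "\n")
  inf <- informativeFeatures(object)
  if (!is.null(inf))
    cat("planted informative:", paste(inf, collapse = ", "), "\n")
})

# 1/0 encoding of the class labels (1 = case) used by correlation-style
# scorers.
.y01 <- function(labels) as.numeric(labels == 1L)

#' Read a FeatureTable from CSV
#'
#' Reads a comma-separated file (header mandatory, `.` decimal point) with
#' one row per subject, named feature columns and one binary label column.
#' Any missing or non-numeric cell is rejected with the offending row and
#' column, mirroring the complete-records rule: incomplete records are
#' excluded from modelling rather than imputed.
#'
#' @param path path to a CSV file.
#' @param labelColumn name of the label column (values 1 and 2).
#' @return a [FeatureTable-class] with features in file column order.
#' @seealso [writeFeatureTable()]
#' @export
readFeatureTable <- function(path, labelColumn = "label") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!labelColumn %in% names(df))
    stop("label column '", labelColumn, "' not found")
  feats <- setdiff(names(df), labelColumn)
  for (f in c(feats, labelColumn)) {
    col <- df[[f]]
    if (is.character(col)) {
      col[col == ""] <- NA
      suppressWarnings(num <- as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad))
        stop(sprintf("non-numeric value in column '%s', row %d", f, bad[1]))
      col <- num
    }
    if (anyNA(col))
      stop(sprintf("missing value in column '%s', row %d (complete records required)",
                   f, which(is.na(col))[1]))
    df[[f]] <- col
  }
  featureTable(as.matrix(df[feats]), df[[labelColumn]])
}

#' Write a FeatureTable to CSV
#'
#' Inverse of [readFeatureTable()]: one row per subject, the feature
#' columns in canonical order and a final label column. Values are written
#' with enough digits that a read-back reproduces them exactly.
#'
#' @param x a [FeatureTable-class]
#' @param path output file path
#' @param labelColumn name for the label column
#' @export
writeFeatureTable <- function(x, path, labelColumn = "label") {
  v <- featureValues(x)
  out <- as.data.frame(apply(v, 2, function(col) sprintf("%.17g", col)),
                       check.names = FALSE)
  out[[labelColumn]] <- classLabels(x)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Min-max normalisation to the unit interval
#'
#' Maps `x` affinely so that its minimum becomes 0 and its maximum 1,
#' preserving order. A constant vector maps to all zeros by convention
#' (this demotes uninformative features and avoids division by zero).
#'
#' @param x numeric vector, length >= 1, no missing values.
#' @return numeric vector in \[0, 1\].
#' @examples
#' minmaxNormalize(c(1, 2, 3))
#' @export
minmaxNormalize <- function(x) {
  if (length(x) < 1L) stop("empty vector")
  if (anyNA(x)) stop("missing values not allowed")
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stratified k-fold assignment
#'
#' Assigns each subject to one of `k` cross-validation folds so that fold
#' sizes differ by at most one and each fold's class composition differs
#' from proportional by at most one subject per class. Deterministic for a
#' given seed.
#'
#' @param labels class labels (any two values).
#' @param k number of folds, >= 2; must not exceed the smallest class size.
#' @param seed integer seed governing the shuffle.
#' @return integer vector of fold ids in 1..k, one per subject.
#' @export
stratifiedKFold <- function(labels, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  tab <- table(labels)
  if (min(tab) < k)
    stop("k exceeds the size of the smallest class (", min(tab), ")")
  fold <- integer(length(labels))
  offset <- 0L
  .withSeed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      # rotate the fold sequence across classes so per-fold totals stay
      # within one of each other even when several classes have remainders
      ids <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      fold[idx] <- ids
      offset <- (offset + length(idx)) %% k
    }
  })
  fold
}
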