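#' @rdname featureTable
#' @export
setGeneric("featureValues", function(x, ...) standardGeneric("featureValues"))

#' @rdname featureTable
#' @export
setGeneric("classLabels", function(x, ...) standardGeneric("classLabels"))

#' @rdname featureTable
#' @export
setGeneric("featureMeta", function(x, ...) standardGeneric("featureMeta"))

#' @rdname featureTable
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname featureTable
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname featureTable
#' @export
setGeneric("informativeFeatures",
           function(x) standardGeneric("informativeFeatures"))

#' @rdname filterScores
#' @export
setGeneric("rawScores", function(x) standardGeneric("rawScores"))

#' @rdname filterScores
#' @export
setGeneric("normalizedScores", function(x) standardGeneric("normalizedScores"))

#' @rdname rankFeatures
#' @export
setGeneric("featureRanking", function(x) standardGeneric("featureRanking"))

#' @rdname prefixAccuracyCurve
#' @export
setGeneric("prefixAccuracy", function(x) standardGeneric("prefixAccuracy"))

#' @rdname prefixAccuracyCurve
#' @export
setGeneric("tunedParams", function(x) standardGeneric("tunedParams"))

#' @rdname contributionsFromCurve
#' @export
setGeneric("rawContribution", function(x) standardGeneric("rawContribution"))

#' @rdname contributionsFromCurve
#' @export
setGeneric("normalizedContribution",
           function(x) standardGeneric("normalizedContribution"))

#' @rdname featureWeights
#' @export
setGeneric("featureWeightsOf", function(x) standardGeneric("featureWeightsOf"))

#' @rdname featureWeights
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
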