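#' Accessors for selection and model results
#'
#' `importanceTable()` returns the per-feature score table of a
#' [FeatureSelectionResult][FeatureSelectionResult-class];
#' `retainedFeatures()` the ids with positive null-centered importance;
#' `stageCounts()` the feature counts logged at each pipeline stage;
#' `selectedFeatures()` the features with nonzero smooths in a
#' [GamLassoFit][GamLassoFit-class].
#'
#' @param object a `FeatureSelectionResult` or `GamLassoFit`.
#' @return See the per-function description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("importanceTable", function(object) standardGeneric("importanceTable"))

#' @rdname accessors
#' @export
setGeneric("retainedFeatures", function(object) standardGeneric("retainedFeatures"))

#' @rdname accessors
#' @export
setGeneric("stageCounts", function(object) standardGeneric("stageCounts"))

#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))

#' @rdname accessors
#' @export
setMethod("importanceTable", "FeatureSelectionResult",
          function(object) object@table)

#' @rdname accessors
#' @export
setMethod("retainedFeatures", "FeatureSelectionResult",
          function(object) object@table$feature[object@table$retained])

#' @rdname accessors
#' @export
setMethod("stageCounts", "FeatureSelectionResult",
          function(object) object@stageCounts)

#' @rdname accessors
#' @export
setMethod("selectedFeatures", "GamLassoFit", function(object) object@selected)

#' @rdname accessors
#' @export
setMethod("stageCounts", "GamLassoFit",
          function(object) c(candidates = length(object@features),
                             selected = length(object@selected)))
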