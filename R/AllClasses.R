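#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData
NULL

#' Multi-tube flow-cytometry panel definition
#'
#' A panel is an ordered set of test tubes, each staining for up to ten
#' surface markers. The combination feature space of a tube is the full set
#' of +/- sign assignments over its markers (2^k signatures per tube, an
#' exhaustive partition of the cells in that tube). Exclusion rules declare
#' signed marker sets that are biologically impossible (the canonical
#' example being simultaneous CD3+ and CD19+); any combination whose
#' signature contains all signed markers of a rule is dropped from the
#' feature space.
#'
#' @slot tubes named list; one character vector of marker names per tube.
#' @slot exclusionRules list of named character vectors of `"+"`/`"-"`
#'   signs, e.g. `c(CD3 = "+", CD19 = "+")`.
#'
#' @aliases PanelDefinition-class
#' @export
setClass("PanelDefinition",
  representation(tubes = "list", exclusionRules = "list"))

setValidity("PanelDefinition", function(object) {
  msg <- character()
  if (length(object@tubes) == 0L) msg <- c(msg, "panel has no tubes")
  if (is.null(names(object@tubes)) || anyDuplicated(names(object@tubes)))
    msg <- c(msg, "tubes must have unique names")
  for (tb in names(object@tubes)) {
    mk <- object@tubes[[tb]]
    if (!is.character(mk) || length(mk) < 1L || length(mk) > 10L)
      msg <- c(msg, sprintf("tube '%s' must list 1-10 marker names", tb))
    else if (anyDuplicated(mk))
      msg <- c(msg, sprintf("tube '%s' has duplicated marker names", tb))
  }
  allMarkers <- unique(unlist(object@tubes, use.names = FALSE))
  for (i in seq_along(object@exclusionRules)) {
    r <- object@exclusionRules[[i]]
    if (!is.character(r) || is.null(names(r)) || !all(r %in% c("+", "-")))
      msg <- c(msg, sprintf("exclusion rule %d must be a named vector of '+'/'-'", i))
    else if (!any(names(r) %in% allMarkers))
      msg <- c(msg, sprintf("exclusion rule %d references no panel marker", i))
  }
  if (length(msg)) msg else TRUE
})

#' Immunome abundance matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose rows are marker
#' combinations (features) and whose columns are samples. The single assay
#' `"abundance"` holds percent abundances in `[0, 100]`; a feature counts
#' as *detected* in a sample when its abundance is strictly positive.
#' `rowData` carries the tube and signature of every feature; `colData`
#' carries at least `patient_id` and `timepoint` (`"pre"` or `"post"`).
#'
#' @aliases ImmunomeExperiment-class
#' @export
setClass("ImmunomeExperiment", contains = "SummarizedExperiment")

setValidity("ImmunomeExperiment", function(object) {
  msg <- character()
  if (!"abundance" %in% names(assays(object)))
    return("assay 'abundance' is required")
  a <- assay(object, "abundance")
  if (any(!is.finite(a)) || any(a < 0))
    msg <- c(msg, "abundances must be finite and nonnegative")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids (rownames) must be unique")
  if (!all(c("tube", "signature") %in% colnames(rowData(object))))
    msg <- c(msg, "rowData must contain 'tube' and 'signature'")
  if (!all(c("patient_id", "timepoint") %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain 'patient_id' and 'timepoint'")
  if (length(msg)) msg else TRUE
})

#' Result of I-index subsampling feature selection
#'
#' @slot table `DataFrame` with one row per scored feature: `feature`,
#'   `importance` (null-centered divergence score), `observed` (raw
#'   divergence), `null` (permutation-null median, the centering value),
#'   `nullMean` (permutation-null mean), `timesSampled`, `retained`
#'   (`importance > 0`).
#' @slot stageCounts named integer vector of feature counts at each
#'   pipeline stage (enumerated, detected, after exclusion, retained).
#' @slot config list echo of the [selectionConfig()] used.
#'
#' @aliases FeatureSelectionResult-class
#' @export
setClass("FeatureSelectionResult",
  representation(table = "DataFrame", stageCounts = "integer",
                 config = "list"))

setValidity("FeatureSelectionResult", function(object) {
  tb <- object@table
  need <- c("feature", "importance", "timesSampled", "retained")
  if (!all(need %in% colnames(tb)))
    return(sprintf("table must contain columns %s",
                   paste(need, collapse = ", ")))
  if (any(tb$retained & !(tb$importance > 0)))
    return("retained features must have importance > 0")
  TRUE
})

#' Fitted group-lasso penalized additive logistic model
#'
#' One cubic spline smooth per selected feature; a group penalty over each
#' feature's basis coefficients zeroes entire smooths, so the nonzero
#' groups are the selected immunophenotypes. At most
#' `maxPrevalentInModel` prevalent features enter the additive part.
#'
#' @slot features character ids of candidate features offered to the fit.
#' @slot prevalent logical flag per candidate feature.
#' @slot selected character ids of features with nonzero smooths.
#' @slot bases list of basis descriptors (knots, boundary knots, centers,
#'   transform) keyed by feature id, used to rebuild the design at
#'   prediction time.
#' @slot coefficients list of numeric coefficient vectors keyed by feature.
#' @slot intercept numeric scalar.
#' @slot lambda numeric penalty at which the model was taken.
#' @slot baseRate training prevalence of the positive class.
#' @slot apparentAuc,cvAuc training-set and cross-validated AUC.
#' @slot config list echo of the [modelConfig()] used.
#'
#' @aliases GamLassoFit-class
#' @export
setClass("GamLassoFit",
  representation(features = "character", prevalent = "logical",
                 selected = "character", bases = "list",
                 coefficients = "list", intercept = "numeric",
                 lambda = "numeric", baseRate = "numeric",
                 apparentAuc = "numeric", cvAuc = "numeric",
                 config = "list"))

setValidity("GamLassoFit", function(object) {
  msg <- character()
  if (length(object@features) != length(object@prevalent))
    msg <- c(msg, "features and prevalent flags differ in length")
  if (!all(object@selected %in% object@features))
    msg <- c(msg, "selected features must be among the candidates")
  cap <- object@config$maxPrevalentInModel
  if (!is.null(cap)) {
    nPrev <- sum(object@selected %in% object@features[object@prevalent])
    if (nPrev > cap)
      msg <- c(msg, sprintf("%d prevalent features selected, cap is %d",
                            nPrev, cap))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PanelDefinition", function(object) {
  k <- lengths(object@tubes)
  cat(sprintf("PanelDefinition: %d tubes, %s markers/tube, %d exclusion rule(s)\n",
              length(object@tubes),
              if (length(unique(k)) == 1L) k[1] else paste(range(k), collapse = "-"),
              length(object@exclusionRules)))
  cat(sprintf("  combination universe: %d signatures\n", sum(2^k)))
})

setMethod("show", "ImmunomeExperiment", function(object) {
  cat(sprintf("ImmunomeExperiment: %d marker-combination features x %d samples\n",
              nrow(object), ncol(object)))
  tp <- table(colData(object)$timepoint)
  cat("  timepoints:", paste(sprintf("%s=%d", names(tp), tp), collapse = ", "), "\n")
  callNextMethod()
})

setMethod("show", "FeatureSelectionResult", function(object) {
  cat(sprintf("FeatureSelectionResult: %d features scored, %d retained (importance > 0)\n",
              nrow(object@table), sum(object@table$retained)))
  cat(sprintf("  subsets: B = %d draws of m = %d features\n",
              object@config$nSubsamples, object@config$subsetSize))
  if (length(object@stageCounts))
    cat("  stages:", paste(sprintf("%s=%d", names(object@stageCounts),
                                   object@stageCounts), collapse = " -> "), "\n")
})

setMethod("show", "GamLassoFit", function(object) {
  nPrev <- sum(object@selected %in% object@features[object@prevalent])
  cat(sprintf("GamLassoFit: %d features selected (%d prevalent, %d non-prevalent) of %d candidates\n",
              length(object@selected), nPrev, length(object@selected) - nPrev,
              length(object@features)))
  cat(sprintf("  lambda = %.4g; apparent AUC = %.3f; cross-validated AUC = %.3f\n",
              object@lambda, object@apparentAuc, object@cvAuc))
})
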