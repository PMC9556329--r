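#' Feature-space construction and filtering
#'
#' The marker-combination feature space is built from abundance data in
#' four steps: enumeration of observed phenotypes, removal of biologically
#' impossible combinations, a detection filter, and a prevalence split.
#' All filters use inclusive (`>=`) boundaries.
#'
#' @name immunomeFeatures
NULL

#' Observed marker-combination phenotypes
#'
#' @param x an [ImmunomeExperiment][ImmunomeExperiment-class].
#' @return Character ids of the features detected (abundance > 0) in at
#'   least one sample — the observed subset of the per-tube `2^k`
#'   combination universe.
#' @export
observedPhenotypes <- function(x) {
  stopifnot(is(x, "ImmunomeExperiment"))
  if (ncol(x) == 0L) stop("abundance matrix has no samples")
  a <- assay(x, "abundance")
  rownames(x)[rowSums(a > 0) >= 1L]
}

#' Remove biologically impossible combinations
#'
#' Drops every feature whose signature contains all signed markers of any
#' of the panel's exclusion rules (e.g. simultaneous CD3+ and CD19+).
#' Rules referencing a marker absent from a feature's tube are skipped for
#' that tube with a message. The result does not depend on rule order.
#'
#' @param features character feature ids.
#' @param panel a [PanelDefinition][PanelDefinition-class].
#' @return The surviving feature ids.
#' @export
applyExclusionRules <- function(features, panel) {
  if (!length(features)) return(features)
  parsed <- parseFeatureId(features, panel)
  features[!.matchesExclusion(parsed, panel)]
}

#' Detection filter
#'
#' Retains features detected (abundance > 0) in at least `minFraction` of
#' the samples; the sample set is unchanged. With the default 0.5 this is
#' the rule that drops combinations detected in fewer than half of
#' patients.
#'
#' @param x an [ImmunomeExperiment][ImmunomeExperiment-class].
#' @param minFraction detection threshold in `[0, 1]` (inclusive `>=`).
#' @return The filtered `ImmunomeExperiment`.
#' @export
filterByDetection <- function(x, minFraction = 0.5) {
  stopifnot(is(x, "ImmunomeExperiment"))
  .checkProportion(minFraction, "minFraction")
  a <- assay(x, "abundance")
  keep <- rowSums(a > 0) / ncol(a) >= minFraction
  x[keep, ]
}

#' Prevalence split
#'
#' Partitions features into *prevalent* (detected in at least `threshold`
#' of the samples — by default the 85% rule applied to training samples)
#' and *non-prevalent* (all others).
#'
#' @param x an [ImmunomeExperiment][ImmunomeExperiment-class], typically
#'   restricted to the training samples.
#' @param threshold prevalence threshold in `[0, 1]` (inclusive `>=`).
#' @return A list with `prevalent`, `nonPrevalent` (character ids) and
#'   `threshold`.
#' @export
splitByPrevalence <- function(x, threshold = 0.85) {
  stopifnot(is(x, "ImmunomeExperiment"))
  .checkProportion(threshold, "threshold")
  a <- assay(x, "abundance")
  prev <- rowSums(a > 0) / ncol(a) >= threshold
  list(prevalent = rownames(x)[prev],
       nonPrevalent = rownames(x)[!prev],
       threshold = threshold)
}

#' Build the analysis feature space
#'
#' Convenience wrapper chaining [observedPhenotypes()],
#' [applyExclusionRules()] and [filterByDetection()], returning the
#' filtered experiment together with the stage-by-stage feature counts.
#'
#' @param x an [ImmunomeExperiment][ImmunomeExperiment-class].
#' @param panel a [PanelDefinition][PanelDefinition-class].
#' @param minFraction detection threshold.
#' @return A list with `experiment` (the filtered `ImmunomeExperiment`)
#'   and `stageCounts` (named integer vector: observed, after exclusion,
#'   after detection filter).
#' @export
buildFeatureSpace <- function(x, panel, minFraction = 0.5) {
  obs <- observedPhenotypes(x)
  kept <- applyExclusionRules(obs, panel)
  filtered <- filterByDetection(x[kept, ], minFraction)
  list(experiment = filtered,
       stageCounts = c(observed = length(obs),
                       after_exclusion = length(kept),
                       after_detection = nrow(filtered)))
}
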