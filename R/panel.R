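#' Construct a panel definition
#'
#' @param tubes named list of character marker vectors (1-10 markers per
#'   tube, unique within a tube).
#' @param exclusionRules list of named `"+"`/`"-"` vectors declaring
#'   biologically impossible signed marker sets. The default single rule
#'   forbids cells that are simultaneously CD3+ (T lineage) and CD19+
#'   (B lineage).
#' @return A [PanelDefinition][PanelDefinition-class].
#' @export
#' @examples
#' panelDefinition(list(T01 = c("CD3", "CD4", "CD8")),
#'                 exclusionRules = list())
panelDefinition <- function(tubes,
                            exclusionRules = list(c(CD3 = "+", CD19 = "+"))) {
  new("PanelDefinition", tubes = tubes, exclusionRules = exclusionRules)
}

#' Default 14-tube, 10-marker panel
#'
#' A panel with the shape of a ten-color, 60-marker immunophenotyping
#' assay: 14 tubes of 10 markers drawn from a pool of 60 surface markers,
#' with lineage anchors (CD45, CD3) shared across tubes. Marker names are
#' illustrative; the combination universe is 14 x 2^10 = 14,336
#' signatures before exclusion and detection filtering.
#'
#' @return A [PanelDefinition][PanelDefinition-class].
#' @export
defaultPanel <- function() {
  pool <- c("CD2", "CD4", "CD5", "CD7", "CD8", "CD10", "CD11b", "CD11c",
            "CD14", "CD15", "CD16", "CD19", "CD20", "CD22", "CD23", "CD25",
            "CD27", "CD28", "CD31", "CD33", "CD34", "CD38", "CD39", "CD40",
            "CD56", "CD57", "CD62L", "CD64", "CD69", "CD71", "CD79b",
            "CD94", "CD117", "CD123", "CD127", "CD138", "CD158a", "CD161",
            "CD163", "CD183", "CD185", "CD194", "CD196", "CD197", "CD244",
            "CD272", "CD279", "CD314", "CD335", "CD337", "HLADR", "ILT2",
            "KIR2DL1", "KIR2DL2", "NKG2A", "TCRgd", "IgD", "IgM")
  extras <- setdiff(pool, c("CD19"))
  tubes <- lapply(seq_len(14), function(i) {
    idx <- (((i - 1L) * 8L) + 0:7) %% length(extras) + 1L
    c("CD45", if (i <= 7) "CD3" else "CD19", extras[idx])
  })
  names(tubes) <- sprintf("T%02d", seq_len(14))
  rules <- list(c(CD3 = "+", CD19 = "+"),
                c(CD3 = "+", CD14 = "+"),
                c(CD19 = "+", CD14 = "+"))
  panelDefinition(tubes, rules)
}

#' Compact panel for examples and simulation studies
#'
#' A deterministic smaller panel (default 5 tubes of 8 markers) drawn
#' from the same marker pool as [defaultPanel()], with the standard
#' lineage exclusion rule. Tube 1 carries both CD3 and CD19 so the rule
#' is exercised.
#'
#' @param nTubes number of tubes.
#' @param markersPerTube markers per tube (2-10).
#' @return A [PanelDefinition][PanelDefinition-class].
#' @export
examplePanel <- function(nTubes = 5, markersPerTube = 8) {
  stopifnot(markersPerTube >= 2, markersPerTube <= 10)
  big <- defaultPanel()
  pool <- setdiff(unique(unlist(big@tubes)), c("CD3", "CD19", "CD14"))
  tubes <- lapply(seq_len(nTubes), function(i) {
    anchors <- if (i == 1) c("CD3", "CD19") else
      if (i %% 2 == 0) "CD3" else "CD19"
    extra <- pool[(((i - 1L) * 6L) %% (length(pool) - markersPerTube)) +
                    seq_len(markersPerTube - length(anchors))]
    c(anchors, extra)
  })
  names(tubes) <- sprintf("T%02d", seq_len(nTubes))
  panelDefinition(tubes, big@exclusionRules[1])
}

#' Compose and parse marker-combination feature ids
#'
#' Feature ids serialize a combination as `"TUBE:Marker1+Marker2-..."`,
#' covering every marker of the tube in panel order.
#'
#' @param tube tube id(s).
#' @param signs for `featureId()`, a character vector (or list of vectors)
#'   of `"+"`/`"-"` in the tube's marker order.
#' @param panel a [PanelDefinition][PanelDefinition-class] supplying
#'   marker order.
#' @param ids character vector of feature ids to parse.
#' @return `featureId()` returns character ids. `parseFeatureId()` returns
#'   a list with `tube` and a named sign vector per id; unknown tubes or
#'   malformed signatures raise an error naming the offending id.
#' @export
featureId <- function(tube, signs, panel) {
  if (!is.list(signs)) signs <- list(signs)
  unname(mapply(function(tb, sg) {
    mk <- panel@tubes[[tb]]
    if (is.null(mk)) stop(sprintf("unknown tube '%s'", tb), call. = FALSE)
    if (length(sg) != length(mk))
      stop(sprintf("signature for tube '%s' must assign all %d markers",
                   tb, length(mk)), call. = FALSE)
    paste0(tb, ":", paste0(mk, sg, collapse = ""))
  }, rep(tube, length.out = length(signs)), signs))
}

#' @rdname featureId
#' @export
parseFeatureId <- function(ids, panel) {
  lapply(ids, function(id) {
    parts <- strsplit(id, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("malformed feature id '%s'", id), call. = FALSE)
    tb <- parts[1]
    mk <- panel@tubes[[tb]]
    if (is.null(mk))
      stop(sprintf("feature id '%s' references unknown tube '%s'", id, tb),
           call. = FALSE)
    sig <- parts[2]
    signs <- character(length(mk))
    pos <- 1L
    for (j in seq_along(mk)) {
      token <- paste0(mk[j])
      if (substr(sig, pos, pos + nchar(token) - 1L) != token)
        stop(sprintf("feature id '%s' does not follow tube '%s' marker order",
                     id, tb), call. = FALSE)
      pos <- pos + nchar(token)
      signs[j] <- substr(sig, pos, pos)
      if (!signs[j] %in% c("+", "-"))
        stop(sprintf("feature id '%s': marker '%s' lacks a +/- sign",
                     id, mk[j]), call. = FALSE)
      pos <- pos + 1L
    }
    if (pos != nchar(sig) + 1L)
      stop(sprintf("feature id '%s' has trailing characters", id),
           call. = FALSE)
    names(signs) <- mk
    list(tube = tb, signs = signs)
  })
}

# TRUE for each parsed signature that matches any exclusion rule of the
# panel; rules referencing markers absent from the tube are skipped for
# that tube (reported via message once per tube/rule pair).
.matchesExclusion <- function(parsed, panel, quiet = FALSE) {
  noted <- character(0)
  vapply(parsed, function(p) {
    for (ri in seq_along(panel@exclusionRules)) {
      r <- panel@exclusionRules[[ri]]
      if (!all(names(r) %in% names(p$signs))) {
        key <- paste(p$tube, ri)
        if (!quiet && !key %in% noted) {
          noted <<- c(noted, key)
          message(sprintf("exclusion rule {%s} ignored for tube %s (marker absent)",
                          paste0(names(r), r, collapse = ","), p$tube))
        }
        next
      }
      if (all(p$signs[names(r)] == r)) return(TRUE)
    }
    FALSE
  }, logical(1))
}

#' Read or write a panel definition file
#'
#' Panels are stored as YAML with two top-level keys: `tubes` (a mapping
#' from tube id to marker list) and `exclusion_rules` (a list of mappings
#' from marker name to `"+"`/`"-"`).
#'
#' @param path file path.
#' @param panel a [PanelDefinition][PanelDefinition-class].
#' @return `readPanel()` returns a `PanelDefinition`; `writePanel()`
#'   returns `path` invisibly.
#' @export
readPanel <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$tubes)) stop("panel file lacks a 'tubes' section")
  tubes <- lapply(y$tubes, function(mk) as.character(unlist(mk)))
  rules <- lapply(y$exclusion_rules %||% list(), function(r) {
    out <- as.character(unlist(r))
    names(out) <- names(unlist(r))
    out
  })
  panelDefinition(tubes, rules)
}

#' @rdname readPanel
#' @export
writePanel <- function(panel, path) {
  y <- list(tubes = panel@tubes,
            exclusion_rules = lapply(panel@exclusionRules, as.list))
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
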