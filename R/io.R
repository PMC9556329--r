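#' Delimited-text input and output
#'
#' All tables are UTF-8, comma-delimited with a single header line;
#' missing values are encoded as empty fields. Numeric values are written
#' with 17 significant digits so that write-then-read is an exact
#' round trip.
#'
#' @name cytometryIO
NULL

.writeCsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  for (j in which(num)) {
    v <- df[[j]]
    df[[j]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an abundance matrix to CSV
#'
#' Samples are rows; the first three columns are `sample_id`,
#' `patient_id`, `timepoint`, followed by one column per
#' marker-combination feature (header = feature id, see [featureId()]).
#'
#' @param x an [ImmunomeExperiment][ImmunomeExperiment-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAbundance <- function(x, path) {
  stopifnot(is(x, "ImmunomeExperiment"))
  a <- t(assay(x, "abundance"))
  df <- data.frame(sample_id = colnames(x),
                   patient_id = colData(x)$patient_id,
                   timepoint = colData(x)$timepoint,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(a, check.names = FALSE))
  .writeCsv(df, path)
}

#' Read an abundance matrix from CSV
#'
#' Malformed rows are rejected with their line number (line 1 is the
#' header). When a panel is supplied, feature ids are parsed and
#' validated against it and any column matching an exclusion rule is
#' flagged with a warning at read time.
#'
#' @param path CSV file written by [writeAbundance()] (or following its
#'   layout).
#' @param panel optional [PanelDefinition][PanelDefinition-class].
#' @return An [ImmunomeExperiment][ImmunomeExperiment-class].
#' @export
readAbundance <- function(path, panel = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("sample_id", "patient_id", "timepoint")
  if (!all(need %in% names(df)))
    stop("abundance file must start with columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  featCols <- setdiff(names(df), need)
  vals <- df[featCols]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (is.character(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "")
      if (length(bad))
        stop(sprintf("non-numeric abundance in column '%s' at line %d",
                     featCols[j], bad[1] + 1L))
      v <- vn
    }
    bad <- which(!is.na(v) & v < 0)
    if (length(bad))
      stop(sprintf("negative abundance in column '%s' at line %d",
                   featCols[j], bad[1] + 1L))
    if (anyNA(v))
      stop(sprintf("missing abundance in column '%s' at line %d",
                   featCols[j], which(is.na(v))[1] + 1L))
    vals[[j]] <- v
  }
  mat <- t(as.matrix(vals))
  dimnames(mat) <- list(featCols, df$sample_id)
  if (!is.null(panel)) {
    parsed <- parseFeatureId(featCols, panel)
    flagged <- .matchesExclusion(parsed, panel, quiet = TRUE)
    if (any(flagged))
      warning("column(s) match an exclusion rule: ",
              paste(featCols[flagged], collapse = ", "))
    tube <- vapply(parsed, `[[`, "", "tube")
    signature <- vapply(parsed, function(p)
      paste0(names(p$signs), p$signs, collapse = ""), "")
  } else {
    tube <- sub(":.*$", "", featCols)
    signature <- sub("^[^:]*:", "", featCols)
  }
  se <- SummarizedExperiment(
    assays = list(abundance = mat),
    rowData = DataFrame(tube = tube, signature = signature,
                        row.names = featCols),
    colData = DataFrame(patient_id = df$patient_id,
                        timepoint = df$timepoint,
                        row.names = df$sample_id))
  new("ImmunomeExperiment", se)
}

#' Read or write a clinical cohort table
#'
#' @param cohort data.frame as returned by [generateCohort()].
#' @param path CSV path.
#' @return `readCohort()` returns the validated cohort data.frame.
#' @export
writeCohort <- function(cohort, path) .writeCsv(cohort, path)

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("patient_id", "surgery", "resection", "viable_percent")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort file lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id)) stop("duplicate patient id(s)")
  bad <- which(is.na(df$viable_percent) != (df$resection == "none"))
  if (length(bad))
    stop(sprintf("viable_percent must be missing exactly when resection is 'none' (line %d)",
                 bad[1] + 1L))
  for (cc in intersect(c("dfs_event", "os_event"), names(df)))
    if (!all(df[[cc]] %in% c(0, 1)))
      stop(sprintf("column '%s' must be 0/1", cc))
  for (cc in intersect(c("dfs_time", "os_time"), names(df)))
    if (any(df[[cc]] <= 0, na.rm = TRUE))
      stop(sprintf("column '%s' must be positive", cc))
  df
}

#' Read or write per-patient variant summaries
#'
#' Columns: `patient_id`, `protein_affecting`, `non_protein_affecting`,
#' `covered_bases` (coding bases at >= 7x unique coverage).
#'
#' @param variants data.frame as from [generateMutationData()].
#' @param path CSV path.
#' @return `readVariants()` returns the validated data.frame.
#' @export
writeVariants <- function(variants, path) .writeCsv(variants, path)

#' @rdname writeVariants
#' @export
readVariants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("patient_id", "protein_affecting", "covered_bases")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant file lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$covered_bases <= 0)) stop("covered_bases must be positive")
  if (any(df$protein_affecting < 0)) stop("mutation counts must be nonnegative")
  df
}

#' Serialize a fitted model to versioned structured text
#'
#' @param model a [GamLassoFit][GamLassoFit-class].
#' @param path JSON path.
#' @return `readModel()` returns the reconstructed `GamLassoFit`.
#' @export
writeModel <- function(model, path) {
  ser <- list(
    format = "immunoMPR-gamlasso", version = 1L,
    features = model@features, prevalent = model@prevalent,
    selected = model@selected,
    bases = lapply(model@bases, function(s) {
      if (s$type == "linear") s
      else list(type = s$type, knots = s$knots, boundary = s$boundary,
                center = s$center,
                transform = apply(s$transform, 1L, identity, simplify = FALSE))
    }),
    coefficients = model@coefficients, intercept = model@intercept,
    lambda = model@lambda, baseRate = model@baseRate,
    apparentAuc = model@apparentAuc, cvAuc = model@cvAuc,
    config = model@config)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  if (!identical(ser$format, "immunoMPR-gamlasso"))
    stop("not an immunoMPR model file")
  bases <- lapply(ser$bases, function(s) {
    if (s$type == "linear")
      list(type = "linear", center = s$center, scale = s$scale)
    else list(type = s$type, knots = as.numeric(s$knots),
              boundary = as.numeric(s$boundary),
              center = as.numeric(s$center),
              transform = do.call(rbind, lapply(s$transform, as.numeric)))
  })
  cfg <- ser$config
  new("GamLassoFit",
      features = as.character(ser$features),
      prevalent = as.logical(ser$prevalent),
      selected = as.character(ser$selected),
      bases = bases,
      coefficients = lapply(ser$coefficients, as.numeric),
      intercept = as.numeric(ser$intercept),
      lambda = as.numeric(ser$lambda), baseRate = as.numeric(ser$baseRate),
      apparentAuc = as.numeric(ser$apparentAuc),
      cvAuc = as.numeric(ser$cvAuc), config = cfg)
}
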