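# Shared fixtures: a minimal one-tube panel and a constructor for small
# in-memory abundance experiments with explicit values.

tinyPanel <- function(markers = c("A", "B", "C"),
                      rules = list(c(A = "+", B = "+"))) {
  panelDefinition(list(T01 = markers), rules)
}

# rows = feature ids, cols = samples; values are percent abundances
toyExperiment <- function(mat, timepoint = "pre",
                          patient = colnames(mat)) {
  if (is.null(rownames(mat))) stop("feature ids required")
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  if (is.null(patient)) patient <- colnames(mat)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = mat),
    rowData = S4Vectors::DataFrame(
      tube = sub(":.*$", "", rownames(mat)),
      signature = sub("^[^:]*:", "", rownames(mat)),
      row.names = rownames(mat)),
    colData = S4Vectors::DataFrame(patient_id = patient,
                                   timepoint = timepoint,
                                   row.names = colnames(mat)))
  new("ImmunomeExperiment", se)
}

# all signatures of a 3-marker tube, in +/- enumeration order
tinyFeatureIds <- function(panel = tinyPanel()) {
  signs <- expand.grid(rep(list(c("+", "-")), 3), stringsAsFactors = FALSE)
  featureId("T01", lapply(seq_len(8), function(i) unlist(signs[i, ])), panel)
}

# independent recursive permutation enumerator (oracle for exact
# permutation p-values; deliberately distinct from the package internals)
oraclePermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (perm in oraclePermutations(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(perm, n, after = pos - 1L)
  out
}
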