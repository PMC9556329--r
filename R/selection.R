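#' Configuration of the I-index subsampling selection
#'
#' @param subsetSize number of features drawn per subsample (m).
#' @param nSubsamples number of random subsamples (B). The reference
#'   procedure uses 1e6 draws; because importance is a mean over draws, B
#'   only controls Monte-Carlo variance and smaller values are appropriate
#'   for testing.
#' @param regressionViableMax viable-percent ceiling defining the
#'   pathological-regression extreme arm.
#' @param progressionViableMin viable-percent floor defining the
#'   pathological-progression extreme arm. The two literal thresholds
#'   overlap; [selectExtremeCohorts()] resolves dual-eligible samples by
#'   distance to the nearer extreme.
#' @param perArmK samples per extreme arm.
#' @param bins histogram bin count of the divergence estimator.
#' @param smooth additive (add-one style) histogram smoothing count.
#' @param seed integer seed.
#' @return A validated list of class `SelectionConfig`.
#' @export
selectionConfig <- function(subsetSize = 30, nSubsamples = 10000,
                            regressionViableMax = 88,
                            progressionViableMin = 20,
                            perArmK = 13, bins = 8, smooth = 1, seed = 1) {
  cfg <- list(subsetSize = as.integer(subsetSize),
              nSubsamples = as.integer(nSubsamples),
              regressionViableMax = regressionViableMax,
              progressionViableMin = progressionViableMin,
              perArmK = as.integer(perArmK), bins = as.integer(bins),
              smooth = smooth, seed = as.integer(seed))
  stopifnot(cfg$subsetSize >= 2L, cfg$nSubsamples >= 1L, cfg$perArmK >= 2L,
            cfg$bins >= 2L, cfg$smooth >= 0)
  class(cfg) <- "SelectionConfig"
  cfg
}

#' Select extreme responder and non-responder cohorts
#'
#' Chooses `perArmK` samples from patients with pathological regression
#' (viable percent at or below `regressionViableMax`) and `perArmK` from
#' patients with pathological progression (viable percent at or above
#' `progressionViableMin`). Arms are disjoint: a sample eligible for both
#' arms is considered only for the arm to whose extreme (0% or 100%
#' viable) it lies closer (ties go to the regression arm). Within an arm
#' the most extreme samples win; ties are broken by viable percent and
#' then patient id, so selection is fully deterministic.
#'
#' @param cohort data.frame with `patient_id` and `viable_percent`.
#' @param x an [ImmunomeExperiment][ImmunomeExperiment-class] whose
#'   samples restrict eligibility (only patients with an immunome are
#'   candidates); pass `NULL` to use the cohort alone.
#' @param config a [selectionConfig()].
#' @return A list with character vectors `regression` and `progression`
#'   of patient ids.
#' @export
selectExtremeCohorts <- function(cohort, x = NULL, config = selectionConfig()) {
  cand <- cohort[!is.na(cohort$viable_percent), , drop = FALSE]
  if (!is.null(x))
    cand <- cand[cand$patient_id %in% colData(x)$patient_id, , drop = FALSE]
  v <- cand$viable_percent
  eligReg <- v <= config$regressionViableMax
  eligProg <- v >= config$progressionViableMin
  dual <- eligReg & eligProg
  # dual-eligible samples go to the arm where they are more extreme
  toReg <- dual & (v <= 100 - v)
  eligReg[dual] <- toReg[dual]
  eligProg[dual] <- !toReg[dual]
  pick <- function(elig, decreasing, arm) {
    if (sum(elig) < config$perArmK)
      stop(sprintf("only %d candidates for the %s arm; %d required",
                   sum(elig), arm, config$perArmK))
    ids <- cand$patient_id[elig]
    vv <- v[elig]
    ord <- order(vv, ids, decreasing = c(decreasing, FALSE),
                 method = "radix")
    ids[ord][seq_len(config$perArmK)]
  }
  list(regression = pick(eligReg, FALSE, "regression"),
       progression = pick(eligProg, TRUE, "progression"))
}

#' Normalize an immunome matrix
#'
#' `rank` maps every feature to mid-ranks scaled to `(0, 1]` (invariant to
#' any strictly monotone transform of the feature); `arcsinh` applies
#' `asinh(x / cofactor)`; `none` is the identity.
#'
#' @param x an [ImmunomeExperiment][ImmunomeExperiment-class].
#' @param method one of `"rank"`, `"arcsinh"`, `"none"`.
#' @param cofactor arcsinh cofactor.
#' @return An `ImmunomeExperiment` of the same shape.
#' @export
normalizeImmunome <- function(x, method = c("rank", "arcsinh", "none"),
                              cofactor = 5) {
  stopifnot(is(x, "ImmunomeExperiment"))
  method <- match.arg(method)
  a <- assay(x, "abundance")
  a <- switch(method,
    none = a,
    arcsinh = asinh(a / cofactor),
    rank = t(apply(a, 1L, function(v) rank(v, ties.method = "average") /
                     length(v))))
  out <- x
  SummarizedExperiment::assay(out, "abundance") <- a
  out
}

#' Information-divergence score between two samples
#'
#' Estimates the Jensen-Shannon divergence between the distributions of
#' two samples, using histograms on shared equal-width bins spanning the
#' pooled range, with additive smoothing. The value lies in
#' `[0, log 2]` (natural log), is symmetric in its arguments, and is 0
#' for identical samples. This is the divergence kernel behind the
#' feature-importance score (the "I-index"): any other divergence with
#' the same signature can be substituted via the `kernel` argument of
#' [subsampleRank()].
#'
#' @param a,b numeric samples (nonempty).
#' @param bins number of shared histogram bins (>= 2).
#' @param smooth additive smoothing count per bin; `0` gives the plug-in
#'   estimate (exactly `log 2` for disjoint point masses).
#' @return Nonnegative numeric divergence estimate.
#' @export
#' @examples
#' iIndex(rnorm(100), rnorm(100, 2), bins = 8)
iIndex <- function(a, b, bins = 8, smooth = 1) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  if (bins < 2) stop("bins must be >= 2")
  rng <- range(a, b)
  if (rng[1] == rng[2]) return(0)
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  ia <- pmin(pmax(findInterval(a, br, rightmost.closed = TRUE), 1L), bins)
  ib <- pmin(pmax(findInterval(b, br, rightmost.closed = TRUE), 1L), bins)
  .jsFromCounts(tabulate(ia, bins), tabulate(ib, bins), smooth)
}

# Jensen-Shannon divergence from two count vectors (or matrices with one
# column per feature), with additive smoothing; natural log.
.jsFromCounts <- function(ca, cb, smooth) {
  ca <- ca + smooth; cb <- cb + smooth
  if (is.matrix(ca)) {
    p <- sweep(ca, 2L, colSums(ca), "/")
    q <- sweep(cb, 2L, colSums(cb), "/")
    m <- (p + q) / 2
    xlx <- function(x, y) ifelse(x > 0, x * log(x / y), 0)
    0.5 * colSums(xlx(p, m)) + 0.5 * colSums(xlx(q, m))
  } else {
    p <- ca / sum(ca); q <- cb / sum(cb)
    m <- (p + q) / 2
    kl <- function(x, y) sum(ifelse(x > 0, x * log(x / y), 0))
    0.5 * kl(p, m) + 0.5 * kl(q, m)
  }
}

#' Rank features by null-centered divergence under random subsampling
#'
#' Draws `B` random subsets of `m` features; within every subset each
#' feature's separation between the two classes is scored with the
#' divergence kernel, once with the true labels and once with a label
#' permutation drawn for that iteration. A feature's importance is its
#' observed score minus the median of its permutation-null scores over
#' the iterations that contained it; features with importance strictly
#' greater than 0 are retained. Raw divergences are nonnegative, so the
#' positivity retention rule is only selective after this null
#' centering. The median (not the mean) is the centering statistic
#' because divergence estimates are right-skewed: an observation exceeds
#' the null median with probability one half regardless of skew, so
#' under pure noise about half the features are retained, which is what
#' makes the positivity rule well calibrated. The null mean is also
#' reported.
#'
#' @param x an [ImmunomeExperiment][ImmunomeExperiment-class] restricted
#'   to the extreme-cohort samples (typically normalized first).
#' @param labels two-level factor/character vector aligned with the
#'   columns of `x` (e.g. regression vs progression arm).
#' @param config a [selectionConfig()].
#' @param stageCounts optional named integer vector of upstream feature
#'   counts to carry into the result.
#' @param kernel divergence kernel; a function `(countsA, countsB,
#'   smooth) -> divergence` on per-bin count matrices. Defaults to the
#'   Jensen-Shannon kernel of [iIndex()].
#' @return A [FeatureSelectionResult][FeatureSelectionResult-class].
#' @export
subsampleRank <- function(x, labels, config = selectionConfig(),
                          stageCounts = integer(), kernel = .jsFromCounts) {
  stopifnot(is(x, "ImmunomeExperiment"))
  labels <- as.factor(labels)
  if (length(labels) != ncol(x))
    stop("labels must match the samples of the matrix")
  if (nlevels(droplevels(labels)) != 2L)
    stop("labels must have exactly two classes")
  nf <- nrow(x)
  if (config$subsetSize > nf)
    stop(sprintf("subset size %d exceeds the %d eligible features",
                 config$subsetSize, nf))
  a <- assay(x, "abundance")
  bins <- config$bins
  isA <- labels == levels(droplevels(labels))[1L]
  n <- ncol(a)

  # shared-bin histogram index per feature (rows), precomputed once
  binIdx <- t(vapply(seq_len(nf), function(i) {
    v <- a[i, ]
    rng <- range(v)
    if (rng[1] == rng[2]) return(rep(1L, n))
    br <- seq(rng[1], rng[2], length.out = bins + 1L)
    pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L), bins)
  }, integer(n)))
  degenerate <- apply(binIdx, 1L, function(z) all(z == z[1L]))

  countsFor <- function(rows, members) {
    # bins x length(rows) count matrix over the given samples
    sub <- binIdx[rows, members, drop = FALSE]
    t(vapply(seq_len(bins), function(b) rowSums(sub == b),
             numeric(length(rows))))
  }
  scoreFor <- function(rows, lab) {
    s <- kernel(countsFor(rows, lab), countsFor(rows, !lab), config$smooth)
    s[degenerate[rows]] <- 0
    s
  }

  observed <- scoreFor(seq_len(nf), isA)

  set.seed(deriveSeed(config$seed, "subsample"))
  B <- config$nSubsamples
  m <- config$subsetSize
  drawFeature <- integer(B * m)
  drawScore <- numeric(B * m)
  timesSampled <- integer(nf)
  for (b in seq_len(B)) {
    rows <- sample.int(nf, m)
    perm <- sample.int(n)
    at <- (b - 1L) * m + seq_len(m)
    drawFeature[at] <- rows
    drawScore[at] <- scoreFor(rows, isA[perm])
    timesSampled[rows] <- timesSampled[rows] + 1L
  }
  nullMedian <- rep(NA_real_, nf)
  nullMean <- rep(NA_real_, nf)
  byFeature <- split(drawScore, drawFeature)
  idx <- as.integer(names(byFeature))
  nullMedian[idx] <- vapply(byFeature, stats::median, 0)
  nullMean[idx] <- vapply(byFeature, mean, 0)
  importance <- observed - nullMedian
  importance[timesSampled == 0L] <- NA_real_
  retained <- !is.na(importance) & importance > 0

  tb <- DataFrame(feature = rownames(x), importance = importance,
                  observed = observed, null = nullMedian,
                  nullMean = nullMean,
                  timesSampled = timesSampled, retained = retained)
  tb <- tb[order(-tb$importance, tb$feature), ]
  counts <- c(stageCounts, scored = nf, retained = sum(retained))
  new("FeatureSelectionResult", table = tb,
      stageCounts = as.integer(counts) |> stats::setNames(names(counts)),
      config = unclass(config))
}

#' Write a feature-selection result to delimited text
#'
#' Emits the per-feature table as CSV preceded by commented run-metadata
#' lines (`# key: value`) recording the seed, subset size, number of
#' subsamples and extreme-cohort thresholds.
#'
#' @param result a [FeatureSelectionResult][FeatureSelectionResult-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSelectionResult <- function(result, path) {
  cfg <- result@config
  meta <- sprintf("# %s: %s",
                  c("seed", "subsetSize", "nSubsamples",
                    "regressionViableMax", "progressionViableMin",
                    "perArmK", "bins", "smooth"),
                  c(cfg$seed, cfg$subsetSize, cfg$nSubsamples,
                    cfg$regressionViableMax, cfg$progressionViableMin,
                    cfg$perArmK, cfg$bins, cfg$smooth))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(as.data.frame(result@table), con, row.names = FALSE)
  invisible(path)
}
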