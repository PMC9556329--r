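#' Configuration of the penalized additive model
#'
#' @param nonPrevalentCap,prevalentCap number of candidate features kept
#'   per stratum by [filterCandidates()] (defaults 17 and 10).
#' @param maxPrevalentInModel cap on prevalent features in the additive
#'   part of the final model (default 1, enforced by exhaustive search
#'   over prevalent singletons).
#' @param basisDf degrees of freedom of the natural cubic spline basis
#'   per smooth.
#' @param penaltyGrid optional explicit grid of positive penalties
#'   (sorted internally, strongest first); when `NULL` the grid is
#'   data-derived.
#' @param nPenalty,penaltyMinRatio geometric penalty grid used when
#'   `penaltyGrid` is `NULL`: `nPenalty` values from the data-derived
#'   `lambda_max` down to `penaltyMinRatio * lambda_max`. The floor is
#'   strictly positive, so a separable fit is never unpenalized.
#' @param cvFolds stratified cross-validation folds used to choose the
#'   penalty by out-of-fold AUC.
#' @param prevalentTest `"auto"` (Welch t unless a per-class Shapiro
#'   screen at alpha 0.05 fails, then Wilcoxon rank-sum), `"t"`, or
#'   `"wilcoxon"`.
#' @param seed integer seed (fold assignment).
#' @return A validated list of class `ModelConfig`.
#' @export
modelConfig <- function(nonPrevalentCap = 17, prevalentCap = 10,
                        maxPrevalentInModel = 1, basisDf = 4,
                        penaltyGrid = NULL,
                        nPenalty = 20, penaltyMinRatio = 0.05,
                        cvFolds = 5, prevalentTest = c("auto", "t", "wilcoxon"),
                        seed = 1) {
  cfg <- list(nonPrevalentCap = as.integer(nonPrevalentCap),
              prevalentCap = as.integer(prevalentCap),
              maxPrevalentInModel = as.integer(maxPrevalentInModel),
              basisDf = as.integer(basisDf),
              penaltyGrid = penaltyGrid,
              nPenalty = as.integer(nPenalty),
              penaltyMinRatio = penaltyMinRatio,
              cvFolds = as.integer(cvFolds),
              prevalentTest = match.arg(prevalentTest),
              seed = as.integer(seed))
  stopifnot(cfg$nonPrevalentCap >= 0L, cfg$prevalentCap >= 0L,
            cfg$maxPrevalentInModel >= 0L, cfg$basisDf >= 1L,
            cfg$cvFolds >= 2L, cfg$nPenalty >= 2L,
            cfg$penaltyMinRatio > 0, cfg$penaltyMinRatio < 1)
  if (!is.null(penaltyGrid)) {
    stopifnot(is.numeric(penaltyGrid), all(penaltyGrid > 0))
    cfg$penaltyGrid <- sort(penaltyGrid, decreasing = TRUE)
  }
  class(cfg) <- "ModelConfig"
  cfg
}

#' Filter candidate features by univariate association with outcome
#'
#' Non-prevalent features are ranked by the chi-squared statistic
#' (without continuity correction) on the 2x2 detected/undetected by
#' outcome table; prevalent features by a Welch t test on abundance (or a
#' Wilcoxon rank-sum test when a per-class normality screen fails, per
#' `config$prevalentTest`). The top `nonPrevalentCap` and `prevalentCap`
#' features per stratum, by p-value, become the model candidates.
#' Degenerate detection tables (a feature detected in all or in no
#' samples) are assigned p = 1 and reported.
#'
#' @param split result of [splitByPrevalence()].
#' @param x an [ImmunomeExperiment][ImmunomeExperiment-class] restricted
#'   to the training samples.
#' @param labels logical (or two-level) outcome per sample, `TRUE` = MPR.
#' @param config a [modelConfig()].
#' @return data.frame with `feature`, `stratum` (`prevalent`/
#'   `nonPrevalent`), `p`, `test` and `candidate` (logical: within cap).
#' @export
filterCandidates <- function(split, x, labels, config = modelConfig()) {
  stopifnot(is(x, "ImmunomeExperiment"))
  y <- .asBinary(labels, ncol(x))
  a <- assay(x, "abundance")
  scoreNonPrev <- function(f) {
    det <- a[f, ] > 0
    if (all(det) || !any(det)) {
      message(sprintf("feature %s: degenerate detection table; p set to 1", f))
      return(c(p = 1, stat = 0))
    }
    tab <- table(factor(det, c(FALSE, TRUE)), factor(y, c(FALSE, TRUE)))
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    c(p = unname(ht$p.value), stat = unname(ht$statistic))
  }
  scorePrev <- function(f) {
    v1 <- a[f, y]; v0 <- a[f, !y]
    if (stats::sd(v1) == 0 && stats::sd(v0) == 0 &&
        mean(v1) == mean(v0))
      return(c(p = 1, stat = 0, wilcox = 0))
    useWilcox <- switch(config$prevalentTest,
      t = FALSE, wilcoxon = TRUE,
      auto = {
        shapiroP <- function(v) {
          v <- v[is.finite(v)]
          if (length(unique(v)) < 3L || length(v) < 3L) return(0)
          stats::shapiro.test(v)$p.value
        }
        shapiroP(v1) < 0.05 || shapiroP(v0) < 0.05
      })
    if (useWilcox) {
      ht <- suppressWarnings(stats::wilcox.test(v1, v0, exact = FALSE))
      c(p = unname(ht$p.value), stat = unname(ht$statistic), wilcox = 1)
    } else {
      ht <- stats::t.test(v1, v0)
      c(p = unname(ht$p.value), stat = unname(ht$statistic), wilcox = 0)
    }
  }
  rows <- list()
  np <- intersect(split$nonPrevalent, rownames(x))
  if (length(np)) {
    s <- vapply(np, scoreNonPrev, c(p = 0, stat = 0))
    rows$np <- data.frame(feature = np, stratum = "nonPrevalent",
                          p = s["p", ], statistic = s["stat", ],
                          test = "chi-squared", stringsAsFactors = FALSE)
  }
  pv <- intersect(split$prevalent, rownames(x))
  if (length(pv)) {
    s <- vapply(pv, scorePrev, c(p = 0, stat = 0, wilcox = 0))
    rows$pv <- data.frame(feature = pv, stratum = "prevalent",
                          p = s["p", ], statistic = s["stat", ],
                          test = ifelse(s["wilcox", ] == 1, "wilcoxon", "welch-t"),
                          stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$p, out$feature), ]
  out$candidate <- FALSE
  for (st in c("nonPrevalent", "prevalent")) {
    cap <- if (st == "prevalent") config$prevalentCap else config$nonPrevalentCap
    idx <- which(out$stratum == st)
    out$candidate[utils::head(idx, cap)] <- TRUE
  }
  out
}

.asBinary <- function(labels, n) {
  if (is.logical(labels)) y <- labels
  else {
    f <- as.factor(labels)
    if (nlevels(droplevels(f)) != 2L) stop("labels must have two classes")
    y <- f == levels(droplevels(f))[2L]
  }
  if (length(y) != n) stop("labels must match the samples")
  if (all(y) || !any(y)) stop("both classes must be present")
  y
}

# --- spline basis machinery -------------------------------------------------

# Basis descriptor for one feature: natural cubic spline on training
# quantile knots, columns centered and orthonormalized (Z'Z/n = I) so the
# group penalty treats every smooth on the same scale. Features with too
# few distinct values degrade to a centered/scaled linear column.
.makeBasisSpec <- function(v, df) {
  ux <- sort(unique(v))
  if (length(ux) < max(3L, df)) {
    s <- stats::sd(v)
    return(list(type = "linear", center = mean(v),
                scale = if (s > 0) s else 1))
  }
  boundary <- range(v)
  knots <- stats::quantile(v, probs = seq_len(df - 1L) / df, names = FALSE,
                           type = 8)
  knots <- knots[knots > boundary[1] & knots < boundary[2]]
  knots <- unique(knots)
  B <- splines::ns(v, knots = knots, Boundary.knots = boundary)
  center <- colMeans(B)
  Bc <- sweep(B, 2L, center)
  sv <- svd(Bc)
  keep <- sv$d > max(sv$d) * 1e-8
  n <- length(v)
  transform <- sv$v[, keep, drop = FALSE] %*%
    diag(sqrt(n) / sv$d[keep], nrow = sum(keep))
  list(type = "ns", knots = knots, boundary = boundary,
       center = center, transform = transform)
}

.evalBasis <- function(spec, v) {
  if (spec$type == "linear")
    return(matrix((v - spec$center) / spec$scale, ncol = 1L))
  B <- splines::ns(v, knots = spec$knots, Boundary.knots = spec$boundary)
  sweep(B, 2L, spec$center) %*% spec$transform
}

# --- group-lasso logistic solver --------------------------------------------

# FISTA proximal gradient for
#   min -loglik(beta)/n + lambda * sum_g sqrt(p_g) ||beta_g||_2
# over a path of decreasing lambda with warm starts. X excludes the
# intercept, which is unpenalized and carried separately.
.groupLassoPath <- function(X, y, groups, lambdas, maxit = 200, tol = 1e-6) {
  n <- nrow(X); p <- ncol(X)
  groupId <- integer(p)
  for (gi in seq_along(groups)) groupId[groups[[gi]]] <- gi
  gw <- sqrt(vapply(groups, length, 1L))
  L <- (svd(X, nu = 0, nv = 0)$d[1]^2 / n + 1) / 4  # +1 for the intercept col
  beta <- numeric(p); b0 <- stats::qlogis(mean(y))
  path <- vector("list", length(lambdas))
  for (li in seq_along(lambdas)) {
    lam <- lambdas[li]
    zb <- beta; zb0 <- b0; tk <- 1
    for (it in seq_len(maxit)) {
      mu <- stats::plogis(drop(X %*% zb) + zb0)
      newB <- zb - drop(crossprod(X, mu - y)) / (n * L)
      new0 <- zb0 - mean(mu - y) / L
      # groupwise soft threshold (the proximal step of the group penalty)
      nrm <- sqrt(drop(rowsum(newB^2, groupId)))
      shrink <- pmax(0, 1 - (lam * gw / L) / pmax(nrm, 1e-300))
      newB <- newB * shrink[groupId]
      tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
      accel <- (tk - 1) / tk1
      zb <- newB + accel * (newB - beta)
      zb0 <- new0 + accel * (new0 - b0)
      delta <- max(abs(c(newB - beta, new0 - b0)))
      beta <- newB; b0 <- new0; tk <- tk1
      if (delta < tol * max(1, max(abs(beta)))) break
    }
    path[[li]] <- list(beta = beta, b0 = b0, lambda = lam)
  }
  path
}

.lambdaGrid <- function(X, y, groups, config) {
  if (!is.null(config$penaltyGrid)) return(config$penaltyGrid)
  n <- nrow(X)
  r <- y - mean(y)
  gmax <- max(vapply(seq_along(groups), function(gi) {
    idx <- groups[[gi]]
    sqrt(sum(drop(crossprod(X[, idx, drop = FALSE], r))^2)) /
      (n * sqrt(length(idx)))
  }, 0))
  gmax <- max(gmax, 1e-6)
  exp(seq(log(gmax), log(gmax * config$penaltyMinRatio),
          length.out = config$nPenalty))
}

.strata_folds <- function(y, k, seed) {
  set.seed(deriveSeed(seed, "cvfolds"))
  fold <- integer(length(y))
  for (cl in c(TRUE, FALSE)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit the group-lasso penalized additive logistic model
#'
#' Each candidate feature enters through a natural cubic spline smooth;
#' a group-lasso penalty over each smooth's coefficients zeroes entire
#' smooths, so penalty selection is feature selection. The penalty is
#' chosen on a geometric grid by stratified cross-validated AUC (ties
#' resolved toward the stronger penalty). The cap on prevalent features
#' in the additive part is enforced exactly: the model is refit over the
#' empty prevalent set and every prevalent singleton (more generally,
#' subsets up to `maxPrevalentInModel`), and the best cross-validated
#' candidate wins.
#'
#' @param candidates data.frame from [filterCandidates()] (rows with
#'   `candidate = TRUE` are used), or a character vector of feature ids
#'   (then `prevalent` must flag the prevalent ones).
#' @param x training [ImmunomeExperiment][ImmunomeExperiment-class].
#' @param labels outcome per training sample (`TRUE` = MPR).
#' @param config a [modelConfig()].
#' @param prevalent logical vector when `candidates` is a character
#'   vector.
#' @return A [GamLassoFit][GamLassoFit-class].
#' @export
fitGamLasso <- function(candidates, x, labels, config = modelConfig(),
                        prevalent = NULL) {
  stopifnot(is(x, "ImmunomeExperiment"))
  y <- .asBinary(labels, ncol(x))
  if (is.data.frame(candidates)) {
    keep <- candidates$candidate %||% rep(TRUE, nrow(candidates))
    feats <- candidates$feature[keep]
    isPrev <- candidates$stratum[keep] == "prevalent"
  } else {
    feats <- as.character(candidates)
    isPrev <- if (is.null(prevalent)) rep(FALSE, length(feats))
              else rep_len(prevalent, length(feats))
  }
  if (!length(feats)) stop("no candidate features to fit")
  missing <- setdiff(feats, rownames(x))
  if (length(missing))
    stop("candidate features absent from the matrix: ",
         paste(missing, collapse = ", "))
  a <- assay(x, "abundance")

  specs <- lapply(feats, function(f) .makeBasisSpec(a[f, ], config$basisDf))
  names(specs) <- feats
  blocks <- lapply(feats, function(f) .evalBasis(specs[[f]], a[f, ]))
  names(blocks) <- feats

  assemble <- function(useFeats) {
    X <- do.call(cbind, blocks[useFeats])
    sizes <- vapply(blocks[useFeats], ncol, 1L)
    ends <- cumsum(sizes)
    groups <- mapply(function(s, e) seq.int(e - s + 1L, e), sizes, ends,
                     SIMPLIFY = FALSE)
    names(groups) <- useFeats
    list(X = X, groups = groups)
  }

  fold <- .strata_folds(y, config$cvFolds, config$seed)
  evalSet <- function(useFeats) {
    d <- assemble(useFeats)
    lambdas <- .lambdaGrid(d$X, y, d$groups, config)
    oof <- matrix(NA_real_, nrow = length(y), ncol = length(lambdas))
    for (k in seq_len(config$cvFolds)) {
      tr <- fold != k
      if (length(unique(y[tr])) < 2L) next
      pathK <- .groupLassoPath(d$X[tr, , drop = FALSE], y[tr], d$groups,
                               lambdas)
      for (li in seq_along(lambdas)) {
        eta <- drop(d$X[!tr, , drop = FALSE] %*% pathK[[li]]$beta) +
          pathK[[li]]$b0
        oof[!tr, li] <- stats::plogis(eta)
      }
    }
    cvAuc <- vapply(seq_along(lambdas), function(li) {
      ok <- !is.na(oof[, li])
      if (!any(ok) || length(unique(y[ok])) < 2L) return(NA_real_)
      rocAuc(oof[ok, li], y[ok])$auc
    }, 0)
    best <- which(cvAuc >= max(cvAuc, na.rm = TRUE) - 1e-12)[1L]  # ties -> larger lambda
    list(features = useFeats, lambdas = lambdas, cvAuc = cvAuc,
         bestIdx = best, bestCv = cvAuc[best], d = d)
  }

  nonPrev <- feats[!isPrev]
  prevFeats <- feats[isPrev]
  prevSets <- list(character(0))
  if (config$maxPrevalentInModel > 0L && length(prevFeats)) {
    for (size in seq_len(min(config$maxPrevalentInModel, length(prevFeats))))
      prevSets <- c(prevSets,
                    utils::combn(prevFeats, size, simplify = FALSE))
  }
  candSets <- lapply(prevSets, function(ps) c(nonPrev, ps))
  candSets <- candSets[vapply(candSets, length, 1L) > 0L]
  if (!length(candSets)) stop("no candidate features to fit")

  evals <- lapply(candSets, evalSet)
  bestSet <- which.max(vapply(evals, `[[`, 0, "bestCv"))
  ev <- evals[[bestSet]]

  finalPath <- .groupLassoPath(ev$d$X, y, ev$d$groups,
                               ev$lambdas[seq_len(ev$bestIdx)],
                               maxit = 1000, tol = 1e-8)
  fit <- finalPath[[length(finalPath)]]
  coefs <- lapply(ev$d$groups, function(idx) fit$beta[idx])
  selected <- names(coefs)[vapply(coefs, function(b) sqrt(sum(b^2)), 0) > 1e-8]
  etaTrain <- drop(ev$d$X %*% fit$beta) + fit$b0
  apparent <- if (length(unique(y)) == 2L)
    rocAuc(stats::plogis(etaTrain), y)$auc else NA_real_

  new("GamLassoFit",
      features = ev$features,
      prevalent = ev$features %in% prevFeats,
      selected = selected,
      bases = specs[ev$features],
      coefficients = coefs,
      intercept = fit$b0,
      lambda = ev$lambdas[ev$bestIdx],
      baseRate = mean(y),
      apparentAuc = apparent,
      cvAuc = ev$bestCv,
      config = unclass(config))
}

#' Predict MPR probability
#'
#' @param model a [GamLassoFit][GamLassoFit-class].
#' @param x an [ImmunomeExperiment][ImmunomeExperiment-class] containing
#'   every feature selected by the model; a missing selected feature is
#'   an error naming the absent ids (never silent imputation).
#' @return Named numeric vector of probabilities in `[0, 1]`.
#' @export
predictProbability <- function(model, x) {
  stopifnot(is(model, "GamLassoFit"), is(x, "ImmunomeExperiment"))
  missing <- setdiff(model@selected, rownames(x))
  if (length(missing))
    stop("matrix lacks selected feature(s): ", paste(missing, collapse = ", "))
  a <- assay(x, "abundance")
  eta <- rep(model@intercept, ncol(x))
  for (f in model@selected) {
    Z <- .evalBasis(model@bases[[f]], a[f, ])
    eta <- eta + drop(Z %*% model@coefficients[[f]])
  }
  stats::setNames(stats::plogis(eta), colnames(x))
}

#' ROC curve and AUC
#'
#' The curve is traced over the distinct score thresholds (descending);
#' the AUC equals the Mann-Whitney U statistic divided by `n1 * n0`, with
#' ties counted one half — identical to the trapezoidal integral of the
#' returned curve.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels outcome per score (`TRUE` = positive class).
#' @return A list of class `RocResult`: `curve` (data.frame `fpr`, `tpr`
#'   from (0,0) to (1,1)) and `auc`.
#' @export
rocAuc <- function(scores, labels) {
  y <- .asBinary(labels, length(scores))
  n1 <- sum(y); n0 <- sum(!y)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  cutIdx <- which(!duplicated(ss, fromLast = TRUE))  # last index of each tie block
  tpr <- c(0, cumsum(ys)[cutIdx] / n1, 1)
  fpr <- c(0, cumsum(!ys)[cutIdx] / n0, 1)
  structure(list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f over %d thresholds\n", x$auc,
              nrow(x$curve) - 2L))
  invisible(x)
}

#' Compare predicted probabilities across outcome groups
#'
#' One-way ANOVA over the groups plus all pairwise Welch t tests with
#' Satterthwaite degrees of freedom and 95% mean-difference confidence
#' intervals. No multiplicity adjustment is applied (flagged in the
#' output). Groups with fewer than two members are excluded with a
#' warning.
#'
#' @param probabilities numeric vector of predicted probabilities.
#' @param groups group label per value (e.g. MPR / non-MPR / PD).
#' @return A list with `anova` (data.frame: term, df, sumsq, meansq,
#'   statistic, p), `pairwise` (data.frame of Welch results) and
#'   `multiplicityAdjusted = FALSE`.
#' @export
compareProbabilityGroups <- function(probabilities, groups) {
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding group(s) with < 2 members: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    probabilities <- probabilities[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2L) stop("need at least two groups of size >= 2")
  g <- factor(groups)
  an <- stats::anova(stats::aov(probabilities ~ g))
  anovaTab <- data.frame(term = c("group", "residuals"),
                         df = an$Df, sumsq = an$`Sum Sq`,
                         meansq = an$`Mean Sq`,
                         statistic = an$`F value`, p = an$`Pr(>F)`)
  pairs <- utils::combn(levels(g), 2L, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    xa <- probabilities[g == pr[1]]; xb <- probabilities[g == pr[2]]
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0 && mean(xa) == mean(xb))
      return(data.frame(group1 = pr[1], group2 = pr[2], t = 0,
                        df = length(xa) + length(xb) - 2, p = 1,
                        estimate = 0, ciLow = 0, ciHigh = 0))
    ht <- stats::t.test(xa, xb)
    data.frame(group1 = pr[1], group2 = pr[2],
               t = unname(ht$statistic), df = unname(ht$parameter),
               p = ht$p.value, estimate = unname(diff(rev(ht$estimate))),
               ciLow = ht$conf.int[1], ciHigh = ht$conf.int[2])
  }))
  list(anova = anovaTab, pairwise = pw, multiplicityAdjusted = FALSE)
}

#' Paired pre/post expansion and contraction tests
#'
#' For every feature shared by the pre- and post-treatment matrices,
#' tests the paired within-patient change (Wilcoxon signed-rank by
#' default, or paired t), adjusts p-values across features by
#' Benjamini-Hochberg, and reports the direction of the median change as
#' expansion or contraction. Samples without a pre/post partner are
#' dropped with a warning.
#'
#' @param pre,post [ImmunomeExperiment][ImmunomeExperiment-class]
#'   objects; columns matched by `patient_id`.
#' @param patients optional patient ids to restrict to (e.g. the MPR
#'   subset).
#' @param method `"wilcoxon"` or `"t"`.
#' @return data.frame with `feature`, `statistic`, `p`, `q` (BH-adjusted),
#'   `medianChange`, `direction` (`expansion`/`contraction`/`none`).
#' @export
pairedPrePostTest <- function(pre, post, patients = NULL,
                              method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  idPre <- colData(pre)$patient_id
  idPost <- colData(post)$patient_id
  common <- intersect(idPre, idPost)
  if (!is.null(patients)) common <- intersect(common, patients)
  dropped <- setdiff(union(idPre, idPost) , common)
  if (length(dropped) && is.null(patients))
    warning(length(dropped), " unpaired sample(s) dropped")
  if (length(common) < 2L) stop("fewer than two paired samples")
  feats <- intersect(rownames(pre), rownames(post))
  aPre <- assay(pre, "abundance")[feats, match(common, idPre), drop = FALSE]
  aPost <- assay(post, "abundance")[feats, match(common, idPost), drop = FALSE]
  res <- lapply(feats, function(f) {
    d <- aPost[f, ] - aPre[f, ]
    if (all(d == 0))
      return(data.frame(feature = f, statistic = NA_real_, p = 1,
                        medianChange = 0))
    ht <- if (method == "wilcoxon")
      suppressWarnings(stats::wilcox.test(aPost[f, ], aPre[f, ],
                                          paired = TRUE, exact = FALSE))
    else stats::t.test(aPost[f, ], aPre[f, ], paired = TRUE)
    data.frame(feature = f, statistic = unname(ht$statistic),
               p = ht$p.value, medianChange = stats::median(d))
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$medianChange > 0, "expansion",
                          ifelse(out$medianChange < 0, "contraction", "none"))
  out[order(out$q, out$p, out$feature), ]
}
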