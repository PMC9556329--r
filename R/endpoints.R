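#' Classify pathological response
#'
#' MPR is at most `mprThreshold` percent viable malignant cells
#' (inclusive) in a completely resected (R0) primary tumor; pCR is 0%
#' viable. Incomplete (R1/R2) resection precludes MPR regardless of the
#' viable percentage; patients without surgery are not evaluable.
#' Pathological regression is `viable percent - 100` (in `[-100, 0]`).
#'
#' @param viablePercent percent viable tumor cells (`NA` when no
#'   resection).
#' @param resection `"R0"`, `"R1/R2"` or `"none"` per patient.
#' @param surgery logical per patient.
#' @param mprThreshold MPR ceiling, default 10 (inclusive).
#' @return data.frame with `category` (factor: `pCR`, `MPR(non-pCR)`,
#'   `non-MPR`, `not-evaluable`), `mpr` (logical, `NA` if not evaluable)
#'   and `pathologicalRegression`.
#' @export
#' @examples
#' classifyResponse(c(0, 10, 5, 40, NA), c("R0", "R0", "R1/R2", "R0", "none"),
#'                  c(TRUE, TRUE, TRUE, TRUE, FALSE))
classifyResponse <- function(viablePercent, resection, surgery,
                             mprThreshold = 10) {
  n <- max(length(viablePercent), length(resection), length(surgery))
  viablePercent <- rep_len(viablePercent, n)
  resection <- rep_len(resection, n)
  surgery <- rep_len(surgery, n)
  if (any(!is.na(viablePercent) & !surgery))
    stop("viable percent present for patient(s) without surgery")
  if (any(!is.na(viablePercent) &
          (viablePercent < 0 | viablePercent > 100)))
    stop("viable percent must lie in [0, 100]")
  if (any(is.na(viablePercent) != (resection == "none")))
    stop("viable percent must be missing exactly when resection is 'none'")
  category <- rep("not-evaluable", n)
  evaluable <- surgery & resection != "none"
  complete <- evaluable & resection == "R0"
  category[evaluable] <- "non-MPR"
  category[complete & viablePercent == 0] <- "pCR"
  category[complete & viablePercent > 0 &
             viablePercent <= mprThreshold] <- "MPR(non-pCR)"
  mpr <- ifelse(evaluable, category %in% c("pCR", "MPR(non-pCR)"), NA)
  data.frame(
    category = factor(category,
                      c("pCR", "MPR(non-pCR)", "non-MPR", "not-evaluable")),
    mpr = mpr,
    pathologicalRegression = viablePercent - 100)
}

#' Response rate with exact or score confidence interval
#'
#' @param successes,n counts.
#' @param method `"clopper_pearson"` (exact, default) or `"wilson"`
#'   (score).
#' @param level confidence level.
#' @return A list with `rate`, `lower`, `upper` (proportions), the
#'   `method`, and `percent` — the rate and bounds as whole percents
#'   rounded half away from zero, the convention used in trial reports.
#' @export
#' @examples
#' responseRateCI(29, 143)$percent  # 20 (14-28)
responseRateCI <- function(successes, n,
                           method = c("clopper_pearson", "wilson"),
                           level = 0.95) {
  method <- match.arg(method)
  stopifnot(n > 0, successes >= 0, successes <= n)
  p <- successes / n
  alpha <- 1 - level
  ci <- if (method == "clopper_pearson") {
    c(if (successes == 0) 0 else
        stats::qbeta(alpha / 2, successes, n - successes + 1),
      if (successes == n) 1 else
        stats::qbeta(1 - alpha / 2, successes + 1, n - successes))
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    denom <- 1 + z^2 / n
    mid <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    c(max(0, mid - half), min(1, mid + half))
  }
  list(rate = p, lower = ci[1], upper = ci[2], method = method,
       level = level,
       percent = c(rate = roundHalfUp(100 * p),
                   lower = roundHalfUp(100 * ci[1]),
                   upper = roundHalfUp(100 * ci[2])))
}

#' Exact contingency-table test (Fisher / Freeman-Halton)
#'
#' For 2x2 tables, the two-sided p-value is the sum of hypergeometric
#' probabilities of all tables (with the observed margins) whose
#' probability does not exceed the observed table's — the
#' point-probability rule — with a relative tolerance of 1e-12 guarding
#' floating-point ties. For r x c tables the Freeman-Halton
#' generalization enumerates every table with the observed margins.
#'
#' @param table integer matrix of nonnegative counts (at least 2x2; every
#'   margin used must be positive).
#' @return Two-sided p-value in `(0, 1]`.
#' @export
#' @examples
#' fisherExact(matrix(c(8, 52, 5, 10), 2, byrow = TRUE))
fisherExact <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  # all-zero rows/columns carry no information; drop them
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least two rows and two columns with positive margins")
  if (nrow(m) == 2L && ncol(m) == 2L) {
    rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
    k <- 0:min(rs[1], cs[1])
    probs <- stats::dhyper(k, cs[1], N - cs[1], rs[1])
    pObs <- stats::dhyper(m[1, 1], cs[1], N - cs[1], rs[1])
    return(min(1, sum(probs[probs <= pObs * (1 + 1e-12)])))
  }
  .freemanHalton(m)
}

# Freeman-Halton exact test by full enumeration of tables with fixed
# margins; probabilities via the log-multivariate hypergeometric mass.
.freemanHalton <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
  logConst <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N)
  logProb <- function(tab) logConst - sum(lfactorial(tab))
  pObs <- exp(logProb(m))
  total <- 0
  nr <- nrow(m); nc <- ncol(m)
  tab <- matrix(0L, nr, nc)
  recurse <- function(i, j, rowRem, colRem) {
    # fill cell (i, j); last column and last row are forced
    if (j == nc) {
      v <- rowRem[i]
      if (v < 0 || v > colRem[j]) return()
      tab[i, j] <<- v
      colRem2 <- colRem; colRem2[j] <- colRem2[j] - v
      if (i == nr - 1L) {
        last <- colRem2
        if (any(last < 0)) return()
        tab[nr, ] <<- last
        p <- exp(logProb(tab))
        if (p <= pObs * (1 + 1e-12)) total <<- total + p
      } else {
        recurse(i + 1L, 1L, rowRem, colRem2)
      }
      return()
    }
    for (v in 0:min(rowRem[i], colRem[j])) {
      tab[i, j] <<- v
      rowRem2 <- rowRem; rowRem2[i] <- rowRem2[i] - v
      colRem2 <- colRem; colRem2[j] <- colRem2[j] - v
      recurse(i, j + 1L, rowRem2, colRem2)
    }
  }
  if (nr == 1L || nc == 1L) return(1)
  recurse(1L, 1L, rs, cs)
  min(1, total)
}

#' Welch two-sample t test
#'
#' Unequal-variance t with Satterthwaite fractional degrees of freedom
#' and a 95% confidence interval for the mean difference.
#'
#' @param x,y numeric samples (each with at least two values and positive
#'   variance).
#' @return A list with `t`, `df`, `p`, `estimate` (mean(x) - mean(y)),
#'   `ciLow`, `ciHigh`.
#' @export
welchT <- function(x, y) {
  if (length(x) < 2L || stats::sd(x) == 0)
    stop("sample 'x' needs >= 2 values with positive variance")
  if (length(y) < 2L || stats::sd(y) == 0)
    stop("sample 'y' needs >= 2 values with positive variance")
  ht <- stats::t.test(x, y)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, estimate = unname(ht$estimate[1] - ht$estimate[2]),
       ciLow = ht$conf.int[1], ciHigh = ht$conf.int[2])
}

#' Two-sided p-value from a reported (t, df) pair
#'
#' @param t t statistic.
#' @param df (possibly fractional) degrees of freedom, > 0.
#' @return `2 * P(T_df > |t|)`.
#' @export
#' @examples
#' welchPFromStats(-5.47, 27.02)
welchPFromStats <- function(t, df) {
  if (!is.finite(t) || !is.finite(df) || df <= 0)
    stop("t and df must be finite with df > 0")
  2 * stats::pt(abs(t), df, lower.tail = FALSE)
}

#' Tumor mutational burden
#'
#' TMB is the count of protein-affecting mutations divided by the number
#' of megabases of coding sequence with at least 7x unique coverage.
#' Groups follow the bins `[0, 10)`, `[10, 16)`, `[16, Inf)` mutations
#' per megabase — labelled `<10`, `10-15`, `>=16` — so the partition is
#' exhaustive for non-integer values.
#'
#' @param proteinAffecting mutation count(s).
#' @param coveredBases coding bases at >= 7x unique coverage (> 0).
#' @return data.frame with `tmb` (mutations/Mb) and `tmbGroup`.
#' @export
#' @examples
#' computeTMB(5, 2.5e6)
computeTMB <- function(proteinAffecting, coveredBases) {
  if (any(coveredBases <= 0)) stop("covered bases must be positive")
  if (any(proteinAffecting < 0)) stop("mutation counts must be nonnegative")
  tmb <- proteinAffecting / (coveredBases / 1e6)
  grp <- cut(tmb, breaks = c(0, 10, 16, Inf), right = FALSE,
             labels = c("<10", "10-15", ">=16"), include.lowest = TRUE)
  data.frame(tmb = tmb, tmbGroup = grp)
}

#' Kaplan-Meier estimate with landmark lookup
#'
#' Product-limit estimate with Greenwood standard errors (via the
#' survival package) and a landmark accessor returning the survival
#' probability at the largest step time not exceeding `t`.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @return A list with `time`, `surv`, `lower`, `upper`, `stderr`,
#'   `nRisk`, `nEvent` and the function `landmark(t)`.
#' @export
kmEstimate <- function(time, event) {
  if (!length(time)) stop("empty survival dataset")
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event flags must be 0/1")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "log-log")
  out <- list(time = sf$time, surv = sf$surv, lower = sf$lower,
              upper = sf$upper, stderr = sf$std.err, nRisk = sf$n.risk,
              nEvent = sf$n.event)
  out$landmark <- function(t) {
    idx <- which(out$time <= t)
    if (!length(idx)) 1 else out$surv[max(idx)]
  }
  out
}

#' Log-rank test
#'
#' @param time,event as in [kmEstimate()].
#' @param group group label per observation.
#' @return A list with `chisq`, `df`, `p`.
#' @export
logRank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) stop("need at least two groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Exact binomial design power
#'
#' For a single-arm design testing H0: p = p0 against p > p0 at one-sided
#' level `alpha`, the rejection threshold is the smallest count `c` with
#' `P(X >= c | n, p0) <= alpha`; power is `P(X >= c | n, p1)`, both by
#' exact binomial sums. An infeasible design (no such `c <= n`) reports
#' power 0.
#'
#' @param p0 null response rate.
#' @param p1 alternative response rate (> p0).
#' @param alpha one-sided significance level.
#' @param n sample size.
#' @return A list with `critical` (count) and `power`.
#' @export
#' @examples
#' designPower(0.05, 0.15, 0.05, 180)
designPower <- function(p0, p1, alpha, n) {
  stopifnot(p0 > 0, p0 < p1, p1 <= 1, n >= 1, alpha > 0, alpha < 1)
  k <- 0:n
  tail <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)  # P(X >= k)
  # relative tolerance guards floating-point ties at the level boundary
  feasible <- which(tail <= alpha * (1 + 1e-12))
  if (!length(feasible)) return(list(critical = NA_integer_, power = 0))
  crit <- k[feasible[1]]
  list(critical = crit,
       power = stats::pbinom(crit - 1, n, p1, lower.tail = FALSE))
}

#' Correlation with exact small-sample permutation p-value
#'
#' Pearson or Spearman correlation; for `n <= 9` the two-sided p-value is
#' computed from the full permutation distribution of the coefficient
#' (`n!` relabellings), otherwise the standard t (Pearson) or
#' large-sample (Spearman) approximation from [stats::cor.test()] is
#' used.
#'
#' @param x,y paired numeric vectors, `n >= 3`, finite, nonconstant.
#' @param method `"spearman"` (default; appropriate for the bounded,
#'   non-normal pathological-regression scale) or `"pearson"`.
#' @return A list with `estimate`, `p`, `method`, `pMethod`.
#' @export
correlateResponse <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L) stop("need >= 3 paired values")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  est <- stats::cor(x, y, method = method)
  n <- length(x)
  if (n <= 9L) {
    perms <- .allPermutations(n)
    rx <- if (method == "spearman") rank(x) else x
    ry <- if (method == "spearman") rank(y) else y
    ref <- apply(perms, 1L, function(ix) stats::cor(rx, ry[ix]))
    obs <- stats::cor(rx, ry)
    p <- mean(abs(ref) >= abs(obs) - 1e-12)
    return(list(estimate = est, p = p, method = method,
                pMethod = "exact permutation"))
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(estimate = est, p = ht$p.value, method = method,
       pMethod = "asymptotic")
}

# all n! permutations of 1..n as a matrix (rows); n <= 9
.allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
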