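test_that("response classification follows the MPR rule table", {
  res <- classifyResponse(c(10, 0, 5, 40, NA),
                          c("R0", "R0", "R1/R2", "R0", "none"),
                          c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # boundary is inclusive: 10% viable with R0 resection is MPR
  expect_identical(as.character(res$category),
                   c("MPR(non-pCR)", "pCR", "non-MPR", "non-MPR",
                     "not-evaluable"))
  expect_identical(res$mpr, c(TRUE, TRUE, FALSE, FALSE, NA))
  expect_equal(res$pathologicalRegression, c(-90, -100, -95, -60, NA))
  # counts are invariant to patient order
  perm <- c(3, 5, 1, 2, 4)
  res2 <- classifyResponse(c(10, 0, 5, 40, NA)[perm],
                           c("R0", "R0", "R1/R2", "R0", "none")[perm],
                           c(TRUE, TRUE, TRUE, TRUE, FALSE)[perm])
  expect_identical(table(res$category), table(res2$category))
  # inconsistent input is refused
  expect_error(classifyResponse(5, "R0", FALSE), "without surgery")
  expect_error(classifyResponse(NA, "R0", TRUE), "missing exactly")
  expect_error(classifyResponse(105, "R0", TRUE), "0, 100")
})

test_that("response rates and intervals reproduce the trial conventions", {
  mpr <- responseRateCI(29, 143)
  expect_identical(unname(mpr$percent), c(20, 14, 28))
  pcr <- responseRateCI(8, 143)
  expect_identical(unname(pcr$percent["rate"]), 6)
  zero <- responseRateCI(0, 50)
  expect_equal(zero$rate, 0)
  expect_equal(zero$lower, 0)
  # Wilson bounds match an independent root-finding inversion of the
  # score equation (p-hat - p)^2 = z^2 p(1-p)/n
  w <- responseRateCI(8, 143, "wilson")
  z <- qnorm(0.975); ph <- 8 / 143
  f <- function(p) (ph - p)^2 - z^2 * p * (1 - p) / 143
  lo <- uniroot(f, c(1e-9, ph), tol = 1e-12)$root
  hi <- uniroot(f, c(ph, 1 - 1e-9), tol = 1e-12)$root
  expect_equal(w$lower, lo, tolerance = 1e-8)
  expect_equal(w$upper, hi, tolerance = 1e-8)
})

test_that("Clopper-Pearson intervals achieve nominal coverage", {
  set.seed(16)
  n <- 143; p <- 0.2
  x <- rbinom(10000, n, p)
  lo <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
  cover <- mean(lo <= p & p <= hi)
  expect_gte(cover, 0.95 - 3 * sqrt(0.05 * 0.95 / 10000))
  # the interval always contains the point estimate
  ci <- responseRateCI(29, 143)
  expect_true(ci$lower <= ci$rate && ci$rate <= ci$upper)
})

test_that("the exact test reproduces the printed subgroup comparisons", {
  # PD-L1 TPS (<1% / 1-49% / >=50%) by MPR
  expect_equal(roundHalfUp(
    fisherExact(matrix(c(6, 47, 1, 19, 15, 30), 3, byrow = TRUE)), 2), 0.01)
  # TMB pairwise 2x2 comparisons
  expect_equal(roundHalfUp(
    fisherExact(matrix(c(8, 52, 1, 9), 2, byrow = TRUE)), 2), 1.00)
  expect_equal(roundHalfUp(
    fisherExact(matrix(c(8, 52, 5, 10), 2, byrow = TRUE)), 2), 0.12)
  expect_equal(roundHalfUp(
    fisherExact(matrix(c(1, 9, 5, 10), 2, byrow = TRUE)), 2), 0.34)
  # proportional rows are exactly independent
  expect_equal(fisherExact(matrix(c(2, 4, 1, 2), 2, byrow = TRUE)), 1)
  expect_error(fisherExact(matrix(c(-1, 2, 1, 2), 2)), "nonnegative")
})

test_that("2x2 exact p agrees with brute-force enumeration for all small margins", {
  # exhaustive sweep: every 2x2 table with margins <= 12
  for (a in 0:4) for (b in 0:4) for (c in 0:4) for (d in 0:4) {
    m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    # oracle: direct enumeration over the first cell with factorial masses
    rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
    logp <- function(x) {
      tab <- matrix(c(x, rs[1] - x, cs[1] - x, rs[2] - cs[1] + x), 2)
      if (any(tab < 0)) return(-Inf)
      sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N) -
        sum(lfactorial(tab))
    }
    probs <- exp(vapply(0:min(rs[1], cs[1]), logp, 0))
    pObs <- exp(logp(m[1, 1]))
    oracle <- min(1, sum(probs[probs <= pObs * (1 + 1e-12)]))
    expect_equal(fisherExact(m), oracle, tolerance = 1e-10)
  }
})

test_that("exact p agrees with the standard implementation on r x c tables", {
  tables <- list(matrix(c(6, 47, 1, 19, 15, 30), 3, byrow = TRUE),
                 matrix(c(3, 1, 4, 2, 2, 5), 3, byrow = TRUE),
                 matrix(c(2, 3, 1, 4, 2, 0, 5, 1, 3), 3, byrow = TRUE))
  for (m in tables)
    expect_equal(fisherExact(m), fisher.test(m)$p.value, tolerance = 1e-6)
})

test_that("a degenerate third column collapses Freeman-Halton to the 2x2 p", {
  m22 <- matrix(c(3, 7, 6, 2), 2, byrow = TRUE)
  m23 <- cbind(m22, c(0, 0))
  expect_equal(fisherExact(m23), fisherExact(m22), tolerance = 1e-12)
  # transposing (2xc as cx2) leaves the p unchanged
  expect_equal(fisherExact(t(m22)), fisherExact(m22), tolerance = 1e-12)
  # a table with an all-zero margin everywhere informative is refused
  expect_error(fisherExact(matrix(c(0, 0, 1, 2), 2)), "two rows")
})

test_that("Welch machinery matches the closed-form and printed values", {
  set.seed(17)
  x <- rnorm(12, 1, 2); y <- rnorm(9, 0, 1)
  w <- welchT(x, y)
  # from-scratch Welch formula oracle
  sx <- var(x) / 12; sy <- var(y) / 9
  tO <- (mean(x) - mean(y)) / sqrt(sx + sy)
  dfO <- (sx + sy)^2 / (sx^2 / 11 + sy^2 / 8)
  expect_equal(w$t, tO, tolerance = 1e-12)
  expect_equal(w$df, dfO, tolerance = 1e-12)
  expect_equal(w$p, 2 * pt(abs(tO), dfO, lower.tail = FALSE),
               tolerance = 1e-12)
  same <- welchT(c(x, 0.1), c(x, 0.1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welchT(rep(1, 5), y), "'x'")
  # printed (t, df) pairs reproduce the reported two-sided p
  expect_equal(signif(welchPFromStats(-5.47, 27.02), 2), 8.6e-6)
  expect_equal(signif(welchPFromStats(-3.18, 28.45), 2), 0.0035)
  expect_equal(roundHalfUp(welchPFromStats(-1.77, 9.52), 2), 0.11)
  expect_equal(welchPFromStats(0, 10), 1)
  expect_error(welchPFromStats(1, 0), "df")
})

test_that("TMB arithmetic and binning follow the stated convention", {
  r <- computeTMB(5, 2.5e6)
  expect_equal(r$tmb, 2)
  expect_identical(as.character(r$tmbGroup), "<10")
  expect_equal(computeTMB(0, 3e7)$tmb, 0)
  # bins [0,10), [10,16), [16,Inf): exhaustive edge scan
  edges <- computeTMB(c(99, 100, 154, 159.9, 160, 200) * 3, 3e7)
  expect_identical(as.character(edges$tmbGroup),
                   c("<10", "10-15", "10-15", "10-15", ">=16", ">=16"))
  expect_error(computeTMB(5, 0), "positive")
})

test_that("the product-limit estimate matches hand computation", {
  # times 1, 2+, 3, 4, 5+ with events at 1, 3, 4:
  # S(1) = 4/5, S(3) = 4/5 * 2/3, S(4) = 4/5 * 2/3 * 1/2
  km <- kmEstimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 1, 0))
  ev <- km$nEvent > 0
  expect_equal(km$surv[ev], c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2),
               tolerance = 1e-12)
  expect_equal(km$landmark(0.5), 1)
  expect_equal(km$landmark(3.5), 8 / 15, tolerance = 1e-12)
  expect_equal(km$landmark(100), 4 / 15, tolerance = 1e-12)
  # all censored: survival stays at 1
  km2 <- kmEstimate(1:4, rep(0, 4))
  expect_true(all(km2$surv == 1))
  # no censoring: KM reduces to 1 - ECDF at every event time
  set.seed(18)
  tt <- sort(runif(20, 1, 10))
  km3 <- kmEstimate(tt, rep(1, 20))
  expect_equal(km3$surv, 1 - ecdf(tt)(km3$time), tolerance = 1e-12)
  expect_error(kmEstimate(numeric(0), numeric(0)), "empty")
  expect_error(kmEstimate(c(0, 1), c(1, 1)), "positive")
})

test_that("the log-rank test separates distinct hazards", {
  set.seed(19)
  t1 <- rexp(60, 0.05); t2 <- rexp(60, 0.25)
  cens <- rexp(120, 0.02)
  time <- pmin(c(t1, t2), cens); event <- as.integer(c(t1, t2) <= cens)
  lr <- logRank(time, event, rep(c("a", "b"), each = 60))
  expect_lt(lr$p, 1e-4)
  expect_identical(lr$df, 1L)
  # identical duplicated groups: no evidence of difference
  lr0 <- logRank(rep(time, 2), rep(event, 2),
                 rep(c("a", "b"), each = 120))
  expect_gt(lr0$p, 0.99)
})

test_that("exact binomial design power matches the trial design", {
  d <- designPower(0.05, 0.15, 0.05, 180)
  expect_gte(d$power, 0.95)
  # direct enumeration of the two-outcome case n = 1:
  # P(X >= 1 | p0 = 0.05) = 0.05 <= alpha, so c = 1 and power = p1
  d1 <- designPower(0.05, 0.3, 0.05, 1)
  expect_identical(d1$critical, 1L)
  expect_equal(d1$power, 0.3)
  # p1 = 1 gives certain rejection whenever the design is feasible
  expect_equal(designPower(0.05, 1, 0.05, 20)$power, 1)
  # infeasible design reports power 0
  expect_equal(designPower(0.5, 0.9, 1e-12, 3)$power, 0)
})

test_that("correlation handles its closed forms and exact permutation", {
  x <- c(1, 3, 4, 7, 9, 12)
  expect_equal(correlateResponse(x, x, "pearson")$estimate, 1)
  expect_equal(correlateResponse(x, -x, "pearson")$estimate, -1)
  expect_error(correlateResponse(x, rep(1, 6)), "variance")
  set.seed(20)
  y <- rnorm(6)
  for (method in c("pearson", "spearman")) {
    res <- correlateResponse(x, y, method)
    expect_identical(res$pMethod, "exact permutation")
    # oracle: independent recursive enumeration of all 720 permutations
    rx <- if (method == "spearman") rank(x) else x
    ry <- if (method == "spearman") rank(y) else y
    ref <- vapply(oraclePermutations(6), function(ix) cor(rx, ry[ix]), 0)
    pOracle <- mean(abs(ref) >= abs(cor(rx, ry)) - 1e-12)
    expect_equal(res$p, pOracle, tolerance = 1e-12)
  }
  # large samples fall back to the asymptotic test
  set.seed(21)
  xl <- rnorm(40); yl <- 0.5 * xl + rnorm(40)
  rl <- correlateResponse(xl, yl, "pearson")
  expect_identical(rl$pMethod, "asymptotic")
  expect_equal(rl$p, cor.test(xl, yl)$p.value, tolerance = 1e-12)
})
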