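# small labelled experiment: nf features x n samples, causal features
# shifted by d in the positive class
labelledExperiment <- function(nf = 40, n = 60, causal = integer(0), d = 0,
                               seed = 1, zeroInflate = integer(0)) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), length.out = n)
  mat <- matrix(abs(rnorm(nf * n, mean = 5)), nrow = nf,
                dimnames = list(sprintf("T01:F%03d", seq_len(nf)),
                                sprintf("S%03d", seq_len(n))))
  for (f in causal) mat[f, y] <- mat[f, y] + d
  for (f in zeroInflate) mat[f, runif(n) < 0.4] <- 0
  list(x = toyExperiment(mat), y = y)
}

test_that("candidate filtering ranks a perfectly separating detection", {
  le <- labelledExperiment(nf = 10, n = 20, seed = 2)
  mat <- SummarizedExperiment::assay(le$x)
  mat[1, ] <- ifelse(le$y, 1, 0)  # detected in 10/10 responders, 0/10 others
  SummarizedExperiment::assay(le$x, "abundance") <- mat
  split <- list(prevalent = rownames(mat)[-1],
                nonPrevalent = rownames(mat)[1])
  cand <- filterCandidates(split, le$x, le$y, modelConfig())
  row1 <- cand[cand$feature == "T01:F001", ]
  expect_lt(row1$p, 0.001)
  expect_equal(row1$statistic, 20)  # 2x2 chi-squared without correction
  expect_identical(cand$feature[1], "T01:F001")
})

test_that("outcome-independent features get p = 1 and degenerate tables are safe", {
  le <- labelledExperiment(nf = 4, n = 20, seed = 3)
  mat <- SummarizedExperiment::assay(le$x)
  mat[1, ] <- 7                       # identical across classes
  mat[2, ] <- rep(c(3, 9), 10)        # identical distribution per class
  SummarizedExperiment::assay(le$x, "abundance") <- mat
  split <- list(prevalent = rownames(mat)[1:2], nonPrevalent = rownames(mat)[3:4])
  expect_message(
    cand <- filterCandidates(split, le$x, le$y, modelConfig()),
    "degenerate")   # features 3-4 are always detected
  expect_equal(cand$p[cand$feature == "T01:F001"], 1)
  expect_true(all(cand$p[cand$stratum == "nonPrevalent"] == 1))
})

test_that("candidate caps keep only the strongest features per stratum", {
  le <- labelledExperiment(nf = 30, n = 80, causal = 1:3, d = 1.2, seed = 4)
  split <- list(prevalent = rownames(le$x), nonPrevalent = character(0))
  cfg <- modelConfig(prevalentCap = 10)
  cand <- filterCandidates(split, le$x, le$y, cfg)
  expect_identical(sum(cand$candidate), 10L)
  top <- cand$feature[cand$candidate]
  expect_true(all(sprintf("T01:F%03d", 1:3) %in% top))
})

test_that("an overwhelming penalty shrinks the model to the base rate", {
  le <- labelledExperiment(nf = 6, n = 40, causal = 1:2, d = 2, seed = 5)
  cfg <- modelConfig(penaltyGrid = c(1e6, 1e5), cvFolds = 3)
  fit <- fitGamLasso(rownames(le$x), le$x, le$y, cfg)
  expect_length(selectedFeatures(fit), 0L)
  p <- predictProbability(fit, le$x)
  expect_true(all(abs(p - mean(le$y)) < 1e-6))
})

test_that("a perfectly aligned feature yields cross-validated AUC 1", {
  le <- labelledExperiment(nf = 3, n = 40, seed = 6)
  mat <- SummarizedExperiment::assay(le$x)
  mat[1, ] <- ifelse(le$y, 10, 1)
  SummarizedExperiment::assay(le$x, "abundance") <- mat
  fit <- fitGamLasso(rownames(le$x), le$x, le$y,
                     modelConfig(cvFolds = 4, seed = 3))
  expect_equal(fit@cvAuc, 1)
  expect_true("T01:F001" %in% selectedFeatures(fit))
})

test_that("the prevalent-feature cap is enforced by exhaustive search", {
  le <- labelledExperiment(nf = 12, n = 80, causal = 1:4, d = 1.5, seed = 7)
  prev <- rep(c(TRUE, FALSE), each = 6)  # features 1-6 flagged prevalent
  fit <- fitGamLasso(rownames(le$x), le$x, le$y,
                     modelConfig(cvFolds = 3, maxPrevalentInModel = 1),
                     prevalent = prev)
  nPrevSel <- sum(selectedFeatures(fit) %in% rownames(le$x)[prev])
  expect_lte(nPrevSel, 1L)
  expect_true(validObject(fit))
})

test_that("selection size is nonincreasing along the penalty grid", {
  le <- labelledExperiment(nf = 10, n = 60, causal = 1:3, d = 1.5, seed = 8)
  a <- SummarizedExperiment::assay(le$x)
  specs <- lapply(rownames(a), function(f)
    immunoMPR:::.makeBasisSpec(a[f, ], 4L))
  blocks <- lapply(seq_along(specs), function(i)
    immunoMPR:::.evalBasis(specs[[i]], a[i, ]))
  X <- do.call(cbind, blocks)
  ends <- cumsum(vapply(blocks, ncol, 1L))
  groups <- mapply(function(s, e) seq.int(e - s + 1L, e),
                   vapply(blocks, ncol, 1L), ends, SIMPLIFY = FALSE)
  lambdas <- exp(seq(log(0.2), log(0.002), length.out = 12))
  path <- immunoMPR:::.groupLassoPath(X, le$y, groups, lambdas,
                                      maxit = 2000, tol = 1e-9)
  sizes <- vapply(path, function(p) {
    sum(vapply(groups, function(idx) sqrt(sum(p$beta[idx]^2)) > 1e-8, TRUE))
  }, 0L)
  expect_true(all(diff(sizes) >= 0))  # lambdas decrease along the path
})

test_that("prediction demands the selected features and round-trips", {
  le <- labelledExperiment(nf = 8, n = 50, causal = 1:2, d = 2, seed = 9)
  fit <- fitGamLasso(rownames(le$x), le$x, le$y, modelConfig(cvFolds = 3))
  p <- predictProbability(fit, le$x)
  expect_true(all(p >= 0 & p <= 1))
  # training samples reproduce the stored apparent AUC
  expect_equal(rocAuc(p, le$y)$auc, fit@apparentAuc)
  if (length(selectedFeatures(fit))) {
    xMissing <- le$x[setdiff(rownames(le$x), selectedFeatures(fit)[1]), ]
    expect_error(predictProbability(fit, xMissing),
                 selectedFeatures(fit)[1], fixed = TRUE)
  }
  # serialization round trip preserves predictions exactly
  path <- withr::local_tempfile(fileext = ".json")
  writeModel(fit, path)
  back <- readModel(path)
  expect_equal(predictProbability(back, le$x), p, tolerance = 1e-12)
  expect_identical(selectedFeatures(back), selectedFeatures(fit))
})

test_that("a monotone single-feature smooth predicts monotonically", {
  le <- labelledExperiment(nf = 1, n = 80, seed = 10)
  mat <- SummarizedExperiment::assay(le$x)
  mat[1, ] <- seq(0, 10, length.out = 80)
  le$y <- mat[1, ] + rnorm(80, sd = 1) > 5
  SummarizedExperiment::assay(le$x, "abundance") <- mat
  fit <- fitGamLasso(rownames(le$x), le$x, le$y, modelConfig(cvFolds = 4))
  grid <- matrix(seq(0, 10, length.out = 50), nrow = 1,
                 dimnames = list(rownames(mat), NULL))
  pg <- predictProbability(fit, toyExperiment(grid))
  # predictions equal the logistic transform of the stored smooth, so
  # wherever the fitted smooth is monotone the probabilities are too
  f <- rownames(mat)[1]
  eta <- fit@intercept
  if (f %in% selectedFeatures(fit))
    eta <- eta + drop(immunoMPR:::.evalBasis(fit@bases[[f]], grid[1, ]) %*%
                        fit@coefficients[[f]])
  expect_equal(unname(pg), unname(plogis(eta)), tolerance = 1e-12)
  if (all(diff(eta) >= 0)) expect_true(all(diff(pg) >= -1e-12))
  # the overall trend tracks the signal even if the tails wiggle
  expect_gt(cor(seq_len(50), pg, method = "spearman"), 0.9)
  expect_gt(pg[50], pg[1])
})

test_that("AUC equals the exhaustive pairwise Mann-Whitney count", {
  set.seed(11)
  for (rep in 1:3) {
    scores <- sample(round(runif(30), 2))  # ties likely
    y <- runif(30) < 0.5
    if (all(y) || !any(y)) y[1:2] <- c(TRUE, FALSE)
    r <- rocAuc(scores, y)
    pos <- scores[y]; neg <- scores[!y]
    oracle <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(r$auc, oracle, tolerance = 1e-12)
    # curve endpoints and monotonicity
    expect_equal(r$curve[1, ], data.frame(fpr = 0, tpr = 0))
    expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
    # trapezoidal integral of the curve equals the rank AUC
    trap <- sum(diff(r$curve$fpr) *
                  (utils::head(r$curve$tpr, -1) + utils::tail(r$curve$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
  }
})

test_that("AUC has its closed-form limits and agrees with pROC", {
  expect_equal(rocAuc(1:10, rep(c(FALSE, TRUE), each = 5))$auc, 1)
  expect_equal(rocAuc(rep(1, 10), rep(c(FALSE, TRUE), each = 5))$auc, 0.5)
  expect_error(rocAuc(1:5, rep(TRUE, 5)), "both classes")
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- rnorm(40); y <- runif(40) < 0.4
  y[1:2] <- c(TRUE, FALSE)
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(
    response = y, predictor = scores, direction = "<", quiet = TRUE))))
  expect_equal(rocAuc(scores, y)$auc, ref, tolerance = 1e-12)
})

test_that("group comparison reproduces the ANOVA decomposition exactly", {
  set.seed(13)
  vals <- rnorm(45); grp <- rep(c("MPR", "non-MPR", "PD"), each = 15)
  res <- compareProbabilityGroups(vals, grp)
  # two-pass textbook decomposition oracle
  gm <- mean(vals)
  ssb <- sum(tapply(vals, grp, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(vals, grp, function(v) sum((v - mean(v))^2)))
  Fo <- (ssb / 2) / (ssw / 42)
  expect_equal(res$anova$sumsq, c(ssb, ssw), tolerance = 1e-10)
  expect_equal(res$anova$statistic[1], Fo, tolerance = 1e-10)
  expect_false(res$multiplicityAdjusted)
  expect_identical(nrow(res$pairwise), 3L)
  # pairwise Welch matches the from-scratch formula
  a <- vals[grp == "MPR"]; b <- vals[grp == "non-MPR"]
  tW <- (mean(a) - mean(b)) / sqrt(var(a) / 15 + var(b) / 15)
  row <- res$pairwise[res$pairwise$group1 == "MPR" &
                        res$pairwise$group2 == "non-MPR", ]
  expect_equal(row$t, tW, tolerance = 1e-10)
})

test_that("group comparison handles identical and separated groups", {
  # three groups with identical values: no between-group variance
  vals <- rep(c(1, 2, 3), 3)
  grp <- rep(c("A", "B", "C"), each = 3)
  res <- compareProbabilityGroups(vals, grp)
  expect_equal(res$anova$statistic[1], 0)
  expect_equal(res$anova$p[1], 1)
  expect_true(all(res$pairwise$p == 1))
  # maximal separation with tiny jitter
  set.seed(14)
  v2 <- c(rnorm(4, 0, 1e-8), rnorm(4, 1, 1e-8))
  r2 <- suppressWarnings(compareProbabilityGroups(v2, rep(c("A", "B"),
                                                          each = 4)))
  expect_lt(r2$pairwise$p[1], 1e-12)
  expect_gt(r2$pairwise$ciLow[1] * r2$pairwise$ciHigh[1], 0)
  # undersized groups are excluded with a warning
  w <- testthat::capture_warnings(
    compareProbabilityGroups(c(v2, 0.5), c(rep(c("A", "B"), each = 4), "C")))
  expect_true(any(grepl("C", w)))
})

test_that("paired pre/post testing flags planted expansion only", {
  panel <- tinyPanel()
  ids <- tinyFeatureIds(panel)
  set.seed(15)
  pre <- matrix(abs(rnorm(8 * 30, 5)), nrow = 8,
                dimnames = list(ids, sprintf("P%02d_pre", 1:30)))
  post <- pre + matrix(rnorm(8 * 30, 0, 0.3), nrow = 8)
  post[2, ] <- post[2, ] + 2  # constant positive shift on one feature
  patients <- sprintf("P%02d", 1:30)
  xPre <- toyExperiment(pre, "pre", patient = patients)
  colnames(post) <- sprintf("P%02d_post", 1:30)
  xPost <- toyExperiment(post, "post", patient = patients)
  res <- pairedPrePostTest(xPre, xPost)
  hit <- res[res$feature == ids[2], ]
  expect_lt(hit$q, 0.05)
  expect_identical(hit$direction, "expansion")
  # BH-adjusted p are monotone nondecreasing in raw p
  expect_true(all(diff(res$q[order(res$p)]) >= 0))
  # identical matrices: all p = 1, nothing flagged
  same <- pairedPrePostTest(xPre, toyExperiment(`colnames<-`(pre,
    colnames(post)), "post", patient = patients))
  expect_true(all(same$p == 1))
  expect_true(all(same$direction == "none"))
})
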