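# synthetic two-arm matrix: nf features over 13 + 13 extreme samples,
# optionally with one planted mean shift
armMatrix <- function(nf = 200, perArm = 13, plantShift = 0, seed = 1) {
  set.seed(seed)
  n <- 2 * perArm
  mat <- matrix(abs(rnorm(nf * n, mean = 5)), nrow = nf,
                dimnames = list(sprintf("T01:F%03d", seq_len(nf)),
                                sprintf("S%02d", seq_len(n))))
  if (plantShift != 0) mat[1, seq_len(perArm)] <- mat[1, seq_len(perArm)] +
    plantShift
  list(x = toyExperiment(mat),
       labels = rep(c("regression", "progression"), each = perArm))
}

test_that("extreme cohorts are forced when candidates exactly fill the arms", {
  v <- c(seq(2, 50, length.out = 13), seq(91, 99, length.out = 13))
  cohort <- data.frame(patient_id = sprintf("P%02d", seq_along(v)),
                       viable_percent = v)
  cfg <- selectionConfig(regressionViableMax = 88, progressionViableMin = 90)
  arms <- selectExtremeCohorts(cohort, NULL, cfg)
  expect_setequal(arms$regression, cohort$patient_id[1:13])
  expect_setequal(arms$progression, cohort$patient_id[14:26])
})

test_that("hand-enumerated two-per-arm selection picks the extremes", {
  cohort <- data.frame(patient_id = c("a", "b", "c", "d"),
                       viable_percent = c(5, 8, 95, 99))
  cfg <- selectionConfig(perArmK = 2, regressionViableMax = 10,
                         progressionViableMin = 90)
  arms <- selectExtremeCohorts(cohort, NULL, cfg)
  expect_setequal(arms$regression, c("a", "b"))
  expect_setequal(arms$progression, c("c", "d"))
})

test_that("dual-eligible samples join one arm only, the more extreme one", {
  # under the literal thresholds (<=88, >=20) viable 50 qualifies for both
  v <- c(1:13, 50, 87:99)
  cohort <- data.frame(patient_id = sprintf("P%02d", seq_along(v)),
                       viable_percent = v)
  arms <- selectExtremeCohorts(cohort, NULL, selectionConfig())
  expect_length(intersect(arms$regression, arms$progression), 0L)
  both <- c(arms$regression, arms$progression)
  expect_identical(anyDuplicated(both), 0L)
  # viable 50 is closer to 0 than to 100 only at a tie; here 50 < 100-50
  # is false, so it is regression-eligible by the tie rule
  p50 <- cohort$patient_id[v == 50]
  expect_false(p50 %in% arms$progression)
})

test_that("an undersized arm raises an error naming it", {
  cohort <- data.frame(patient_id = c("a", "b", "c"),
                       viable_percent = c(5, 6, 95))
  cfg <- selectionConfig(perArmK = 2, regressionViableMax = 10,
                         progressionViableMin = 90)
  expect_error(selectExtremeCohorts(cohort, NULL, cfg), "progression")
})

test_that("normalization methods behave as documented", {
  panel <- tinyPanel()
  ids <- tinyFeatureIds(panel)
  mat <- matrix(runif(8 * 3, 0, 50), nrow = 8,
                dimnames = list(ids, c("S01", "S02", "S03")))
  x <- toyExperiment(mat)
  expect_identical(SummarizedExperiment::assay(normalizeImmunome(x, "none")),
                   mat)
  # mid-ranks of {1, 2, 3} are {1/3, 2/3, 1}
  m3 <- matrix(c(1, 2, 3), nrow = 1,
               dimnames = list(ids[1], NULL))
  r <- SummarizedExperiment::assay(normalizeImmunome(toyExperiment(m3),
                                                     "rank"))
  expect_equal(unname(r[1, ]), c(1, 2, 3) / 3)
  # rank normalization is invariant to strictly monotone transforms
  cube <- toyExperiment(mat^3)
  expect_equal(SummarizedExperiment::assay(normalizeImmunome(x, "rank")),
               SummarizedExperiment::assay(normalizeImmunome(cube, "rank")))
  # arcsinh matches the closed form
  expect_equal(SummarizedExperiment::assay(normalizeImmunome(x, "arcsinh",
                                                             cofactor = 5)),
               asinh(mat / 5))
  expect_error(normalizeImmunome(x, "log"))
})

test_that("the divergence kernel has its closed-form limits", {
  set.seed(1)
  v <- rnorm(1000)
  expect_lt(iIndex(v, v, bins = 10), 1e-3)       # identical samples
  expect_identical(iIndex(rep(1, 5), rep(1, 5)), 0)  # degenerate range
  # disjoint point masses without smoothing: exactly log 2
  expect_equal(iIndex(rep(0, 50), rep(1, 50), bins = 2, smooth = 0), log(2))
  # symmetry and the log 2 ceiling
  a <- rnorm(200); b <- rnorm(200, 3)
  expect_equal(iIndex(a, b), iIndex(b, a))
  expect_lte(iIndex(a, b), log(2))
  expect_error(iIndex(a, b, bins = 1), "bins")
  expect_error(iIndex(numeric(0), b), "nonempty")
})

test_that("the divergence estimate increases with the mean shift", {
  est <- vapply(c(0, 1, 2), function(d) {
    mean(vapply(1:10, function(s) {
      set.seed(s)
      iIndex(rnorm(2000), rnorm(2000, d), bins = 10)
    }, 0))
  }, 0)
  expect_true(all(diff(est) > 0))
})

test_that("subsampling accounting and determinism hold", {
  am <- armMatrix(nf = 50, seed = 2)
  cfg <- selectionConfig(subsetSize = 10, nSubsamples = 200, seed = 9)
  r1 <- subsampleRank(am$x, am$labels, cfg)
  r2 <- subsampleRank(am$x, am$labels, cfg)
  expect_identical(importanceTable(r1), importanceTable(r2))
  tb <- importanceTable(r1)
  expect_identical(sum(tb$timesSampled), 10L * 200L)
  expect_true(all(tb$importance[tb$retained] > 0))
  # B = 1 with m = #features samples everything exactly once
  cfgAll <- selectionConfig(subsetSize = 50, nSubsamples = 1, seed = 9)
  expect_true(all(importanceTable(subsampleRank(am$x, am$labels,
                                                cfgAll))$timesSampled == 1L))
})

test_that("null labels retain about half the features after centering", {
  am <- armMatrix(nf = 200, seed = 3)
  cfg <- selectionConfig(subsetSize = 30, nSubsamples = 2000, seed = 4)
  res <- subsampleRank(am$x, am$labels, cfg)
  frac <- mean(importanceTable(res)$retained)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 200))
  # the mean-centered score is a zero-mean statistic whose estimate
  # tightens as B grows
  meanCentered <- vapply(c(500, 5000), function(B) {
    cfgB <- selectionConfig(subsetSize = 30, nSubsamples = B, seed = 5)
    tb <- importanceTable(subsampleRank(am$x, am$labels, cfgB))
    mean(tb$observed - tb$nullMean)
  }, 0)
  expect_lt(abs(meanCentered[2]), abs(meanCentered[1]) + 0.005)
  expect_lt(abs(meanCentered[2]), 0.01)
})

test_that("a strongly planted feature ranks at the top", {
  hits <- vapply(1:5, function(s) {
    am <- armMatrix(nf = 200, plantShift = 2, seed = s)
    cfg <- selectionConfig(subsetSize = 30, nSubsamples = 2000, seed = s)
    tb <- importanceTable(subsampleRank(am$x, am$labels, cfg))
    match("T01:F001", tb$feature) <= 5
  }, TRUE)
  expect_gte(sum(hits), 4L)
})

test_that("subsampling rejects inconsistent inputs", {
  am <- armMatrix(nf = 20, seed = 6)
  expect_error(subsampleRank(am$x, am$labels[-1], selectionConfig()),
               "match the samples")
  expect_error(subsampleRank(am$x, rep("one", 26), selectionConfig()),
               "two classes")
  expect_error(subsampleRank(am$x, am$labels,
                             selectionConfig(subsetSize = 30)),
               "exceeds")
})
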