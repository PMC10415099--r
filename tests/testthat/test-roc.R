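test_that("six-voxel hand-enumerated sweep is reproduced exactly", {
  adc <- ImageVolume(array(c(400, 500, 450, 700, 800, 900, rep(2000, 21)),
                           c(3, 3, 3)), units = "adc_1e-6_mm2_per_s")
  truth <- BinaryMask(array(c(TRUE, TRUE, rep(FALSE, 25)), c(3, 3, 3)))
  region <- BinaryMask(array(c(rep(TRUE, 6), rep(FALSE, 21)), c(3, 3, 3)))
  roc <- rocSweep(adc, truth, region, thresholds = c(425, 475, 550))
  # t = 475: positives are ADC {400, 450} -> TP 1, FP 1
  expect_equal(unname(roc@counts[2, ]), c(1, 1, 1, 3))
  expect_equal(roc@sensitivity[2], 0.5)
  expect_equal(roc@specificity[2], 0.75)
  expect_equal(roc@youden[2], 0.25)
  # t = 550: sens 1, spec 0.75 -> J = 0.75, the optimum
  expect_equal(roc@optimal_threshold, 550)
  expect_equal(roc@optimal_youden, 0.75)
})

test_that("sweep counts match brute-force voxel classification", {
  set.seed(23)
  thresholds <- seq(0, 1000, by = 100)
  for (rep in 1:10) {
    a <- array(runif(6^3, 0, 1100), c(6, 6, 6))
    region <- array(runif(6^3) < 0.8, c(6, 6, 6))
    truth <- region & array(runif(6^3) < 0.3, c(6, 6, 6))
    if (!any(truth) || !any(region & !truth)) next
    adc <- ImageVolume(a, units = "adc_1e-6_mm2_per_s")
    roc <- rocSweep(adc, BinaryMask(truth), BinaryMask(region), thresholds)
    for (i in seq_along(thresholds)) {
      want <- bruteRocCounts(adc, BinaryMask(truth), BinaryMask(region),
                             thresholds[i])
      expect_equal(unname(roc@counts[i, ]), unname(want))
    }
  }
})

test_that("rate monotonicity and the Youden identity hold", {
  set.seed(4)
  a <- array(rnorm(8^3, 700, 150), c(8, 8, 8)); a[a < 0] <- 0
  truth <- array(FALSE, c(8, 8, 8)); truth[2:4, 2:4, 2:4] <- TRUE
  roc <- rocSweep(ImageVolume(a, units = "adc_1e-6_mm2_per_s"),
                  BinaryMask(truth), fullMask(c(8, 8, 8)), 0:1500)
  expect_true(all(diff(roc@sensitivity) >= 0))
  expect_true(all(diff(roc@specificity) <= 0))
  expect_equal(roc@youden, roc@sensitivity + roc@specificity - 1)
  expect_true(roc@auc >= 0 && roc@auc <= 1)
})

test_that("AUC agrees with pROC on random voxel data", {
  skip_if_not_installed("pROC")
  set.seed(31)
  n <- 400
  scores <- c(rnorm(n / 2, 500, 80), rnorm(n / 2, 800, 80))
  scores[scores < 0] <- 0
  labels <- rep(c(1, 0), each = n / 2)
  a <- array(scores, c(8, 10, 5))
  truth <- array(labels == 1, c(8, 10, 5))
  roc <- rocSweep(ImageVolume(a, units = "adc_1e-6_mm2_per_s"),
                  BinaryMask(truth), fullMask(c(8, 10, 5)),
                  thresholds = 0:1500)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              direction = ">")))
  expect_equal(roc@auc, as.numeric(ref), tolerance = 1e-3)
})

test_that("identically distributed classes give a null ROC", {
  set.seed(41)
  a <- array(runif(22^3, 200, 1200), c(22, 22, 22))   # ~10^4 voxels
  truth <- array(runif(22^3) < 0.5, c(22, 22, 22))
  roc <- rocSweep(ImageVolume(a, units = "adc_1e-6_mm2_per_s"),
                  BinaryMask(truth), fullMask(c(22, 22, 22)), 0:1500)
  expect_equal(roc@auc, 0.5, tolerance = 0.02)
  expect_lt(roc@optimal_youden, 0.05)
})

test_that("degenerate inputs are rejected", {
  adc <- tinyVolume(500, units = "adc_1e-6_mm2_per_s")
  empty <- BinaryMask(array(FALSE, c(4, 4, 4)))
  full <- fullMask()
  expect_error(rocSweep(adc, empty, full), "empty")
  outside <- tinyMask(cbind(1, 1, 1))
  region <- tinyMask(cbind(2, 2, 2))
  expect_error(rocSweep(adc, outside, region), "contained")
  expect_error(rocSweep(adc, outside, full, thresholds = c(2, 1)),
               "ascending")
})

test_that("dilated search region grows 6-connected inside the parenchyma", {
  par <- fullMask(c(7, 7, 7))
  truth <- tinyMask(cbind(4, 4, 4), dim = c(7, 7, 7))
  r0 <- dilatedSearchRegion(truth, par, 0L)
  expect_identical(imgData(r0), imgData(truth))
  r1 <- dilatedSearchRegion(truth, par, 1L)
  expect_equal(voxelCount(r1), 7L)
  expect_equal(attr(r1, "excluded_fraction"), 1 - 7 / 343)
  # monotone growth toward the parenchyma
  prev <- 0L
  for (it in 1:8) {
    ri <- dilatedSearchRegion(truth, par, it)
    expect_gte(voxelCount(ri), prev)
    prev <- voxelCount(ri)
  }
  expect_equal(voxelCount(dilatedSearchRegion(truth, par, 20L)), 343L)
})

test_that("pooling count tables reproduces and generalizes the sweep", {
  set.seed(55)
  a <- array(rnorm(6^3, 650, 120), c(6, 6, 6)); a[a < 0] <- 0
  truth <- array(FALSE, c(6, 6, 6)); truth[2:3, 2:3, 2:3] <- TRUE
  adc <- ImageVolume(a, units = "adc_1e-6_mm2_per_s")
  roc <- rocSweep(adc, BinaryMask(truth), fullMask(c(6, 6, 6)), 0:1500)

  # singleton pooling is the identity
  pooled1 <- pooledRoc(list(roc))
  expect_equal(pooled1@optimal_threshold, roc@optimal_threshold)
  expect_equal(pooled1@auc, roc@auc)

  # two identical subjects: rates unchanged (scale invariance)
  pooled2 <- pooledRoc(list(roc, roc))
  expect_equal(pooled2@sensitivity, roc@sensitivity)
  expect_equal(pooled2@youden, roc@youden)

  # count tables pool the same as ROCResult objects
  pooled3 <- pooledRoc(list(rocCountTable(roc), rocCountTable(roc)))
  expect_equal(pooled3@youden, pooled2@youden)

  expect_error(pooledRoc(list(roc,
    rocSweep(adc, BinaryMask(truth), fullMask(c(6, 6, 6)), 0:1400))),
    "share")
})

test_that("subjects separated at disjoint gaps cannot pool perfectly", {
  mk <- function(les_adc, par_adc) {
    a <- array(par_adc, c(6, 6, 6))
    truth <- array(FALSE, c(6, 6, 6)); truth[2:3, 2:3, 2:3] <- TRUE
    a[truth] <- les_adc
    rocSweep(ImageVolume(a, units = "adc_1e-6_mm2_per_s"),
             BinaryMask(truth), fullMask(c(6, 6, 6)), 0:1500)
  }
  r1 <- mk(500, 600)   # gap 500-600
  r2 <- mk(700, 800)   # gap 700-800
  expect_equal(r1@optimal_youden, 1)
  expect_equal(r2@optimal_youden, 1)
  pooled <- pooledRoc(list(r1, r2))
  expect_lt(pooled@optimal_youden, 1)
  # pooled optimum can never beat the mean of individual optima
  expect_lte(pooled@optimal_youden,
             mean(c(r1@optimal_youden, r2@optimal_youden)))
})

test_that("individual thresholds concentrate at the equal-density point", {
  # lesion ~ N(500, 60), parenchyma ~ N(850, 60): equal density at 675
  base <- PhantomSpec(seed = 1L)
  cohort <- generateCohort(base, 6, lesion_volume_range_ml = c(5, 15),
                           adc_jitter = 0, seed = 101)
  thr <- vapply(cohort, function(cs) {
    par <- parenchymaMask(cs@adc, cs@brain_mask)
    rocSweep(cs@adc, cs@truth_lesion, par)@optimal_threshold
  }, numeric(1))
  expect_lt(abs(median(thr) - 675), 40)
})
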