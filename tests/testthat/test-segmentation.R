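test_that("ratio image divides trace by ADC with guarded zeros", {
  tr <- tinyVolume(100)
  adc <- tinyVolume(200, units = "adc_1e-6_mm2_per_s")
  brain <- fullMask()
  out <- ratioImage(tr, adc, brain)
  expect_equal(unique(as.vector(imgData(out))), 0.5)

  a <- array(200, c(4, 4, 4)); a[2, 2, 2] <- 0
  out2 <- ratioImage(tr, ImageVolume(a, units = "adc_1e-6_mm2_per_s"), brain)
  expect_equal(imgData(out2)[2, 2, 2], 0)     # adc <= 0 guarded, no failure
  expect_equal(imgData(out2)[1, 1, 1], 0.5)

  # out-of-brain voxels are zeroed
  half <- tinyMask(cbind(1, 1, 1))
  out3 <- ratioImage(tr, adc, half)
  expect_equal(sum(imgData(out3) != 0), 1)

  bad <- tinyVolume(1, dim = c(5, 4, 4))
  expect_error(ratioImage(bad, adc, brain), "grid mismatch")
})

test_that("lesion-like voxels have strictly larger ratio", {
  # high trace / low ADC beats low trace / high ADC
  expect_gt(600 / 450, 420 / 850)
})

test_that("slice normalization divides by the in-brain slice mean", {
  a <- array(0, c(2, 2, 3))
  a[, , 1] <- 5                        # constant slice -> all 1
  a[, , 2] <- c(1, 3, 1, 3)            # mean 2 -> {0.5, 1.5}
  brain <- BinaryMask(array(c(rep(TRUE, 8), rep(FALSE, 4)), c(2, 2, 3)))
  out <- imgData(sliceNormalize(ImageVolume(a), brain, 3L))
  expect_equal(as.vector(out[, , 1]), rep(1, 4))
  expect_equal(as.vector(out[, , 2]), c(0.5, 1.5, 0.5, 1.5))
  expect_equal(as.vector(out[, , 3]), rep(0, 4))  # empty slice untouched
})

test_that("Gaussian smoothing preserves constants and kernel mass", {
  # kernel radius is ceiling(6 sigma) = 13 voxels; keep that margin
  const <- tinyVolume(3, dim = c(34, 34, 34))
  sm <- gaussianSmooth(const, 5)
  expect_equal(imgData(sm)[17, 17, 17], 3, tolerance = 1e-9)

  imp <- array(0, c(21, 21, 21)); imp[11, 11, 11] <- 1
  out <- imgData(gaussianSmooth(ImageVolume(imp), 5))
  expect_lte(sum(out), 1 + 1e-12)
  sigma <- 5 / (2 * sqrt(2 * log(2)))
  r <- ceiling(6 * sigma)
  w <- dnorm(-r:r, sd = sigma); w <- w / sum(w)
  expect_equal(out[11, 11, 11], w[r + 1]^3, tolerance = 1e-12)
})

test_that("Gaussian smoothing has the semigroup property", {
  set.seed(13)
  img <- tinyVolume(runif(24^3), dim = c(24, 24, 24))
  f <- 4
  twice <- gaussianSmooth(gaussianSmooth(img, f), f)
  once <- gaussianSmooth(img, f * sqrt(2))
  interior <- 9:16
  expect_lt(max(abs(imgData(twice)[interior, interior, interior] -
                    imgData(once)[interior, interior, interior])), 1e-6)
})

test_that("mirror subtraction cancels symmetry and clips negatives", {
  set.seed(3)
  half <- array(runif(2 * 4 * 4), c(2, 4, 4))
  sym <- array(0, c(4, 4, 4))
  sym[1:2, , ] <- half
  sym[4:3, , ] <- half
  out <- mirrorSubtract(ImageVolume(sym), 1L)
  expect_true(all(imgData(out) == 0))

  a <- array(0, c(4, 4, 4)); a[1, 2, 2] <- 2; a[4, 2, 2] <- 0.5
  out2 <- imgData(mirrorSubtract(ImageVolume(a), 1L))
  expect_equal(out2[1, 2, 2], 1.5)
  expect_equal(out2[4, 2, 2], 0)
})

test_that("mirror subtraction matches a voxelwise oracle on random fields", {
  set.seed(17)
  for (rep in 1:20) {
    a <- array(rnorm(4^3), c(4, 4, 4))
    got <- imgData(mirrorSubtract(ImageVolume(a), 1L))
    want <- array(0, c(4, 4, 4))
    for (i in 1:4) for (j in 1:4) for (k in 1:4)
      want[i, j, k] <- max(0, a[i, j, k] - a[5 - i, j, k])
    expect_equal(got, want)
  }
})

test_that("primary mask thresholds inclusively and dilates 6-connected", {
  zero <- tinyVolume(0, dim = c(6, 6, 6))
  brain <- fullMask(c(6, 6, 6))
  expect_equal(voxelCount(primaryMask(zero, brain)), 0L)

  a <- array(0, c(6, 6, 6)); a[3, 3, 3] <- 1
  pm <- primaryMask(ImageVolume(a), brain,
                    SegmentationConfig(dilation_iterations = 1L))
  expect_equal(voxelCount(pm), 7L)     # centre + 6 face neighbours
  got <- which(imgData(pm), arr.ind = TRUE)
  expect_true(all(rowSums(abs(sweep(got, 2, c(3, 3, 3)))) <= 1))

  b <- array(0, c(6, 6, 6))
  b[1:3, 1, 1] <- c(0.74, 0.75, 0.76)
  pm2 <- primaryMask(ImageVolume(b), brain,
                     SegmentationConfig(dilation_iterations = 0L))
  expect_equal(as.vector(imgData(pm2)[1:3, 1, 1]), c(FALSE, TRUE, TRUE))

  # dilation at the array corner stays inside the brain mask
  corner <- array(0, c(6, 6, 6)); corner[1, 1, 1] <- 1
  pm3 <- primaryMask(ImageVolume(corner), brain)
  expect_equal(voxelCount(pm3), 4L)
})

test_that("ADC gate keeps the closed band", {
  vals <- c(150, 200, 450, 620, 700)
  adc <- ImageVolume(array(c(vals, rep(1000, 59)), c(4, 4, 4)),
                     units = "adc_1e-6_mm2_per_s")
  mask <- BinaryMask(array(c(rep(TRUE, 5), rep(FALSE, 59)), c(4, 4, 4)))
  out <- adcGate(mask, adc)
  expect_equal(which(imgData(out)), c(2L, 3L, 4L))   # 200, 450, 620 survive

  empty <- BinaryMask(array(FALSE, c(4, 4, 4)))
  expect_equal(voxelCount(adcGate(empty, adc)), 0L)

  wide <- SegmentationConfig(adc_lower = 0, adc_upper = Inf)
  expect_identical(imgData(adcGate(mask, adc, wide)), imgData(mask))
})

test_that("trace percentile cleanup uses linear-interpolation percentiles", {
  d <- c(5, 5, 4)
  tr <- ImageVolume(array(c(1:100), d))
  parenchyma <- fullMask(d)
  # 95th percentile of 1..100 by type-7 interpolation = 95.05
  mask <- BinaryMask(array(c(rep(FALSE, 89), TRUE, rep(FALSE, 8), TRUE, FALSE), d))
  out <- tracePercentileCleanup(mask, tr, parenchyma)
  expect_false(imgData(out)[[90]])     # trace 90 < 95.05 removed
  expect_true(imgData(out)[[99]])      # trace 99 kept

  cfg0 <- SegmentationConfig(trace_percentile = 0)
  expect_error(SegmentationConfig(trace_percentile = 100), "0, 100")
  allm <- fullMask(d)
  kept <- tracePercentileCleanup(allm, tr, parenchyma, cfg0)
  expect_equal(voxelCount(kept), 100L) # percentile 0 keeps everything

  # mask-internal population variant
  cfgm <- SegmentationConfig(percentile_population = "mask")
  outm <- tracePercentileCleanup(allm, tr, parenchyma, cfgm)
  expect_equal(sum(imgData(outm)), sum((1:100) >= quantile(1:100, 0.95)))
})

test_that("parenchyma mask excludes CSF by the ADC cutoff", {
  case <- generateCase(PhantomSpec(grid_shape = c(32L, 38L, 26L),
                                   lesion_radii_vox = c(3, 3, 3),
                                   lesion_center_vox = c(24, 19, 13),
                                   noise_sd = 0, parenchyma_adc_sd = 0,
                                   seed = 8))
  par <- parenchymaMask(case@adc, case@brain_mask)
  adc <- imgData(case@adc); brain <- imgData(case@brain_mask)
  expect_true(all(adc[imgData(par)] < 2000))
  csf <- brain & adc >= 2000
  expect_gt(sum(csf), 0)
  expect_false(any(imgData(par) & csf))

  everything <- parenchymaMask(case@adc, case@brain_mask,
                               SegmentationConfig(csf_adc_cutoff = Inf))
  expect_identical(imgData(everything), brain)
  expect_warning(parenchymaMask(case@adc, case@brain_mask,
                                SegmentationConfig(csf_adc_cutoff = 0)),
                 "empty")
})

test_that("delineate composes the stages and respects its invariants", {
  case <- generateCase(PhantomSpec(seed = 7,
                                   lesion_radii_vox = c(6.5, 6.5, 6.5)))
  res <- delineate(case@b0, case@trace, case@adc, case@brain_mask)
  les <- imgData(res@lesion_mask)
  expect_true(any(les))
  expect_true(all(imgData(res@primary_mask)[les]))  # lesion subset of primary
  adc <- imgData(case@adc)
  expect_true(all(adc[les] >= 200 & adc[les] <= 620))
  expect_true(all(imgData(case@brain_mask)[les]))
  # stages only remove voxels from the primary mask onward
  log <- res@stage_log
  expect_lte(log[["adc_gate"]], log[["primary_mask"]])
  expect_lte(log[["trace_cleanup"]], log[["adc_gate"]])
  # determinism
  res2 <- delineate(case@b0, case@trace, case@adc, case@brain_mask)
  expect_identical(les, imgData(res2@lesion_mask))
})

test_that("a lesion above the ADC band is suppressed by the gate", {
  spec <- PhantomSpec(seed = 19, lesion_adc_mean = 700, lesion_adc_sd = 20,
                      lesion_radii_vox = c(6, 6, 6))
  case <- generateCase(spec)
  res <- delineate(case@b0, case@trace, case@adc, case@brain_mask)
  # trace-hyperintense but ADC ~700 > 620: nearly nothing survives the gate
  expect_lt(voxelCount(res@lesion_mask), 0.1 * voxelCount(case@truth_lesion))
})
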