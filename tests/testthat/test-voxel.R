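suv_vol <- function(arr, sp = c(4, 4, 4)) image_volume(arr, sp, "SUV")

test_that("QSD equals the sample SD of the reference liver ROI", {
  v <- toy_suv_volume(c(15L, 15L, 3L), seed = 4)
  roi <- roi_spec("liver", 2L, c(8, 8), 10)
  q <- compute_qsd(v, roi)
  expect_equal(q$value, roi_stats(v, roi)$sd)
  # brute-force oracle
  xs <- axis_coords(15, 4)
  m <- outer((xs - xs[8])^2, (xs - xs[8])^2, `+`) <= 100
  expect_equal(q$value, sd(v$values[, , 2][m]))
})

test_that("a degenerate (constant) reference is rejected for QSD", {
  v <- suv_vol(array(2.5, c(15L, 15L, 3L)))
  expect_error(compute_qsd(v, roi_spec("liver", 2L, c(8, 8), 10)), "degenerate")
})

test_that("voxel differences are signed RR - TR and antisymmetric", {
  rr <- toy_suv_volume(c(6L, 6L, 2L), seed = 1)
  tr <- toy_suv_volume(c(6L, 6L, 2L), seed = 2)
  d1 <- voxel_difference(tr, rr)
  d2 <- voxel_difference(rr, tr)
  expect_equal(d1$values, -d2$values)
  expect_equal(d1$values[2, 3, 1], rr$values[2, 3, 1] - tr$values[2, 3, 1])
  # rr 2.0, tr 1.9 -> +0.1 (underestimation is positive)
  rr$values[1, 1, 1] <- 2.0; tr$values[1, 1, 1] <- 1.9
  expect_equal(voxel_difference(tr, rr)$values[1, 1, 1], 0.1)
  # grid mismatch is a hard error, never silent resampling
  small <- toy_suv_volume(c(5L, 6L, 2L), seed = 3)
  expect_error(voxel_difference(small, rr), "grid")
})

test_that("paired voxel test is two-sided, symmetric, and degenerate on identity", {
  rr <- toy_suv_volume(c(10L, 10L, 10L), seed = 11)
  expect_true(is.na(paired_voxel_test(rr, rr)))
  # systematic offset of 0.01 with tiny jitter over 1000 voxels: p < 1e-4
  set.seed(42)
  tr <- suv_vol(rr$values + 0.01 + rnorm(1000, 0, 0.002))
  expect_lt(paired_voxel_test(tr, rr), 1e-4)
  expect_equal(paired_voxel_test(tr, rr), paired_voxel_test(rr, tr))
  # matches the closed-form oracle
  oracle <- paired_t_oracle(as.numeric(rr$values), as.numeric(tr$values))
  expect_equal(paired_voxel_test(tr, rr), oracle$p, tolerance = 1e-10)
})

test_that("exceedance counting is exact and strictly greater-than", {
  # 10-voxel toy volume: exactly 3 voxels differ by 0.2, QSD = 0.1
  rr <- suv_vol(array(2, c(10L, 1L, 1L)))
  tr <- suv_vol(array(2, c(10L, 1L, 1L)))
  tr$values[c(2, 5, 9), 1, 1] <- 1.8
  d <- voxel_difference(tr, rr)
  ex <- exceedance_summary(d, 0.1, rr)
  expect_equal(ex$pct_gt_qsd, 30)
  expect_equal(ex$n_exceed, 3L)
  expect_equal(ex$max_diff_pct, 100 * 0.2 / 2)
  # a difference exactly equal to the QSD does not exceed it (0.25 is
  # exactly representable, so the strict inequality is what is tested)
  tr2 <- suv_vol(array(2, c(10L, 1L, 1L)))
  tr2$values[1, 1, 1] <- 1.75
  ex2 <- exceedance_summary(voxel_difference(tr2, rr), 0.25, rr)
  expect_equal(ex2$pct_gt_qsd, 0)
})

test_that("percentage statistics respect the reference floor", {
  rr <- suv_vol(array(c(0.05, 2, 2, 2), c(4L, 1L, 1L)))
  tr <- suv_vol(array(c(0.00, 1.8, 1.9, 2.2), c(4L, 1L, 1L)))
  ex <- exceedance_summary(voxel_difference(tr, rr), 0.15, rr, floor_suv = 0.1)
  # the 0.05-SUV voxel is excluded from the percentages
  expect_equal(ex$max_diff_pct, 10)                 # (2-1.8)/2
  expect_equal(ex$mean_diff_pct, mean(c(10, 5, -10)))
  expect_gte(ex$max_diff_pct, ex$mean_diff_pct)
  # but still counted in the exceedance denominator
  expect_equal(ex$n_support, 4L)
})

test_that("significance mask matches the exceedance count bit-exactly", {
  for (seed in 1:5) {
    rr <- toy_suv_volume(c(12L, 12L, 3L), seed = seed)
    tr <- toy_suv_volume(c(12L, 12L, 3L), seed = seed + 100)
    d <- voxel_difference(tr, rr)
    q <- 0.5
    ex <- exceedance_summary(d, q, rr)
    mask <- significance_mask(d, q)
    expect_equal(sum(mask$values), ex$n_exceed)
    expect_equal(100 * sum(mask$values) / length(mask$values), ex$pct_gt_qsd)
    # brute force
    expect_equal(sum(mask$values), sum(abs(rr$values - tr$values) > q))
    # constructed case: mask flags exactly the exceeding voxels
    expect_equal(which(mask$values > 0), which(abs(d$values) > q))
  }
  # identity comparison: empty mask
  rr <- toy_suv_volume(c(8L, 8L, 2L), seed = 1)
  m0 <- significance_mask(voxel_difference(rr, rr), 0.1)
  expect_true(all(m0$values == 0))
})

test_that("localisation scores are flat for a spatially random mask", {
  set.seed(7)
  d <- c(30L, 30L, 4L)
  mask <- array(runif(prod(d)) < 0.2, d)
  regions <- list(a = array(rep(c(TRUE, FALSE), length.out = prod(d)), d),
                  b = array(rep(c(FALSE, TRUE), length.out = prod(d)), d))
  sc <- spatial_localization_score(mask, regions)
  expect_true(all(abs(sc$enrichment - 1) < 0.15))
})

test_that("a mask confined to one region concentrates all enrichment there", {
  d <- c(20L, 20L, 2L)
  tum <- array(FALSE, d); tum[9:12, 9:12, 1] <- TRUE
  bg <- !tum
  mask <- tum   # every tumour voxel exceeds, nothing else
  sc <- spatial_localization_score(mask, list(tumour = tum, background = bg))
  g <- attr(sc, "global_rate")
  expect_equal(sc$enrichment[sc$region == "tumour"], 1 / g)
  expect_equal(sc$rate[sc$region == "background"], 0)
  expect_error(spatial_localization_score(mask, list(x = array(TRUE, c(2, 2, 2)))),
               "grid")
})
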