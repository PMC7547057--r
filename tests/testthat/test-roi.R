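const_vol <- function(value, dims = c(20L, 20L, 3L), sp = c(4, 4, 4)) {
  image_volume(array(value, dims), sp, "SUV")
}

test_that("a constant field has SD 0 and COV 0", {
  v <- const_vol(2.5)
  st <- roi_stats(v, roi_spec("liver", 2L, c(10, 10), 9))
  expect_equal(st$mean, 2.5)
  expect_equal(st$max, 2.5)
  expect_equal(st$sd, 0)
  expect_equal(st$cov, 0)
})

test_that("ROI statistics equal direct enumeration on a printed voxel list", {
  # five voxels laid out along x on one slice, radius covering exactly them
  vals <- c(2.1, 2.7, 1.9, 3.3, 2.4)
  v <- const_vol(0, dims = c(9L, 9L, 1L), sp = c(1, 1, 1))
  v$values[3:7, 5, 1] <- vals
  roi <- roi_spec("custom", 1L, c(5, 5), 2)
  got <- roi_values(v, roi)
  # enumeration oracle: every voxel centre within 2 voxels of (5, 5)
  inside <- c()
  for (i in 1:9) for (j in 1:9)
    if ((i - 5)^2 + (j - 5)^2 <= 4) inside <- c(inside, v$values[i, j, 1])
  expect_equal(sort(got), sort(inside))
  st <- roi_stats(v, roi)
  expect_equal(st$mean, mean(inside))
  expect_equal(st$max, max(inside))
  expect_equal(st$sd, sd(inside))   # sample SD, n - 1 denominator
})

test_that("ROI membership is by voxel centre with ties inside", {
  v <- const_vol(1, dims = c(11L, 11L, 1L), sp = c(1, 1, 1))
  # radius exactly 1 voxel: centre + 4 face neighbours (tie at distance 1)
  roi <- roi_spec("custom", 1L, c(6, 6), 1)
  expect_equal(length(roi_values(v, roi)), 5L)
})

test_that("ROIs outside the volume or too small are rejected", {
  v <- const_vol(1, dims = c(10L, 10L, 2L), sp = c(4, 4, 4))
  expect_error(roi_stats(v, roi_spec("custom", 5L, c(5, 5), 8)), "slice")
  expect_error(roi_stats(v, roi_spec("custom", 1L, c(1, 1), 12)), "outside")
  expect_error(roi_stats(v, roi_spec("custom", 1L, c(5, 5), 0.5)), "voxels")
})

test_that("COV follows SD/mean x 100 and rejects nonpositive means", {
  expect_equal(suv_cov(0.1, 2.5), 4.0)
  expect_equal(suv_cov(0, 17), 0)
  expect_equal(suv_cov(0.3, 2.5), 12.0)
  expect_error(suv_cov(0.1, 0), "positive")
  expect_error(suv_cov(0.1, -1), "positive")
})

test_that("delta COV is oriented so that noisier FBP gives positive values", {
  expect_equal(delta_cov(5, 5), 0)
  expect_equal(delta_cov(6.2, 5.0), 1.2)
  expect_gt(delta_cov(8, 3), 0)   # FBP noisier -> positive
  expect_lt(delta_cov(3, 8), 0)   # IR noisier -> negative
})

test_that("paired COV test matches the closed-form paired t oracle", {
  fbp <- c(1, 2, 3); ir <- c(2, 2, 5)
  oracle <- paired_t_oracle(fbp, ir)
  res <- paired_cov_test(fbp, ir)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
  expect_equal(res$mean, mean(fbp - ir))
  expect_equal(res$min, -2); expect_equal(res$max, 0)
  expect_true(res$min <= res$median && res$median <= res$max)
})

test_that("identical COV lists give a degenerate test, not an error", {
  res <- paired_cov_test(c(4, 5, 6), c(4, 5, 6))
  expect_true(res$degenerate)
  expect_true(is.na(res$p))
  expect_equal(res$mean, 0)
})

test_that("matched-pair COV differences are more variable at low CT dose", {
  bundle <- small_study(1L)
  rt <- roi_table(bundle, default_rois(small_spec()))
  rt <- rt[rt$statistic == "mean", ]
  fbp <- rt[rt$algorithm == "FBP", ]; ir <- rt[rt$algorithm == "IR", ]
  m <- match(interaction(fbp$mAs, fbp$kVp, fbp$pitch, fbp$region, drop = TRUE),
             interaction(ir$mAs, ir$kVp, ir$pitch, ir$region, drop = TRUE))
  dcov <- delta_cov(fbp$cov, ir$cov[m])
  expect_gt(sd(dcov[fbp$ctdi_mGy < 1]), sd(dcov[fbp$ctdi_mGy >= 1.6]))
})

test_that("ROI statistics agree with enumeration on random volumes", {
  for (seed in 1:5) {
    v <- toy_suv_volume(c(15L, 15L, 4L), seed = seed)
    roi <- roi_spec("custom", 2L, c(8, 8), 10)
    m <- outer((axis_coords(15, 4) - axis_coords(15, 4)[8])^2,
               (axis_coords(15, 4) - axis_coords(15, 4)[8])^2, `+`) <= 100
    vals <- v$values[, , 2][m]
    st <- roi_stats(v, roi)
    expect_equal(st$mean, mean(vals))
    expect_equal(st$sd, sd(vals))
    expect_equal(st$cov, sd(vals) / mean(vals) * 100)
    expect_equal(st$n, sum(m))
  }
})
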