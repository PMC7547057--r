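# Emission simulation and OSEM reconstruction: projection geometry,
# attenuation physics, convergence and the direction of AC-driven bias.

test_that("zero activity produces an all-zero sinogram and image", {
  d <- c(16L, 16L, 2L)
  act <- image_volume(array(0, d), c(8, 8, 8), "SUV")
  mu <- image_volume(array(0.05, d), c(8, 8, 8), "MU_511")
  sino <- simulate_pet(act, mu, seed = 1)
  expect_true(all(sino$counts == 0))
  rec <- reconstruct_osem(sino, mu)
  expect_true(all(rec$values == 0))
})

test_that("without attenuation the sinogram equals the ray-sum projection", {
  d <- c(16L, 16L, 1L)
  set.seed(5)
  act <- image_volume(array(runif(prod(d)), d), c(4, 4, 4), "SUV")
  mu0 <- image_volume(array(0, d), c(4, 4, 4), "MU_511")
  sino <- simulate_pet(act, mu0, seed = 1, nangles = 12, poisson = FALSE)
  # oracle: the angle-0 projection collapses y, i.e. row sums times voxel size
  raysum <- rowSums(act$values[, , 1]) * 4
  p0 <- sino$expected[, 1, 1] / sino$scale
  expect_equal(as.numeric(p0), raysum, tolerance = 1e-8)
})

test_that("a uniform cylinder attenuates the central ray by exp(-mu * D)", {
  n <- 64L; sp <- 4
  xs <- (seq_len(n) - (n + 1) / 2) * sp
  r2 <- outer(xs^2, xs^2, `+`)
  R <- 80   # 160-mm diameter cylinder
  disk <- r2 <= R^2
  act <- image_volume(array(as.numeric(disk), c(n, n, 1)), c(sp, sp, sp), "SUV")
  mu_val <- 0.096
  mu <- image_volume(array(disk * mu_val, c(n, n, 1)), c(sp, sp, sp), "MU_511")
  s_att <- simulate_pet(act, mu, seed = 1, nangles = 8, poisson = FALSE)
  s_0 <- simulate_pet(act, image_volume(array(0, c(n, n, 1)), c(sp, sp, sp), "MU_511"),
                      seed = 1, nangles = 8, poisson = FALSE)
  mid <- n / 2  # central detector bins straddle the axis
  factor <- (s_att$expected[mid, 1, 1] / s_att$scale) /
    (s_0$expected[mid, 1, 1] / s_0$scale)
  expect_equal(factor, exp(-mu_val * 2 * R / 10), tolerance = 0.05)
})

test_that("mismatched grids and invalid subset counts are rejected", {
  d <- c(16L, 16L, 2L)
  act <- image_volume(array(1, d), c(8, 8, 8), "SUV")
  mu_bad <- image_volume(array(0.05, c(8L, 8L, 2L)), c(8, 8, 8), "MU_511")
  expect_error(simulate_pet(act, mu_bad), "grid")
  mu <- image_volume(array(0.05, d), c(8, 8, 8), "MU_511")
  sino <- simulate_pet(act, mu, seed = 1, nangles = 12)
  expect_error(reconstruct_osem(sino, mu, subsets = 5L), "divide")
})

test_that("OSEM with the true attenuation converges to the compartment activities", {
  spec <- small_spec()
  ph <- build_phantom(spec)
  mu <- hu_to_mu(downsample_xy(ph$attenuation, spec$ct_supersample))
  sino <- simulate_pet(ph$activity, mu, counts_target = 5e6, seed = 3,
                       nangles = 96, poisson = FALSE)
  rec <- reconstruct_osem(sino, mu, iterations = 10L, subsets = 8L)
  sup <- ph$labels > 0L
  sc <- mean(ph$activity$values[sup]) / mean(rec$values[sup])
  v <- rec$values * sc
  # large compartments converge within a few percent (the small tumour
  # converges much more slowly; see the recovery checks)
  expect_lt(abs(mean(v[compartment_mask(ph, "liver")]) - 2.5) / 2.5, 0.03)
  expect_lt(abs(mean(v[compartment_mask(ph, "heart")]) - 4.0) / 4.0, 0.03)
  expect_lt(abs(mean(v[ph$labels == 1L]) - 1.0), 0.03)
})

test_that("an underestimated AC map lowers the reconstructed liver mean", {
  spec <- small_spec()
  ph <- build_phantom(spec)
  mu <- hu_to_mu(downsample_xy(ph$attenuation, spec$ct_supersample))
  liver <- compartment_mask(ph, "liver")
  n_below <- 0L
  for (s in 1:5) {
    sino <- simulate_pet(ph$activity, mu, seed = s)
    rec_true <- reconstruct_osem(sino, mu)
    mu_low <- image_volume(mu$values * 0.9, mu$spacing, "MU_511")
    rec_low <- reconstruct_osem(sino, mu_low)
    n_below <- n_below + (mean(rec_low$values[liver]) < mean(rec_true$values[liver]))
  }
  expect_equal(n_below, 5L)
})

test_that("the Poisson draw is reproducible and isolated from the caller RNG", {
  d <- c(16L, 16L, 2L)
  act <- image_volume(array(1, d), c(8, 8, 8), "SUV")
  mu <- image_volume(array(0.02, d), c(8, 8, 8), "MU_511")
  s1 <- simulate_pet(act, mu, seed = 7, nangles = 12)
  set.seed(123); x_before <- runif(1)
  s2 <- simulate_pet(act, mu, seed = 7, nangles = 12)
  expect_identical(s1$counts, s2$counts)
  set.seed(123); expect_equal(runif(1), x_before)
})
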