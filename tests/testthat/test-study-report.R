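# End-to-end plumbing: bundle structure, determinism, report tables, file
# round trips and the external-volume entry point. Uses the minimal grid so
# the full 48-protocol chain stays fast.

tiny_bundle <- function(seed = 1L, grid = default_protocol_grid()) {
  generate_study(tiny_spec(), grid = grid, seed = seed, nangles = 24L)
}

test_that("the default grid yields 48 reconstructions with one reference", {
  b <- tiny_bundle()
  expect_length(b$entries, 48L)
  refs <- vapply(b$entries, `[[`, logical(1), "reference")
  expect_equal(sum(refs), 1L)
  expect_true(all(vapply(b$entries, `[[`, 0, "ctdi") > 0))
  # all volumes share the reference grid
  for (e in b$entries) expect_silent(stopifnot_same_grid(e$volume, b$reference))
  expect_identical(b$entries[[which(refs)]]$volume$values, b$reference$values)
})

test_that("the same master seed reproduces the bundle bit-identically", {
  ref_only <- Filter(function(p) p$reference, default_protocol_grid())
  few <- c(list(ct_protocol(15, 80, 0.671, "IR")), ref_only)
  b1 <- tiny_bundle(7L, few)
  b2 <- tiny_bundle(7L, few)
  expect_identical(b1$entries[[1]]$volume$values, b2$entries[[1]]$volume$values)
  expect_identical(b1$reference$values, b2$reference$values)
  b3 <- tiny_bundle(8L, few)
  expect_false(identical(b1$entries[[1]]$volume$values, b3$entries[[1]]$volume$values))
})

test_that("degenerate protocol lists are rejected", {
  expect_error(generate_study(tiny_spec(), grid = list(), seed = 1), "empty")
  noref <- list(ct_protocol(15, 80, 0.671, "IR"))
  expect_error(generate_study(tiny_spec(), grid = noref, seed = 1),
               "reference")
})

test_that("a reference-only study compares the reference with itself", {
  ref_only <- Filter(function(p) p$reference, default_protocol_grid())
  b <- tiny_bundle(3L, ref_only)
  expect_length(b$entries, 1L)
  vc <- voxel_comparison(b$entries[[1]]$volume, b$reference, 0.1)
  expect_true(vc$degenerate)
  expect_true(is.na(vc$p))
  expect_true(all(vc$mask$values == 0))
})

test_that("run_study produces consistent tables and a manifest", {
  out <- tempfile("report")
  # coarse grid: ROIs in mm need enough voxels, so use the small spec with a
  # reduced protocol grid (both algorithms at two exposures + reference)
  grid <- c(list(ct_protocol(15, 80, 0.671, "FBP"),
                 ct_protocol(15, 80, 0.671, "IR"),
                 ct_protocol(50, 120, 0.828, "FBP")),
            Filter(function(p) p$reference, default_protocol_grid()))
  cfg <- run_config(out_dir = out, seed = 2L, spec = small_spec(), grid = grid)
  rep <- run_study(cfg)
  expect_equal(nrow(rep$voxel), 4L)
  # the reference row is the degenerate one
  ref_row <- rep$voxel[rep$voxel$reference, ]
  expect_true(is.na(ref_row$p) && is.na(ref_row$pct_gt_qsd))
  expect_equal(sum(!is.na(rep$voxel$p)), 3L)
  # every mask count agrees with its table row
  sup_n <- rep$voxel$n_support[1]
  for (i in which(!rep$voxel$reference)) {
    expect_equal(100 * sum(rep$masks[[i]]$values) / sup_n,
                 rep$voxel$pct_gt_qsd[i])
  }
  # files written
  expect_true(file.exists(file.path(out, "table1_acquisitions.csv")))
  expect_true(file.exists(file.path(out, "table3_voxel_analysis.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 2L)
  expect_equal(man$qsd, rep$qsd$value)
  # rerunning the analysis tables from the same config is identical
  tab1 <- utils::read.csv(file.path(out, "table3_voxel_analysis.csv"))
  rep2 <- run_study(cfg)
  tab2 <- utils::read.csv(file.path(out, "table3_voxel_analysis.csv"))
  expect_identical(tab1, tab2)
})

test_that("invalid configs fail with named-field diagnostics", {
  expect_error(run_config(qsd_roi = "nope"), "qsd_roi")
  noref <- list(ct_protocol(15, 80, 0.671, "IR"))
  expect_error(run_config(grid = noref), "grid")
})

test_that("volumes and ROI specs round-trip through NIfTI and YAML", {
  v <- toy_suv_volume(c(8L, 8L, 4L))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f, extra = list(ctdi_mGy = 3.3))
  v2 <- read_volume(f)
  expect_equal(v2$values, v$values, tolerance = 1e-6)
  expect_equal(v2$spacing, v$spacing)
  expect_equal(v2$unit, "SUV")
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$ctdi_mGy, 3.3)

  rois <- default_rois(small_spec())
  yf <- tempfile(fileext = ".yaml")
  write_roi_yaml(rois, yf)
  rois2 <- read_roi_yaml(yf)
  expect_equal(names(rois2), names(rois))
  expect_equal(rois2$liver$radius_mm, rois$liver$radius_mm)
  expect_equal(rois2$tumour$statistic, "max")
})

test_that("external co-registered volumes are analysed without simulation", {
  dir <- tempfile("ext"); dir.create(dir)
  set.seed(31)
  d <- c(24L, 24L, 4L)
  base <- array(2.5 + rnorm(prod(d), 0, 0.1), d)
  base[base < 0] <- 0
  rr <- image_volume(base, c(4, 4, 4), "SUV")
  tr_arr <- base; tr_arr[1:6, 1:6, 1] <- tr_arr[1:6, 1:6, 1] - 0.5
  tr <- image_volume(pmax(tr_arr, 0), c(4, 4, 4), "SUV")
  rr_p <- file.path(dir, "rr.nii.gz"); tr_p <- file.path(dir, "tr.nii.gz")
  write_volume(rr, rr_p); write_volume(tr, tr_p)
  rois <- list(liver = roi_spec("liver", 2L, c(16, 16), 9))
  res <- analyze_external(rr_p, c(tr_p), rois, out_dir = file.path(dir, "out"))
  # brute-force expectations
  q <- res$qsd$value
  n_exp <- sum(abs(rr$values - tr$values) > q)
  expect_equal(res$voxel$pct_gt_qsd, 100 * n_exp / prod(d))
  expect_equal(sum(res$masks[[1]]$values), n_exp)
  expect_lt(res$voxel$p, 1e-4)
  expect_true(file.exists(file.path(dir, "out", "voxel_analysis.csv")))

  # tr identical to rr: degenerate
  res0 <- analyze_external(rr_p, c(rr_p), rois)
  expect_true(is.na(res0$voxel$p))
  expect_equal(sum(res0$masks[[1]]$values), 0)

  # missing file and grid mismatch are clean errors
  expect_error(analyze_external(file.path(dir, "absent.nii"), tr_p, rois),
               "not found")
  small <- image_volume(array(1, c(8L, 8L, 2L)), c(4, 4, 4), "SUV")
  sm_p <- file.path(dir, "small.nii.gz"); write_volume(small, sm_p)
  expect_error(analyze_external(rr_p, sm_p, rois), "mismatch")
})

test_that("a study bundle round-trips through a NIfTI directory", {
  ref_only <- Filter(function(p) p$reference, default_protocol_grid())
  few <- c(list(ct_protocol(15, 80, 0.671, "IR")), ref_only)
  b <- tiny_bundle(5L, few)
  dir <- tempfile("study")
  write_study(b, dir)
  b2 <- read_study(dir)
  expect_length(b2$entries, 2L)
  expect_equal(b2$entries[[1]]$volume$values, b$entries[[1]]$volume$values,
               tolerance = 1e-6)
  expect_equal(b2$entries[[1]]$protocol$mAs, 15)
  expect_equal(b2$entries[[1]]$ctdi, b$entries[[1]]$ctdi)
  expect_identical(attr(b2$labels, "levels"), attr(b$labels, "levels"))
  expect_equal(b2$seed, 5L)
  # analysis machinery runs identically on the read-back bundle
  expect_true(sum(vapply(b2$entries, `[[`, logical(1), "reference")) == 1L)
  vt <- voxel_table(b2, 0.1, b2$labels > 0L)
  expect_equal(nrow(vt$table), 2L)
})

test_that("overlay rendering writes a PNG", {
  v <- toy_suv_volume(c(16L, 16L, 4L))
  mask <- significance_mask(voxel_difference(v, toy_suv_volume(c(16L, 16L, 4L), seed = 3)), 0.5)
  f <- tempfile(fileext = ".png")
  write_overlay_png(v, mask, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
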