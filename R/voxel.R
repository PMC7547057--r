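#' Quantitatively significant difference (QSD)
#'
#' The voxel-level significance threshold: one sample standard deviation of
#' the SUVs inside the liver ROI of the reference reconstruction. A
#' non-positive SD (e.g. a constant reference) is rejected, since the
#' threshold must be strictly positive.
#'
#' @param rr reference reconstruction (SUV \code{image_volume}).
#' @param liver_roi the liver \code{roi_spec} used by the ROI analysis.
#' @return object of class \code{qsd}: list with \code{value} (SUV) and
#'   \code{roi}.
#' @export
compute_qsd <- function(rr, liver_roi) {
  st <- roi_stats(rr, liver_roi)
  if (!is.finite(st$sd) || st$sd <= 0)
    stop("QSD must be positive; the reference liver ROI is degenerate")
  structure(list(value = st$sd, roi = liver_roi, liver_mean = st$mean),
            class = "qsd")
}

#' Signed voxel-wise difference between reference and test reconstruction
#'
#' \code{rr - tr} per voxel, so positive values mean the test reconstruction
#' underestimates the reference. Grids must match exactly; no resampling is
#' ever performed silently.
#'
#' @param tr,rr test and reference SUV \code{image_volume}s on one grid.
#' @return \code{image_volume} of differences (unit SUV is retained on the
#'   magnitude scale; values may be negative).
#' @export
voxel_difference <- function(tr, rr) {
  expect_unit(tr, "SUV"); expect_unit(rr, "SUV")
  stopifnot_same_grid(tr, rr, "test and reference")
  structure(list(values = rr$values - tr$values, spacing = rr$spacing,
                 unit = "SUV_DIFF", label = sprintf("RR - TR (%s)", tr$label)),
            class = "image_volume")
}

#' Paired t test of a test reconstruction against the reference
#'
#' Two-sided paired t test over all support voxels. The reference compared
#' with itself (zero difference variance) yields the defined degenerate
#' result \code{NA} rather than an error, mirroring the reference row of the
#' voxel-analysis table.
#'
#' @param tr,rr SUV volumes on one grid.
#' @param support logical array of voxels entering the test (default: all).
#' @return p value (\code{NA} when degenerate).
#' @export
paired_voxel_test <- function(tr, rr, support = NULL) {
  stopifnot_same_grid(tr, rr, "test and reference")
  a <- as.numeric(tr$values); b <- as.numeric(rr$values)
  if (!is.null(support)) { a <- a[support]; b <- b[support] }
  if (length(a) < 2L) stop("need at least 2 support voxels")
  d <- b - a
  if (stats::sd(d) == 0) return(NA_real_)
  stats::t.test(b, a, paired = TRUE, alternative = "two.sided",
                conf.level = 0.95)$p.value
}

#' Voxel-wise exceedance summary against the QSD
#'
#' The proportion of support voxels whose absolute difference exceeds the
#' QSD (strictly: a difference exactly equal to the QSD does not exceed it),
#' plus the maximum and mean voxel difference expressed as a percentage of
#' the reference voxel value. The percentage statistics are computed over
#' support voxels whose reference value exceeds \code{floor_suv}, to avoid
#' division blow-up in zero-activity air and lung.
#'
#' @param diff difference volume from \code{\link{voxel_difference}}
#'   (oriented RR - TR).
#' @param qsd a \code{qsd} object (or a positive number).
#' @param rr the reference volume (denominator of the percentages).
#' @param support logical array; default all voxels.
#' @param floor_suv reference-value floor for the percentage statistics
#'   (default 0.1 SUV).
#' @return list with \code{pct_gt_qsd}, \code{max_diff_pct},
#'   \code{mean_diff_pct}, \code{n_support}, \code{n_exceed}.
#' @export
exceedance_summary <- function(diff, qsd, rr, support = NULL, floor_suv = 0.1) {
  qv <- if (inherits(qsd, "qsd")) qsd$value else as.numeric(qsd)
  if (!is.finite(qv) || qv <= 0) stop("QSD must be positive")
  dv <- as.numeric(diff$values); rv <- as.numeric(rr$values)
  keep <- if (is.null(support)) rep(TRUE, length(dv)) else as.logical(support)
  if (!any(keep)) stop("empty support")
  n_sup <- sum(keep)
  n_exc <- sum(abs(dv[keep]) > qv)
  denom_ok <- keep & rv > floor_suv
  pct <- 100 * dv[denom_ok] / rv[denom_ok]
  list(pct_gt_qsd = 100 * n_exc / n_sup,
       max_diff_pct = if (any(denom_ok)) max(pct) else NA_real_,
       mean_diff_pct = if (any(denom_ok)) mean(pct) else NA_real_,
       n_support = n_sup, n_exceed = n_exc)
}

#' Binary mask of voxels exceeding the QSD
#'
#' \code{mask = 1} where \code{|diff| > QSD} (strict), restricted to the
#' support so the mask count is exactly consistent with the exceedance
#' percentage.
#'
#' @inheritParams exceedance_summary
#' @return \code{image_volume} with 0/1 values (unit \code{LABEL}).
#' @export
significance_mask <- function(diff, qsd, support = NULL) {
  qv <- if (inherits(qsd, "qsd")) qsd$value else as.numeric(qsd)
  if (!is.finite(qv) || qv <= 0) stop("QSD must be positive")
  m <- abs(diff$values) > qv
  if (!is.null(support)) m <- m & array(as.logical(support), dim(diff$values))
  image_volume(array(as.numeric(m), dim(diff$values)), diff$spacing, "LABEL",
               sprintf("QSD significance mask (QSD=%.4g)", qv))
}

#' Full voxel comparison of one test reconstruction against the reference
#'
#' Convenience wrapper producing one voxel-analysis table row: paired t test
#' p value, percent of voxels beyond the QSD, maximum and mean percentage
#' difference, and the significance mask.
#'
#' @inheritParams exceedance_summary
#' @param tr,rr test and reference volumes.
#' @param qsd a \code{qsd} object.
#' @return list of class \code{voxel_comparison}.
#' @export
voxel_comparison <- function(tr, rr, qsd, support = NULL, floor_suv = 0.1) {
  diff <- voxel_difference(tr, rr)
  degenerate <- all(diff$values == 0)
  exc <- exceedance_summary(diff, qsd, rr, support, floor_suv)
  structure(list(
    p = if (degenerate) NA_real_ else paired_voxel_test(tr, rr, support),
    pct_gt_qsd = if (degenerate) NA_real_ else exc$pct_gt_qsd,
    max_diff_pct = if (degenerate) NA_real_ else exc$max_diff_pct,
    mean_diff_pct = if (degenerate) NA_real_ else exc$mean_diff_pct,
    n_support = exc$n_support,
    mask = significance_mask(diff, qsd, support),
    degenerate = degenerate
  ), class = "voxel_comparison")
}

#' Spatial localisation of QSD exceedances
#'
#' Quantifies where the exceeding voxels live: for each labelled region the
#' exceedance rate and its enrichment relative to the global rate
#' (enrichment 1 = no spatial structure). Typical regions: high-activity
#' compartments, attenuation-interface shells, the beam-hardening corridor,
#' and remaining body background.
#'
#' @param mask significance mask (\code{image_volume} or logical array).
#' @param regions named list of logical arrays on the same grid.
#' @param support logical array over which rates are computed (default: the
#'   union of all regions).
#' @return data frame with region, n, n_exceed, rate, enrichment.
#' @export
spatial_localization_score <- function(mask, regions, support = NULL) {
  mv <- if (inherits(mask, "image_volume")) mask$values > 0 else as.logical(mask)
  dmask <- if (inherits(mask, "image_volume")) dim(mask$values) else dim(mask)
  for (nm in names(regions))
    if (!identical(dim(regions[[nm]]), dmask))
      stop(sprintf("region '%s' grid does not match the mask", nm))
  if (is.null(support)) support <- Reduce(`|`, regions)
  g_rate <- sum(mv & support) / sum(support)
  rows <- lapply(names(regions), function(nm) {
    r <- regions[[nm]] & support
    n <- sum(r); ne <- sum(mv & r)
    rate <- if (n > 0) ne / n else NA_real_
    data.frame(region = nm, n = n, n_exceed = ne, rate = rate,
               enrichment = if (g_rate > 0) rate / g_rate else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "global_rate") <- g_rate
  out
}

#' Standard localisation regions for a simulated study
#'
#' Builds the region masks used by \code{\link{spatial_localization_score}}
#' from the phantom labels: high-activity compartments (those with activity
#' above the soft-tissue background: heart, tumour, liver),
#' attenuation-interface shells (voxels within \code{shell_voxels} of a
#' boundary between materials whose CT numbers differ by more than
#' \code{hu_contrast}, taken on both sides of the boundary), the
#' beam-hardening corridor (chords linking the arms to the spine), the
#' remaining body, and the surrounding background air. The masks may overlap — an interface voxel inside the
#' liver belongs to both regions — since each region's exceedance rate is
#' computed independently.
#'
#' @param bundle a \code{study_bundle}.
#' @param shell_voxels interface shell half-thickness in voxels (default 1).
#' @param hu_contrast minimum CT-number contrast (HU) defining an
#'   attenuation interface (default 100).
#' @return named list of logical arrays on the PET grid.
#' @export
localization_regions <- function(bundle, shell_voxels = 1L, hu_contrast = 100) {
  lab <- bundle$labels
  lev <- attr(lab, "levels")
  d <- dim(lab)
  body <- lab > 0L
  spec <- bundle$spec
  high <- array(lab %in% which(lev %in% c("heart", "tumour", "liver")), d)
  # material CT numbers per label (air = -1000)
  hu_of <- c(-1000, vapply(spec$compartments, `[[`, 0, "hu"))
  humap <- array(hu_of[lab + 1L], d)
  shift <- function(arr, dimi, by) {
    idx <- lapply(d, seq_len)
    src <- idx; src[[dimi]] <- pmin(pmax(idx[[dimi]] + by, 1L), d[dimi])
    arr[src[[1]], src[[2]], src[[3]]]
  }
  shell <- array(FALSE, d)
  for (dimi in 1:3) for (by in c(-1L, 1L))
    shell <- shell | abs(shift(humap, dimi, by) - humap) > hu_contrast
  for (i in seq_len(shell_voxels - 1L)) {
    grown <- shell
    for (dimi in 1:3) for (by in c(-1L, 1L)) grown <- grown | shift(shell, dimi, by)
    shell <- grown
  }
  interface <- shell & body
  # beam-hardening corridor: thickened chords from each arm centre to the
  # spine centre, within the torso
  xs <- axis_coords(d[1], spec$spacing[1]); ys <- axis_coords(d[2], spec$spacing[2])
  X <- matrix(rep(xs, times = d[2]), d[1]); Y <- matrix(rep(ys, each = d[1]), d[1])
  corridor2d <- matrix(FALSE, d[1], d[2])
  spine <- spec$compartments$spine$centre
  for (arm_nm in c("arm_l", "arm_r")) {
    a <- spec$compartments[[arm_nm]]$centre
    v <- spine - a; len <- sqrt(sum(v^2)); u <- v / len
    t <- (X - a[1]) * u[1] + (Y - a[2]) * u[2]
    perp <- abs(-(X - a[1]) * u[2] + (Y - a[2]) * u[1])
    corridor2d <- corridor2d | (t >= 0 & t <= len & perp <= 25)
  }
  corridor <- array(rep(corridor2d, d[3]), d) & body
  rest <- body & !high & !interface & !corridor
  list(high_activity = high, interface = interface,
       beam_hardening = corridor, body_rest = rest, background = !body)
}
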