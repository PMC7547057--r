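#' Circular 2-D region of interest on a named slice
#'
#' A voxel belongs to the ROI if its centre lies within \code{radius_mm} of
#' the ROI centre (a tie at exactly the radius counts as inside). The centre
#' may be given in voxel indices (1-based, on the slice) or in world mm.
#'
#' @param name region name (\code{liver}, \code{soft_tissue},
#'   \code{beam_hardening_soft_tissue}, \code{tumour}, or custom).
#' @param slice 1-based slice index.
#' @param centre length-2 centre (x, y).
#' @param radius_mm circle radius in mm.
#' @param centre_units \code{"voxel"} or \code{"mm"} (world coordinates,
#'   origin at the in-plane grid centre).
#' @param statistic statistic of record: \code{"mean"} (default) or
#'   \code{"max"} (used for the lung tumour, as lesional analysis
#'   conventionally uses maximum SUV).
#' @export
roi_spec <- function(name, slice, centre, radius_mm,
                     centre_units = c("voxel", "mm"),
                     statistic = if (name == "tumour") "max" else "mean") {
  centre_units <- match.arg(centre_units)
  statistic <- match.arg(statistic, c("mean", "max"))
  if (radius_mm <= 0) stop("radius must be positive")
  structure(list(name = name, slice = as.integer(slice),
                 centre = as.numeric(centre), radius_mm = radius_mm,
                 centre_units = centre_units, statistic = statistic),
            class = "roi_spec")
}

# logical in-plane mask of an ROI on a volume's grid
roi_mask_slice <- function(volume, roi) {
  d <- dim(volume$values)
  if (roi$slice < 1L || roi$slice > d[3])
    stop(sprintf("ROI '%s' slice %d outside volume", roi$name, roi$slice))
  xs <- axis_coords(d[1], volume$spacing[1])
  ys <- axis_coords(d[2], volume$spacing[2])
  c_mm <- if (roi$centre_units == "mm") roi$centre else
    c(xs[1] + (roi$centre[1] - 1) * volume$spacing[1],
      ys[1] + (roi$centre[2] - 1) * volume$spacing[2])
  m <- outer((xs - c_mm[1])^2, (ys - c_mm[2])^2, `+`) <= roi$radius_mm^2
  if (!any(m)) stop(sprintf("ROI '%s' contains no voxels", roi$name))
  edge <- c_mm + c(roi$radius_mm, roi$radius_mm)
  edge_lo <- c_mm - c(roi$radius_mm, roi$radius_mm)
  if (edge[1] > max(xs) + volume$spacing[1] / 2 || edge[2] > max(ys) + volume$spacing[2] / 2 ||
      edge_lo[1] < min(xs) - volume$spacing[1] / 2 || edge_lo[2] < min(ys) - volume$spacing[2] / 2)
    stop(sprintf("ROI '%s' extends outside the volume", roi$name))
  m
}

#' Extract the SUV values inside an ROI
#' @inheritParams roi_stats
#' @return numeric vector of in-ROI voxel values.
#' @export
roi_values <- function(volume, roi) {
  m <- roi_mask_slice(volume, roi)
  volume$values[, , roi$slice][m]
}

#' ROI SUV statistics
#'
#' Mean, maximum, sample standard deviation (n - 1 denominator) and
#' coefficient of variation of the SUVs inside a circular 2-D ROI.
#'
#' @param volume SUV \code{image_volume}.
#' @param roi a \code{roi_spec}.
#' @return object of class \code{roi_stats}: list with \code{mean},
#'   \code{max}, \code{sd}, \code{cov} (percent; \code{NA} if the mean is
#'   not positive), \code{n}.
#' @export
roi_stats <- function(volume, roi) {
  expect_unit(volume, "SUV")
  v <- roi_values(volume, roi)
  if (length(v) < 2L)
    stop(sprintf("ROI '%s' contains fewer than 2 voxels", roi$name))
  m <- mean(v); s <- stats::sd(v)
  structure(list(name = roi$name, mean = m, max = max(v), sd = s,
                 cov = if (m > 0) suv_cov(s, m) else NA_real_,
                 n = length(v), statistic = roi$statistic),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("ROI %s: mean %.3f, max %.3f, SD %.4f, COV %.2f%% (n=%d)\n",
              x$name, x$mean, x$max, x$sd, x$cov, x$n))
  invisible(x)
}

#' SUV coefficient of variation
#'
#' \code{COV = SD / mean * 100}, the conventional ROI noise proxy.
#'
#' @param sd,mean SUV standard deviation and mean; \code{mean} must be
#'   positive.
#' @return COV in percent.
#' @export
suv_cov <- function(sd, mean) {
  if (any(!is.finite(mean)) || any(mean <= 0))
    stop("COV requires a positive mean")
  sd / mean * 100
}

#' COV difference between matched FBP and IR reconstructions
#'
#' \code{delta_cov = COV_FBP - COV_IR} for the same ROI in the two
#' reconstructions of one CT acquisition: positive means the FBP-based
#' reconstruction is noisier.
#'
#' @param cov_fbp,cov_ir COV (percent) of the matched pair.
#' @export
delta_cov <- function(cov_fbp, cov_ir) cov_fbp - cov_ir

#' Paired comparison of matched FBP/IR COVs
#'
#' Two-sided paired t test of the COVs of one ROI across all matched
#' protocol pairs, together with the summary row (minimum, median, mean,
#' maximum of the COV differences). A pair set with zero difference
#' variance yields a degenerate result (\code{p = NA},
#' \code{degenerate = TRUE}) rather than an error, mirroring the reference-
#' versus-itself case.
#'
#' @param fbp_covs,ir_covs equal-length numeric vectors of matched COVs.
#' @return list with \code{delta} (the pairwise differences), \code{min},
#'   \code{median}, \code{mean}, \code{max}, \code{sd}, \code{p},
#'   \code{degenerate}.
#' @export
paired_cov_test <- function(fbp_covs, ir_covs) {
  if (length(fbp_covs) != length(ir_covs)) stop("unequal pair lists")
  if (length(fbp_covs) < 2L) stop("need at least 2 matched pairs")
  d <- delta_cov(fbp_covs, ir_covs)
  degenerate <- stats::sd(d) == 0
  p <- if (degenerate) NA_real_ else
    stats::t.test(fbp_covs, ir_covs, paired = TRUE,
                  alternative = "two.sided", conf.level = 0.95)$p.value
  list(delta = d, min = min(d), median = stats::median(d), mean = mean(d),
       max = max(d), sd = stats::sd(d), p = p, degenerate = degenerate)
}

#' Default ROI set for the simulated phantom
#'
#' Placements mirror the physical study: liver, anterior soft tissue, soft
#' tissue in the beam-hardening corridor between an arm and the spine, and
#' the lung tumour (statistic of record: maximum SUV). Centres are specified
#' in mm so the set is resolution-independent; slices are chosen from the
#' phantom geometry.
#'
#' @param spec a \code{phantom_spec}.
#' @return named list of \code{roi_spec}.
#' @export
default_rois <- function(spec) {
  sp <- spec$spacing; nz <- spec$shape[3]
  zc <- nz * sp[3] / 2
  slice_at <- function(z_mm) max(1L, min(nz, as.integer(ceiling(z_mm / sp[3]))))
  liver_z <- zc - 35; tum_z <- zc + 22
  list(
    liver = roi_spec("liver", slice_at(liver_z), c(60, 5), 15, "mm"),
    soft_tissue = roi_spec("soft_tissue", slice_at(liver_z), c(-30, -95), 10, "mm"),
    beam_hardening_soft_tissue =
      roi_spec("beam_hardening_soft_tissue", slice_at(liver_z), c(-105, 55), 8, "mm"),
    tumour = roi_spec("tumour", slice_at(tum_z), c(78, -18), 8.5, "mm")
  )
}

#' Read / write ROI specifications as YAML
#'
#' @param path YAML file; a top-level list of ROIs with fields name, slice,
#'   centre, radius_mm, centre_units, statistic.
#' @export
read_roi_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  rois <- lapply(raw, function(r)
    roi_spec(r$name, r$slice, unlist(r$centre), r$radius_mm,
             centre_units = if (is.null(r$centre_units)) "voxel" else r$centre_units,
             statistic = if (is.null(r$statistic))
               (if (r$name == "tumour") "max" else "mean") else r$statistic))
  stats::setNames(rois, vapply(rois, `[[`, "", "name"))
}

#' @rdname read_roi_yaml
#' @param rois named list of \code{roi_spec}.
#' @export
write_roi_yaml <- function(rois, path) {
  yaml::write_yaml(lapply(unname(rois), function(r)
    list(name = r$name, slice = r$slice, centre = as.list(r$centre),
         radius_mm = r$radius_mm, centre_units = r$centre_units,
         statistic = r$statistic)), path)
  invisible(path)
}
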