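#' Configuration of a full simulated study run
#'
#' Bundles everything \code{\link{run_study}} needs. Defaults reproduce the
#' study design: the default phantom, the 48-protocol grid, liver-ROI QSD,
#' body support mask.
#'
#' @param out_dir output directory (created if needed); \code{NULL} keeps
#'   everything in memory.
#' @param seed master seed.
#' @param spec a \code{phantom_spec}.
#' @param grid protocol list.
#' @param rois named list of \code{roi_spec} (default placements from the
#'   phantom geometry).
#' @param qsd_roi name of the ROI defining the QSD (default liver).
#' @param support \code{"body"} (default; exclude surrounding air, which is
#'   degenerate in a simulator without scatter) or \code{"all"} (every voxel
#'   in the volume).
#' @param floor_suv reference floor for percentage differences.
#' @param nangles,iterations,subsets PET simulation/reconstruction settings.
#' @param ct_options see \code{\link{ct_sim_options}}.
#' @param write_volumes also write every reconstruction and mask as NIfTI.
#' @param write_overlays write orthogonal-slice overlay PNGs for the lowest
#'   and highest dose comparisons.
#' @export
run_config <- function(out_dir = NULL, seed = 1L, spec = phantom_spec(),
                       grid = default_protocol_grid(), rois = default_rois(spec),
                       qsd_roi = "liver", support = c("body", "all"),
                       floor_suv = 0.1, nangles = 72L, iterations = 3L,
                       subsets = 3L, ct_options = ct_sim_options(),
                       write_volumes = FALSE, write_overlays = FALSE) {
  support <- match.arg(support)
  if (!qsd_roi %in% names(rois))
    stop(sprintf("config field 'qsd_roi': ROI '%s' not among the ROI set", qsd_roi))
  n_ref <- sum(vapply(grid, function(p) isTRUE(p$reference), logical(1)))
  if (n_ref != 1L)
    stop("config field 'grid': exactly one protocol must be flagged reference")
  structure(list(out_dir = out_dir, seed = as.integer(seed), spec = spec,
                 grid = grid, rois = rois, qsd_roi = qsd_roi, support = support,
                 floor_suv = floor_suv, nangles = nangles,
                 iterations = iterations, subsets = subsets,
                 ct_options = ct_options, write_volumes = write_volumes,
                 write_overlays = write_overlays),
            class = "run_config")
}

protocol_df_row <- function(prot, ctdi) {
  data.frame(mAs = prot$mAs, kVp = prot$kVp, pitch = prot$pitch,
             algorithm = prot$algorithm, ctdi_mGy = ctdi,
             reference = isTRUE(prot$reference))
}

#' ROI statistics table for every reconstruction in a bundle
#'
#' @param bundle a \code{study_bundle}.
#' @param rois named list of \code{roi_spec}.
#' @return data frame, one row per reconstruction x ROI, with the protocol,
#'   CTDI, ROI statistics and the statistic of record.
#' @export
roi_table <- function(bundle, rois) {
  rows <- list()
  for (e in bundle$entries) {
    for (roi in rois) {
      st <- roi_stats(e$volume, roi)
      rows[[length(rows) + 1L]] <- cbind(
        protocol_df_row(e$protocol, e$ctdi),
        data.frame(region = roi$name, statistic = roi$statistic,
                   mean = st$mean, max = st$max, sd = st$sd, cov = st$cov,
                   value_of_record = if (roi$statistic == "max") st$max else st$mean,
                   n_voxels = st$n))
    }
  }
  do.call(rbind, rows)
}

#' Matched FBP/IR COV comparison table
#'
#' For every mean-statistic region, pairs each FBP reconstruction with the
#' IR reconstruction of the same acquisition and summarises the COV
#' differences (minimum, median, mean, maximum) with the paired t test.
#'
#' @param rt output of \code{\link{roi_table}}.
#' @return data frame, one row per region.
#' @export
delta_cov_table <- function(rt) {
  regions <- unique(rt$region[rt$statistic == "mean"])
  rows <- lapply(regions, function(rg) {
    sub <- rt[rt$region == rg, ]
    key <- interaction(sub$mAs, sub$kVp, sub$pitch, drop = TRUE)
    fbp <- sub[sub$algorithm == "FBP", ]; ir <- sub[sub$algorithm == "IR", ]
    fkey <- interaction(fbp$mAs, fbp$kVp, fbp$pitch, drop = TRUE)
    ikey <- interaction(ir$mAs, ir$kVp, ir$pitch, drop = TRUE)
    m <- match(fkey, ikey)
    ok <- !is.na(m)
    res <- paired_cov_test(fbp$cov[ok], ir$cov[m[ok]])
    data.frame(region = rg, n_pairs = sum(ok), min = res$min,
               median = res$median, mean = res$mean, max = res$max,
               p = res$p)
  })
  do.call(rbind, rows)
}

#' Voxel-analysis table for every test reconstruction
#'
#' One row per reconstruction in the bundle: protocol, CTDI, paired t test
#' p value, percent of voxels beyond the QSD, and maximum / mean percentage
#' voxel difference. The reference compared with itself gives the degenerate
#' all-NA row. Masks are returned alongside.
#'
#' @param bundle a \code{study_bundle}.
#' @param qsd a \code{qsd} object (from \code{\link{compute_qsd}}).
#' @param support logical array or \code{NULL} (all voxels).
#' @param floor_suv see \code{\link{exceedance_summary}}.
#' @return list with \code{table} (data frame) and \code{masks} (list of
#'   \code{image_volume}).
#' @export
voxel_table <- function(bundle, qsd, support = NULL, floor_suv = 0.1) {
  rr <- bundle$reference
  rows <- list(); masks <- list()
  for (i in seq_along(bundle$entries)) {
    e <- bundle$entries[[i]]
    vc <- voxel_comparison(e$volume, rr, qsd, support, floor_suv)
    rows[[i]] <- cbind(protocol_df_row(e$protocol, e$ctdi),
                       data.frame(pct_gt_qsd = vc$pct_gt_qsd,
                                  max_diff_pct = vc$max_diff_pct,
                                  mean_diff_pct = vc$mean_diff_pct,
                                  p = vc$p, n_support = vc$n_support))
    masks[[i]] <- vc$mask
  }
  list(table = do.call(rbind, rows), masks = masks)
}

#' Run the full simulated study and report
#'
#' Orchestrates generate, analyse, report: simulates the study bundle,
#' computes the acquisition/dose table, the ROI statistics and matched-COV
#' tables, the QSD, the voxel-analysis table with significance masks, the
#' localisation scores, and (optionally) writes everything under
#' \code{config$out_dir} — CSV tables, plot data (statistic versus CTDI per
#' algorithm), NIfTI masks and a JSON manifest recording version and seeds.
#' Rerunning with an identical config is bit-identical.
#'
#' @param config a \code{run_config}.
#' @return list of class \code{study_report}: \code{bundle}, \code{qsd},
#'   tables \code{acquisitions}, \code{roi}, \code{delta_cov}, \code{voxel},
#'   \code{localization}, \code{masks}, \code{manifest}.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  bundle <- generate_study(config$spec, config$grid, config$seed,
                           config$nangles, config$iterations, config$subsets,
                           config$ct_options)
  acq <- unique(do.call(rbind, lapply(bundle$entries, function(e)
    data.frame(mAs = e$protocol$mAs, kVp = e$protocol$kVp,
               pitch = e$protocol$pitch, ctdi_mGy = e$ctdi))))
  rownames(acq) <- NULL

  rt <- roi_table(bundle, config$rois)
  dct <- if (sum(rt$algorithm == "FBP") && sum(rt$algorithm == "IR"))
    delta_cov_table(rt) else NULL
  qsd <- compute_qsd(bundle$reference, config$rois[[config$qsd_roi]])
  support <- if (config$support == "body") bundle$labels > 0L else NULL
  vt <- voxel_table(bundle, qsd, support, config$floor_suv)

  regions <- localization_regions(bundle)
  low <- which.min(vapply(bundle$entries, `[[`, 0, "ctdi") +
                     ifelse(vapply(bundle$entries, function(e) e$protocol$algorithm, "") == "IR", 0, 1e-3))
  loc <- spatial_localization_score(vt$masks[[low]], regions)

  manifest <- list(package = "petacdose",
                   version = as.character(utils::packageVersion("petacdose")),
                   seed = config$seed, qsd = qsd$value,
                   qsd_roi = config$qsd_roi, support = config$support,
                   floor_suv = config$floor_suv,
                   n_reconstructions = length(bundle$entries))
  report <- structure(list(bundle = bundle, qsd = qsd, acquisitions = acq,
                           roi = rt, delta_cov = dct, voxel = vt$table,
                           localization = loc, masks = vt$masks,
                           manifest = manifest),
                      class = "study_report")
  if (!is.null(config$out_dir)) write_report(report, config)
  report
}

write_report <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  utils::write.csv(report$acquisitions, out("table1_acquisitions.csv"), row.names = FALSE)
  if (!is.null(report$delta_cov))
    utils::write.csv(report$delta_cov, out("table2_delta_cov.csv"), row.names = FALSE)
  utils::write.csv(report$voxel, out("table3_voxel_analysis.csv"), row.names = FALSE)
  utils::write.csv(report$roi, out("roi_statistics.csv"), row.names = FALSE)
  # plot data: statistic of record / COV / exceedance versus CTDI per algorithm
  rt <- report$roi
  utils::write.csv(rt[, c("region", "statistic", "mAs", "kVp", "pitch",
                          "algorithm", "ctdi_mGy", "value_of_record", "cov")],
                   out("fig_suv_vs_ctdi.csv"), row.names = FALSE)
  utils::write.csv(report$voxel[, c("mAs", "kVp", "pitch", "algorithm",
                                    "ctdi_mGy", "pct_gt_qsd")],
                   out("fig_exceedance_vs_ctdi.csv"), row.names = FALSE)
  utils::write.csv(report$localization, out("localization.csv"), row.names = FALSE)
  manifest <- c(report$manifest, list(files = list.files(config$out_dir)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (config$write_volumes) {
    vol_dir <- out("volumes"); dir.create(vol_dir, showWarnings = FALSE)
    for (i in seq_along(report$bundle$entries)) {
      e <- report$bundle$entries[[i]]
      stem <- sprintf("pet_%03.0fmAs_%03.0fkVp_%0.3f_%s", e$protocol$mAs,
                      e$protocol$kVp, e$protocol$pitch, e$protocol$algorithm)
      write_volume(e$volume, file.path(vol_dir, paste0(stem, ".nii.gz")),
                   extra = list(protocol = unclass(e$protocol), ctdi_mGy = e$ctdi))
      write_volume(report$masks[[i]], file.path(vol_dir, paste0(stem, "_mask.nii.gz")))
    }
  }
  if (config$write_overlays) {
    ctdis <- vapply(report$bundle$entries, `[[`, 0, "ctdi")
    for (i in c(which.min(ctdis), which.max(ctdis))) {
      e <- report$bundle$entries[[i]]
      write_overlay_png(e$volume, report$masks[[i]],
                        out(sprintf("overlay_%02d_%s.png", i, e$protocol$algorithm)))
    }
  }
  invisible(config$out_dir)
}

#' Orthogonal-slice overlay rendering
#'
#' Greyscale axial, coronal and sagittal mid-slices of a volume with the
#' significance mask overlaid in red.
#'
#' @param vol SUV \code{image_volume}.
#' @param mask significance mask on the same grid.
#' @param path output PNG path.
#' @param slices length-3 integer slice index per axis (x, y, z); default
#'   mid-volume.
#' @export
write_overlay_png <- function(vol, mask, path, slices = NULL) {
  d <- dim(vol$values)
  if (is.null(slices)) slices <- pmax(1L, d %/% 2L)
  mv <- if (inherits(mask, "image_volume")) mask$values > 0 else as.logical(mask)
  grDevices::png(path, width = 900, height = 320)
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  panes <- list(axial = list(img = vol$values[, , slices[3]], m = mv[, , slices[3]]),
                coronal = list(img = vol$values[, slices[2], ], m = mv[, slices[2], ]),
                sagittal = list(img = vol$values[slices[1], , ], m = mv[slices[1], , ]))
  for (nm in names(panes)) {
    p <- panes[[nm]]
    img <- p$img / max(vol$values, 1e-9)
    graphics::image(img, col = grDevices::gray.colors(128, 0, 1), zlim = c(0, 1),
                    axes = FALSE, main = nm, useRaster = TRUE)
    if (any(p$m)) {
      red <- array(NA_real_, dim(p$m)); red[p$m] <- 1
      graphics::image(red, col = grDevices::rgb(1, 0, 0, 0.8), add = TRUE,
                      useRaster = TRUE)
    }
  }
  invisible(path)
}

#' Analyse user-supplied co-registered volumes
#'
#' Applies the ROI and voxel analyses to real (or external) reconstructions:
#' no simulation is involved. All volumes must be NIfTI files on identical
#' grids; a grid mismatch is rejected naming the offending file.
#'
#' @param rr_path NIfTI path of the reference reconstruction.
#' @param tr_paths character vector of test reconstruction paths.
#' @param rois named list of \code{roi_spec}, or a YAML path.
#' @param qsd_roi ROI name defining the QSD.
#' @param support optional logical array (default: all voxels, since no
#'   phantom geometry is available for a body mask).
#' @param floor_suv percentage-difference floor.
#' @param out_dir optional output directory for CSV tables and masks.
#' @return list with \code{qsd}, \code{roi} table, \code{voxel} table,
#'   \code{masks}.
#' @export
analyze_external <- function(rr_path, tr_paths, rois, qsd_roi = "liver",
                             support = NULL, floor_suv = 0.1, out_dir = NULL) {
  if (!file.exists(rr_path)) stop(sprintf("reference volume not found: %s", rr_path))
  missing <- tr_paths[!file.exists(tr_paths)]
  if (length(missing)) stop(sprintf("test volume not found: %s", missing[1]))
  if (is.character(rois)) rois <- read_roi_yaml(rois)
  if (!qsd_roi %in% names(rois)) stop(sprintf("no ROI named '%s'", qsd_roi))
  rr <- read_volume(rr_path, unit = "SUV")
  trs <- lapply(tr_paths, read_volume, unit = "SUV")
  for (i in seq_along(trs)) {
    ok <- tryCatch(stopifnot_same_grid(rr, trs[[i]]), error = function(e) FALSE)
    if (!isTRUE(ok))
      stop(sprintf("volume grid mismatch: %s does not match the reference grid",
                   tr_paths[i]))
  }
  qsd <- compute_qsd(rr, rois[[qsd_roi]])
  roi_rows <- list()
  vols <- c(list(reference = rr), stats::setNames(trs, basename(tr_paths)))
  for (nm in names(vols)) for (roi in rois) {
    st <- roi_stats(vols[[nm]], roi)
    roi_rows[[length(roi_rows) + 1L]] <-
      data.frame(volume = nm, region = roi$name, mean = st$mean, max = st$max,
                 sd = st$sd, cov = st$cov, n_voxels = st$n)
  }
  vox_rows <- list(); masks <- list()
  for (i in seq_along(trs)) {
    vc <- voxel_comparison(trs[[i]], rr, qsd, support, floor_suv)
    vox_rows[[i]] <- data.frame(volume = basename(tr_paths[i]),
                                pct_gt_qsd = vc$pct_gt_qsd,
                                max_diff_pct = vc$max_diff_pct,
                                mean_diff_pct = vc$mean_diff_pct, p = vc$p)
    masks[[i]] <- vc$mask
  }
  out <- list(qsd = qsd, roi = do.call(rbind, roi_rows),
              voxel = do.call(rbind, vox_rows), masks = masks)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$roi, file.path(out_dir, "roi_statistics.csv"), row.names = FALSE)
    utils::write.csv(out$voxel, file.path(out_dir, "voxel_analysis.csv"), row.names = FALSE)
    for (i in seq_along(masks))
      write_volume(masks[[i]], file.path(out_dir, sprintf("mask_%02d.nii.gz", i)))
    jsonlite::write_json(list(package = "petacdose",
                              version = as.character(utils::packageVersion("petacdose")),
                              qsd = qsd$value, reference = basename(rr_path)),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
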