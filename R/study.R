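#' Generate a complete simulated study
#'
#' Runs the whole simulation chain: rasterize the phantom, simulate the
#' single PET emission acquisition against the true attenuation map, then
#' for every CT protocol in the grid simulate the CT, convert it to a
#' 511-keV attenuation map (after averaging the CT grid down to the PET
#' grid) and reconstruct the shared emission data with that AC map. The
#' reconstruction using the \emph{true} attenuation map calibrates the
#' global counts-to-SUV scale (its whole-phantom mean is matched to the
#' ground truth), and the same scale is applied to every reconstruction.
#'
#' All randomness derives from the single master seed: stage seeds are drawn
#' by \code{sample.int} under the master seed in a fixed order (one for the
#' PET acquisition, then one per unique CT acquisition in grid order). The
#' two reconstructions (FBP/IR) of one CT acquisition share that
#' acquisition's seed, as two reconstructions of one physical scan share
#' their raw data.
#'
#' @param spec a \code{phantom_spec}.
#' @param grid list of \code{ct_protocol} with exactly one reference.
#' @param seed master seed.
#' @param nangles projection angles for the PET simulation/reconstruction.
#' @param iterations,subsets OSEM settings (default 3 and 3).
#' @param ct_options see \code{\link{ct_sim_options}}.
#' @param calibration CTDI calibration table.
#' @return object of class \code{study_bundle}: \code{reference} (SUV
#'   volume), \code{entries} (list of protocol/ctdi/volume records, one
#'   flagged reference), \code{ground_truth}, \code{labels}, \code{spec},
#'   \code{seed}.
#' @export
generate_study <- function(spec, grid = default_protocol_grid(), seed = 1L,
                           nangles = 72L, iterations = 3L, subsets = 3L,
                           ct_options = ct_sim_options(),
                           calibration = ctdi_calibration()) {
  if (length(grid) == 0L) stop("empty protocol list")
  n_ref <- sum(vapply(grid, function(p) isTRUE(p$reference), logical(1)))
  if (n_ref != 1L) stop("exactly one protocol must be flagged as reference")

  acq_key <- vapply(grid, function(p) sprintf("%g_%g_%g", p$mAs, p$kVp, p$pitch), "")
  acqs <- unique(acq_key)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max, 1L + length(acqs))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  seed_pet <- stage_seeds[1]
  seed_acq <- stats::setNames(stage_seeds[-1], acqs)

  phantom <- build_phantom(spec)
  ct_factor <- spec$ct_supersample
  att_pet <- downsample_xy(phantom$attenuation, ct_factor)
  mu_true <- hu_to_mu(att_pet)
  sino <- simulate_pet(phantom$activity, mu_true, spec$counts_target,
                       seed_pet, nangles)

  recon_true <- reconstruct_osem(sino, mu_true, iterations, subsets,
                                 label = "true-mu calibration reconstruction")
  support <- phantom$labels > 0L
  scale <- mean(phantom$activity$values[support]) / mean(recon_true$values[support])

  entries <- vector("list", length(grid))
  reference <- NULL
  for (i in seq_along(grid)) {
    prot <- grid[[i]]
    ct <- simulate_ct(phantom$attenuation, prot, seed_acq[[acq_key[i]]],
                      ct_options, calibration)
    mu <- hu_to_mu(downsample_xy(ct, ct_factor))
    vol <- reconstruct_osem(sino, mu, iterations, subsets, scale = scale,
                            label = sprintf("PET with AC from %s", format(prot)))
    entries[[i]] <- list(protocol = prot,
                         ctdi = ctdi_model(prot, calibration, extrapolate = TRUE),
                         volume = vol, reference = isTRUE(prot$reference))
    if (isTRUE(prot$reference)) reference <- vol
  }
  structure(list(reference = reference, entries = entries,
                 ground_truth = phantom$activity,
                 true_mu_recon = image_volume(recon_true$values * scale,
                                              recon_true$spacing, "SUV",
                                              recon_true$label),
                 labels = phantom$labels, spec = spec, seed = seed,
                 nangles = nangles, iterations = iterations, subsets = subsets),
            class = "study_bundle")
}

#' Write / read a study bundle as a directory of NIfTI volumes
#'
#' Every reconstruction is written as \code{pet_###.nii.gz} with its
#' protocol, CTDI and reference flag in the JSON sidecar; the ground-truth
#' activity and compartment labels are written alongside, and
#' \code{study.json} records the phantom-specification arguments and the
#' master seed. \code{read_study} reconstructs a \code{study_bundle} from
#' such a directory (assuming the default compartment geometry for the
#' stored grid).
#'
#' @param bundle a \code{study_bundle}.
#' @param dir output directory.
#' @return \code{dir} (write) / a \code{study_bundle} (read), the read-back
#'   bundle carrying no \code{true_mu_recon}.
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(bundle$entries)) {
    e <- bundle$entries[[i]]
    write_volume(e$volume, file.path(dir, sprintf("pet_%03d.nii.gz", i)),
                 extra = list(protocol = unclass(e$protocol), ctdi_mGy = e$ctdi,
                              reference = e$reference))
  }
  write_volume(bundle$ground_truth, file.path(dir, "ground_truth.nii.gz"))
  lab <- image_volume(array(as.numeric(bundle$labels), dim(bundle$labels)),
                      bundle$spec$spacing, "LABEL", "compartment labels")
  write_volume(lab, file.path(dir, "labels.nii.gz"),
               extra = list(levels = attr(bundle$labels, "levels")))
  spec <- bundle$spec
  jsonlite::write_json(list(shape = spec$shape, spacing = spec$spacing,
                            ct_supersample = spec$ct_supersample,
                            tumour_diameter_mm = spec$tumour_diameter_mm,
                            counts_target = spec$counts_target,
                            seed = bundle$seed,
                            n_entries = length(bundle$entries)),
                       file.path(dir, "study.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "study.json"), simplifyVector = TRUE)
  spec <- phantom_spec(shape = meta$shape, spacing = meta$spacing,
                       ct_supersample = meta$ct_supersample,
                       tumour_diameter_mm = meta$tumour_diameter_mm,
                       counts_target = meta$counts_target)
  entries <- vector("list", meta$n_entries)
  reference <- NULL
  for (i in seq_len(meta$n_entries)) {
    path <- file.path(dir, sprintf("pet_%03d.nii.gz", i))
    vol <- read_volume(path)
    side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    prot <- ct_protocol(side$protocol$mAs, side$protocol$kVp, side$protocol$pitch,
                        side$protocol$algorithm, side$protocol$ir_level,
                        isTRUE(side$protocol$reference))
    entries[[i]] <- list(protocol = prot, ctdi = side$ctdi_mGy, volume = vol,
                         reference = isTRUE(side$reference))
    if (isTRUE(side$reference)) reference <- vol
  }
  gt <- read_volume(file.path(dir, "ground_truth.nii.gz"))
  labv <- read_volume(file.path(dir, "labels.nii.gz"))
  lab_side <- jsonlite::read_json(file.path(dir, "labels.nii.gz.json"),
                                  simplifyVector = TRUE)
  labels <- array(as.integer(round(labv$values)), dim(labv$values))
  attr(labels, "levels") <- lab_side$levels
  structure(list(reference = reference, entries = entries, ground_truth = gt,
                 labels = labels, spec = spec, seed = meta$seed),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d reconstructions, seed %d\n",
              length(x$entries), x$seed))
  cat(sprintf("  reference: %s\n",
              format(x$entries[[which(vapply(x$entries, `[[`, logical(1), "reference"))[1]]]$protocol)))
  invisible(x)
}
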