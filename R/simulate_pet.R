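#' Simulate a PET emission acquisition
#'
#' Per-slice parallel-beam forward projection of the activity map, with each
#' line of response attenuated by \code{exp(-integral of mu)} along the same
#' ray through the true attenuation map, scaled so that the expected true
#' coincidence total per slice averages \code{counts_target}, then Poisson
#' sampled. The sinogram is generated once per study and shared by all
#' reconstructions, mirroring a single physical emission acquisition
#' reconstructed repeatedly with different AC maps.
#'
#' @param activity SUV \code{image_volume} on the PET grid (square slices).
#' @param mu_true MU_511 \code{image_volume} on the same grid (per cm).
#' @param counts_target expected true counts per slice (mean over slices).
#' @param seed integer RNG seed for the Poisson draw.
#' @param nangles number of projection angles over [0, pi).
#' @param poisson if \code{FALSE}, return the noise-free expected sinogram
#'   as the counts (useful for convergence studies).
#' @return object of class \code{pet_sinogram}: counts and expectation arrays
#'   (nbins x nangles x nslices), geometry, and the activity-to-counts scale.
#' @export
simulate_pet <- function(activity, mu_true, counts_target = 2e5, seed = 1L,
                         nangles = 72L, poisson = TRUE) {
  expect_unit(activity, "SUV"); expect_unit(mu_true, "MU_511")
  stopifnot_same_grid(activity, mu_true, "activity and attenuation")
  d <- dim(activity$values)
  if (d[1] != d[2]) stop("square in-plane grid required")
  proj <- get_projector(d[1], nangles, activity$spacing[1])
  nz <- d[3]
  expected <- array(0, c(proj$nbins, nangles, nz))
  for (k in seq_len(nz)) {
    p <- forward_project_slice(proj, activity$values[, , k])
    l <- forward_project_slice(proj, mu_true$values[, , k] / 10)  # mu per mm
    expected[, , k] <- exp(-l) * p
  }
  tot <- sum(expected)
  if (tot > 0) {
    scale <- counts_target * nz / tot
    expected <- expected * scale
  } else scale <- 1
  counts <- if (poisson) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    cnt <- array(stats::rpois(length(expected), expected), dim(expected))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    cnt
  } else expected
  structure(list(counts = counts, expected = expected, scale = scale,
                 nangles = nangles, nbins = proj$nbins, n = d[1], nz = nz,
                 spacing = activity$spacing, seed = seed, poisson = poisson),
            class = "pet_sinogram")
}

.osem_cache <- new.env(parent = emptyenv())

get_osem_ops <- function(proj, subsets) {
  key <- sprintf("o_%d_%d_%.6f_%d", proj$n, proj$nangles, proj$spacing, subsets)
  if (!is.null(.osem_cache[[key]])) return(.osem_cache[[key]])
  rows <- subset_rows(proj, subsets)
  ops <- lapply(rows, function(r)
    list(rows = r, A = proj$A[r, , drop = FALSE],
         At = Matrix::t(proj$A[r, , drop = FALSE])))
  .osem_cache[[key]] <- ops
  ops
}

#' OSEM reconstruction of a simulated PET acquisition
#'
#' Standard attenuation-weighted ordered-subset expectation-maximisation with
#' interleaved angle subsets. The attenuation factors entering the system
#' model come from \code{mu_for_ac}, which may differ from the attenuation
#' used to generate the data — that difference is exactly what propagates a
#' biased or noisy AC map into the reconstructed SUVs. Nonnegativity is
#' preserved at every multiplicative update and an all-zero sinogram yields
#' an all-zero image.
#'
#' @param sinogram a \code{pet_sinogram}.
#' @param mu_for_ac MU_511 \code{image_volume} on the reconstruction grid.
#' @param iterations full OSEM iterations (default 3).
#' @param subsets number of angle subsets (default 3); must divide the
#'   number of projection angles.
#' @param scale multiplicative calibration applied to the output so that it
#'   is in SUV units (see \code{\link{generate_study}}, which calibrates it
#'   from the true-attenuation reconstruction).
#' @param label provenance label of the output volume.
#' @return SUV \code{image_volume}.
#' @export
reconstruct_osem <- function(sinogram, mu_for_ac, iterations = 3L, subsets = 3L,
                             scale = 1, label = "OSEM reconstruction") {
  stopifnot(inherits(sinogram, "pet_sinogram"))
  expect_unit(mu_for_ac, "MU_511")
  d <- dim(mu_for_ac$values)
  if (!identical(d, c(sinogram$n, sinogram$n, sinogram$nz)) ||
      !isTRUE(all.equal(mu_for_ac$spacing, sinogram$spacing, tolerance = 1e-9)))
    stop("AC map grid does not match the sinogram geometry")
  if (sinogram$nangles %% subsets != 0L)
    stop("subsets must divide the number of projection angles")
  proj <- get_projector(sinogram$n, sinogram$nangles, sinogram$spacing[1])
  ops <- get_osem_ops(proj, subsets)
  nvox <- sinogram$n^2
  out <- array(0, d)
  for (k in seq_len(sinogram$nz)) {
    y <- as.numeric(sinogram$counts[, , k])
    if (all(y == 0)) next
    att <- exp(-as.numeric(proj$A %*% as.numeric(mu_for_ac$values[, , k] / 10)))
    x <- rep(1, nvox)
    for (it in seq_len(iterations)) {
      for (s in seq_len(subsets)) {
        op <- ops[[s]]
        a_s <- att[op$rows]
        sens <- as.numeric(op$At %*% a_s)
        yhat <- a_s * as.numeric(op$A %*% x)
        ratio <- ifelse(yhat > 0, y[op$rows] / yhat, 0)
        upd <- as.numeric(op$At %*% (a_s * ratio))
        x <- ifelse(sens > 0, x * upd / sens, 0)
      }
    }
    out[, , k] <- x
  }
  image_volume(out * scale, sinogram$spacing, "SUV", label)
}
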