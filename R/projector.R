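# Parallel-beam slice projector.
#
# Pixel-driven linear-interpolation projector: for each view angle the voxel
# centres are projected onto the detector axis and each voxel's value is
# split linearly between the two nearest detector bins. Entries are scaled by
# the voxel size so that A %*% x approximates the line integral (in mm) of
# the slice x. The detector has n bins of width equal to the voxel size,
# centred on the field of view; view angles cover [0, pi).
#
# Matrices are cached per (n, nangles, spacing) since they are shared by the
# CT artifact model, the PET forward model and every OSEM reconstruction.

.projector_cache <- new.env(parent = emptyenv())

#' Build (or fetch) a parallel-beam projector for an n x n slice
#'
#' @param n slice dimension (square slices).
#' @param nangles number of view angles in [0, pi).
#' @param spacing in-plane voxel size, mm.
#' @return list with the sparse system matrix \code{A}
#'   (\code{nangles*n} rays by \code{n^2} voxels), its transpose \code{At},
#'   the angle vector and geometry constants.
#' @export
get_projector <- function(n, nangles = 72L, spacing = 1) {
  key <- sprintf("p_%d_%d_%.6f", n, nangles, spacing)
  if (!is.null(.projector_cache[[key]])) return(.projector_cache[[key]])
  angles <- (seq_len(nangles) - 1L) * pi / nangles
  xs <- axis_coords(n, spacing)
  X <- rep(xs, times = n); Y <- rep(xs, each = n)
  nb <- n
  ii <- jj <- xx <- vector("list", nangles)
  for (k in seq_len(nangles)) {
    s <- X * cos(angles[k]) + Y * sin(angles[k])
    u <- s / spacing + (nb + 1) / 2      # continuous bin coordinate
    i0 <- floor(u)
    fr <- u - i0
    vox <- seq_len(n * n)
    keep0 <- i0 >= 1 & i0 <= nb
    keep1 <- i0 + 1 >= 1 & i0 + 1 <= nb
    row0 <- (k - 1L) * nb + i0[keep0]
    row1 <- (k - 1L) * nb + i0[keep1] + 1
    ii[[k]] <- c(row0, row1)
    jj[[k]] <- c(vox[keep0], vox[keep1])
    xx[[k]] <- c((1 - fr[keep0]), fr[keep1]) * spacing
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nangles * nb, n * n))
  proj <- list(A = A, At = Matrix::t(A), angles = angles, n = n,
               nbins = nb, nangles = nangles, spacing = spacing)
  .projector_cache[[key]] <- proj
  proj
}

# forward projection of one slice (vectorised over the full angle set);
# returns matrix nbins x nangles
forward_project_slice <- function(proj, slice) {
  y <- as.numeric(proj$A %*% as.numeric(slice))
  matrix(y, proj$nbins, proj$nangles)
}

back_project_slice <- function(proj, sino) {
  x <- as.numeric(proj$At %*% as.numeric(sino))
  matrix(x, proj$n, proj$n)
}

# interleaved angle subsets for OSEM; returns list of ray-row index vectors
subset_rows <- function(proj, subsets) {
  lapply(seq_len(subsets), function(s) {
    ang <- seq(s, proj$nangles, by = subsets)
    as.vector(outer(seq_len(proj$nbins), (ang - 1L) * proj$nbins, `+`))
  })
}
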