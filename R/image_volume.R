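#' 3-D image volume with spacing and unit tag
#'
#' The universal currency of the pipeline: a 3-D scalar field plus voxel
#' spacing in mm and a unit tag. Units are \code{"SUV"} (standardised uptake
#' value), \code{"HU"} (CT numbers), \code{"MU_511"} (linear attenuation at
#' 511 keV, per cm) or \code{"COUNTS"}. HU volumes are bounded to
#' [-1024, 3071]; SUV and MU_511 volumes must be nonnegative.
#'
#' World coordinates place voxel centres at
#' \code{(index - (n + 1)/2) * spacing} per axis, so the grid is centred on
#' the origin.
#'
#' @param values numeric 3-D array.
#' @param spacing numeric length-3, mm per axis (x, y, z).
#' @param unit one of \code{"SUV"}, \code{"HU"}, \code{"MU_511"},
#'   \code{"COUNTS"}, \code{"LABEL"}.
#' @param label free-text provenance label.
#' @return an object of class \code{image_volume}.
#' @export
image_volume <- function(values, spacing, unit = c("SUV", "HU", "MU_511", "COUNTS", "LABEL"),
                         label = "") {
  unit <- match.arg(unit)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive voxel dimensions in mm")
  storage.mode(values) <- "double"
  vol <- structure(list(values = values, spacing = spacing, unit = unit, label = label),
                   class = "image_volume")
  validate_volume(vol)
  vol
}

validate_volume <- function(vol) {
  v <- vol$values
  if (anyNA(v)) stop("volume contains NA values")
  if (vol$unit == "HU" && (min(v) < -1024 || max(v) > 3071))
    stop("HU volume out of bounds [-1024, 3071]")
  if (vol$unit %in% c("SUV", "MU_511", "COUNTS") && min(v) < 0)
    stop(sprintf("%s volume must be nonnegative", vol$unit))
  invisible(vol)
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %dx%dx%d @ %s mm [%s] %s\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = "x"),
              x$unit, x$label))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' Check that two volumes live on the same grid
#'
#' Volumes are comparable only if shape and spacing match exactly; no silent
#' resampling is ever performed.
#'
#' @param a,b \code{image_volume} objects.
#' @param what short description used in the error message.
#' @export
stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("%s have different grid shapes (%s vs %s)", what,
                 paste(dim(a$values), collapse = "x"),
                 paste(dim(b$values), collapse = "x")))
  if (!isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-12)))
    stop(sprintf("%s have different voxel spacing", what))
  invisible(TRUE)
}

expect_unit <- function(vol, unit) {
  if (!inherits(vol, "image_volume")) stop("not an image_volume")
  if (vol$unit != unit)
    stop(sprintf("volume has unit '%s', expected '%s'", vol$unit, unit))
  invisible(vol)
}

#' World coordinates of voxel centres along one axis
#' @param n number of voxels; @param spacing mm per voxel.
#' @keywords internal
axis_coords <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

#' Downsample a volume in-plane by integer block averaging
#'
#' Used to bring the finer CT grid onto the PET grid before conversion to
#' attenuation coefficients. The z axis is left untouched (slice-stacked
#' geometry).
#'
#' @param vol an \code{image_volume}.
#' @param factor integer in-plane downsampling factor.
#' @export
downsample_xy <- function(vol, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(vol)
  d <- dim(vol$values)
  if (any(d[1:2] %% factor != 0L))
    stop("in-plane dimensions not divisible by downsampling factor")
  nx <- d[1] %/% factor; ny <- d[2] %/% factor
  v <- vol$values
  out <- array(0, c(nx, ny, d[3]))
  for (i in seq_len(factor)) for (j in seq_len(factor))
    out <- out + v[seq(i, by = factor, length.out = nx),
                   seq(j, by = factor, length.out = ny), , drop = FALSE]
  out <- out / factor^2
  image_volume(out, c(vol$spacing[1:2] * factor, vol$spacing[3]), vol$unit,
               paste0(vol$label, " (downsampled x", factor, ")"))
}

#' Write / read an image volume as NIfTI-1 with a JSON sidecar
#'
#' The voxel data and spacing go into the NIfTI file; the unit tag, label and
#' any extra metadata (e.g. the CT protocol) go into \code{<path>.json}.
#'
#' @param vol an \code{image_volume}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param extra named list merged into the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path, extra = list()) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  side <- c(list(unit = vol$unit, label = vol$label, spacing_mm = vol$spacing), extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @param unit unit tag to assume when no sidecar is present.
#' @export
read_volume <- function(path, unit = "SUV") {
  img <- RNifti::readNifti(path)
  side_path <- paste0(path, ".json")
  label <- basename(path)
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$unit)) unit <- side$unit
    if (!is.null(side$label)) label <- side$label
  }
  spacing <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  image_volume(arr, spacing, unit, label)
}
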