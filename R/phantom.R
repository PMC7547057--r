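#' Digital anthropomorphic torso phantom specification
#'
#' Parametric description of a torso phantom with soft-tissue body, two
#' air-filled lungs, heart, liver, spine, a small spherical lung tumour and
#' two arm-like lateral attenuators. Activities are in SUV units; tissue
#' densities in HU. Default activities: soft tissue 1.0, heart 4.0, liver
#' 2.5, tumour 4.0; the lungs, spine insert and arms carry no activity.
#'
#' Compartments are rasterized in a fixed priority order (body, lungs, liver,
#' heart, spine, tumour, arms) with later compartments overriding earlier
#' ones, so the rasterized compartments are disjoint. A voxel belongs to a
#' compartment if its centre falls inside the parametric geometry.
#'
#' @param shape integer length-3 PET grid (voxels per axis).
#' @param spacing numeric length-3 PET voxel spacing in mm.
#' @param ct_supersample integer in-plane supersampling factor of the CT grid
#'   relative to the PET grid (default 2: 2 mm CT over 4 mm PET).
#' @param activities named list of compartment activities (SUV).
#' @param tumour_diameter_mm diameter of the lung lesion (default 17 mm).
#' @param counts_target expected true coincidence counts per slice in the
#'   simulated PET acquisition.
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 40L),
                         spacing = c(4, 4, 4),
                         ct_supersample = 2L,
                         activities = list(soft_tissue = 1.0, heart = 4.0,
                                           liver = 2.5, tumour = 4.0),
                         tumour_diameter_mm = 17,
                         counts_target = 2e5) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  if (any(shape <= 0) || any(spacing <= 0)) stop("grid shape and spacing must be positive")
  fov <- shape * spacing
  acts <- utils::modifyList(list(soft_tissue = 1.0, heart = 4.0, liver = 2.5, tumour = 4.0),
                            activities)
  zc <- fov[3] / 2  # z runs 0..fov, compartment centres given in mm from volume bottom
  # geometry in mm; world x/y centred on the grid, z from the bottom slice face
  comps <- list(
    body   = list(type = "ecyl",  centre = c(0, 0),    semi = c(160, 115),
                  zrange = c(0, fov[3]), hu = 40,  suv = acts$soft_tissue),
    lung_l = list(type = "ecyl",  centre = c(-65, -10), semi = c(45, 62),
                  zrange = c(zc - 12, fov[3]), hu = -800, suv = 0),
    lung_r = list(type = "ecyl",  centre = c(65, -10),  semi = c(45, 62),
                  zrange = c(zc - 12, fov[3]), hu = -800, suv = 0),
    liver  = list(type = "ellip", centre = c(60, 5),   semi = c(68, 52, 45),
                  zcentre = zc - 35, hu = 55,  suv = acts$liver),
    heart  = list(type = "ellip", centre = c(-15, -25), semi = c(42, 40, 38),
                  zcentre = zc + 28, hu = 45,  suv = acts$heart),
    spine  = list(type = "cyl",   centre = c(0, 88),   radius = 16,
                  zrange = c(0, fov[3]), hu = 700, suv = 0),
    tumour = list(type = "sphere", centre = c(78, -18), radius = tumour_diameter_mm / 2,
                  zcentre = zc + 22, hu = 30, suv = acts$tumour),
    arm_l  = list(type = "cyl",   centre = c(-192, 10), radius = 36,
                  zrange = c(0, fov[3]), hu = 40, suv = 0),
    arm_r  = list(type = "cyl",   centre = c(192, 10),  radius = 36,
                  zrange = c(0, fov[3]), hu = 40, suv = 0)
  )
  structure(list(shape = shape, spacing = spacing,
                 ct_supersample = as.integer(ct_supersample),
                 compartments = comps, tumour_diameter_mm = tumour_diameter_mm,
                 counts_target = counts_target),
            class = "phantom_spec")
}

# logical mask of one compartment on a grid given by coordinate vectors
comp_mask <- function(comp, xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  X <- array(rep(xs, times = ny), c(nx, ny))
  Y <- array(rep(ys, each = nx), c(nx, ny))
  inplane <- switch(comp$type,
    ecyl   = ((X - comp$centre[1]) / comp$semi[1])^2 +
             ((Y - comp$centre[2]) / comp$semi[2])^2 <= 1,
    cyl    = (X - comp$centre[1])^2 + (Y - comp$centre[2])^2 <= comp$radius^2,
    ellip  = NULL, sphere = NULL)
  m <- array(FALSE, c(nx, ny, nz))
  if (comp$type %in% c("ecyl", "cyl")) {
    zin <- zs >= comp$zrange[1] & zs <= comp$zrange[2]
    for (k in which(zin)) m[, , k] <- inplane
  } else if (comp$type == "ellip") {
    for (k in seq_len(nz)) {
      r2 <- ((X - comp$centre[1]) / comp$semi[1])^2 +
            ((Y - comp$centre[2]) / comp$semi[2])^2 +
            ((zs[k] - comp$zcentre) / comp$semi[3])^2
      m[, , k] <- r2 <= 1
    }
  } else if (comp$type == "sphere") {
    for (k in seq_len(nz)) {
      r2 <- (X - comp$centre[1])^2 + (Y - comp$centre[2])^2 + (zs[k] - comp$zcentre)^2
      m[, , k] <- r2 <= comp$radius^2
    }
  }
  m
}

phantom_grid_coords <- function(spec, supersample = 1L) {
  shape <- spec$shape; spacing <- spec$spacing
  nx <- shape[1] * supersample; ny <- shape[2] * supersample
  sp <- c(spacing[1:2] / supersample, spacing[3])
  list(xs = axis_coords(nx, sp[1]), ys = axis_coords(ny, sp[2]),
       zs = (seq_len(shape[3]) - 0.5) * spacing[3], spacing = sp,
       shape = c(nx, ny, shape[3]))
}

#' Rasterize the phantom into activity and attenuation volumes
#'
#' Produces the ground-truth activity map (SUV, on the PET grid, noise-free)
#' and the attenuation map (HU, on the CT grid, which may be supersampled
#' in-plane). Voxel values equal the compartment values exactly.
#'
#' @param spec a \code{phantom_spec}.
#' @return list with elements \code{activity} (SUV \code{image_volume}),
#'   \code{attenuation} (HU \code{image_volume} on the CT grid), and
#'   \code{labels} (integer compartment label volume on the PET grid, with a
#'   \code{levels} attribute naming the compartments; 0 = air).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_compartments_fit(spec)
  pet <- phantom_grid_coords(spec, 1L)
  ct  <- phantom_grid_coords(spec, spec$ct_supersample)

  act <- array(0, pet$shape)
  lab <- array(0L, pet$shape)
  hu  <- array(-1000, ct$shape)
  comp_names <- names(spec$compartments)
  for (i in seq_along(spec$compartments)) {
    comp <- spec$compartments[[i]]
    mp <- comp_mask(comp, pet$xs, pet$ys, pet$zs)
    act[mp] <- comp$suv
    lab[mp] <- i
    if (spec$ct_supersample > 1L) {
      mc <- comp_mask(comp, ct$xs, ct$ys, ct$zs)
      hu[mc] <- comp$hu
    } else {
      hu[mp] <- comp$hu
    }
  }
  attr(lab, "levels") <- comp_names
  list(
    activity = image_volume(act, spec$spacing, "SUV", "phantom ground truth"),
    attenuation = image_volume(hu, ct$spacing, "HU", "phantom attenuation (noise-free)"),
    labels = lab
  )
}

check_compartments_fit <- function(spec) {
  half <- spec$shape[1:2] * spec$spacing[1:2] / 2
  for (nm in names(spec$compartments)) {
    comp <- spec$compartments[[nm]]
    ext <- switch(comp$type,
      ecyl = abs(comp$centre) + comp$semi[1:2],
      ellip = abs(comp$centre) + comp$semi[1:2],
      cyl = abs(comp$centre) + comp$radius,
      sphere = abs(comp$centre) + comp$radius)
    if (any(ext > half))
      stop(sprintf("compartment '%s' extends outside the grid", nm))
  }
  invisible(TRUE)
}

#' Compartment masks on the PET grid
#'
#' @param phantom result of \code{\link{build_phantom}}.
#' @param name compartment name (e.g. \code{"liver"}); \code{"lungs"} unions
#'   the two lungs, \code{"body"} unions everything except air and arms.
#' @return logical array.
#' @export
compartment_mask <- function(phantom, name) {
  lab <- phantom$labels
  lev <- attr(lab, "levels")
  if (name == "lungs") return(array(lab %in% which(lev %in% c("lung_l", "lung_r")), dim(lab)))
  if (name == "body")  return(array(lab %in% which(!lev %in% c("arm_l", "arm_r")) & lab > 0L, dim(lab)))
  if (name == "support") return(array(lab > 0L, dim(lab)))
  idx <- match(name, lev)
  if (is.na(idx)) stop(sprintf("unknown compartment '%s'", name))
  array(lab == idx, dim(lab))
}
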