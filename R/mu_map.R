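#' Convert CT numbers to 511-keV linear attenuation coefficients
#'
#' Standard bilinear conversion: below water (HU <= 0) the attenuation
#' scales with the water fraction, \code{mu = mu_water * (1 + HU/1000)};
#' above water a shallower bone segment applies,
#' \code{mu = mu_water + HU * bone_slope}, because the photoelectric
#' contribution that raises CT numbers at diagnostic energies contributes
#' much less at 511 keV. Output is clipped at zero.
#'
#' @param ct HU \code{image_volume}.
#' @param mu_water water attenuation at 511 keV, per cm (default 0.096).
#' @param bone_slope attenuation per HU above water, per cm (default 5e-5;
#'   gives cortical-bone-like mu of about 0.146/cm at +1000 HU).
#' @return MU_511 \code{image_volume} (per cm).
#' @export
hu_to_mu <- function(ct, mu_water = 0.096, bone_slope = 5e-5) {
  expect_unit(ct, "HU")
  hu <- ct$values
  mu <- ifelse(hu <= 0, mu_water * (1 + hu / 1000), mu_water + hu * bone_slope)
  mu <- pmax(mu, 0)
  image_volume(mu, ct$spacing, "MU_511", paste0("mu map of: ", ct$label))
}
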