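#' Neutral-buoyancy gas volume
#'
#' Theoretical gas volume a fish of given wet mass and tissue density must
#' carry to be neutrally buoyant in seawater. Balancing total density against
#' the water density gives
#' \deqn{V = m (\rho_f - \rho_w) / (\rho_f \rho_w)}
#' with mass in g, densities in kg/m3 and volume returned in ml. The volume
#' is computed at atmospheric pressure and held constant with depth (no
#' Boyle-compression is applied): tissue densities are measured at the
#' surface and the gas content is assumed regulated at depth.
#'
#' @param mass_g wet mass, g (vectorised)
#' @param tissue_density fish tissue density rho_f, kg/m3
#' @param water_density seawater density rho_w, kg/m3
#' @return gas volume, ml. If `tissue_density <= water_density` the tissue
#'   alone is already buoyant: the function returns 0 with a warning.
#' @examples
#' gas_volume_neutral_buoyancy(1, 1038.39, 1027.4) # ~0.01030 ml
#' @export
gas_volume_neutral_buoyancy <- function(mass_g, tissue_density,
                                        water_density) {
  if (any(mass_g <= 0)) stop("mass_g must be > 0")
  if (tissue_density <= 0 || water_density <= 0)
    stop("densities must be > 0")
  if (tissue_density < water_density) {
    warning("fish not denser than seawater; no gas needed")
    return(rep(0, length(mass_g)))
  }
  # g * (kg/m3) / (kg/m3)^2 -> need SI: m kg, V m3; 1 g = 1e-3 kg, 1 m3 = 1e6 ml
  m_kg <- mass_g * 1e-3
  v_m3 <- m_kg * (tissue_density - water_density) /
    (tissue_density * water_density)
  v_m3 * 1e6
}

#' Equivalent spherical radius of a gas volume
#'
#' r = (3V / 4 pi)^(1/3), volume in ml, radius returned in mm. Used to check
#' the no-resonance assumption: for the taxa considered, equivalent radii
#' exceed 1 mm so the 38 kHz signal sits above bubble resonance.
#'
#' @param volume_ml gas volume, ml (vectorised)
#' @return equivalent spherical radius, mm
#' @examples
#' equivalent_spherical_radius(4 * pi / 3 * 1e-3) # 1 mm
#' @export
equivalent_spherical_radius <- function(volume_ml) {
  if (any(volume_ml < 0)) stop("volume must be >= 0")
  # 1 ml = 1000 mm3
  (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
}
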