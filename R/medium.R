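#' Acoustic medium constants
#'
#' Bundles the physical constants of the survey medium used by every
#' target-strength model: sound speed and density of seawater, sound speed in
#' fish tissue, echosounder frequency, and the nominal depth at which
#' swimbladder targets are modelled.
#'
#' Defaults are the Scotia Sea survey means: sound speed in seawater
#' 1465.836 m/s and density 1027.4 kg/m3 (CTD means), sound speed in fish
#' tissue 1510 m/s (measured for a myctophid at 4 degrees C), 38 kHz, 500 m.
#'
#' @param sound_speed_water sound speed in seawater, m/s
#' @param density_water seawater density, kg/m3
#' @param sound_speed_fish sound speed in fish tissue, m/s
#' @param frequency echosounder frequency, Hz
#' @param depth modelling depth for swimbladder targets, m
#' @return an object of class `acoustic_medium`
#' @examples
#' med <- acoustic_medium()
#' wavenumber(med)
#' @export
acoustic_medium <- function(sound_speed_water = 1465.836,
                            density_water = 1027.4,
                            sound_speed_fish = 1510,
                            frequency = 38000,
                            depth = 500) {
  vals <- c(sound_speed_water = sound_speed_water,
            density_water = density_water,
            sound_speed_fish = sound_speed_fish,
            frequency = frequency, depth = depth)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all acoustic_medium fields must be strictly positive and finite")
  structure(as.list(vals), class = "acoustic_medium")
}

#' Acoustic wavenumber of the medium
#'
#' k = 2 pi f / c_w, in rad/m.
#'
#' @param medium an [acoustic_medium()]
#' @return wavenumber, rad/m
#' @export
wavenumber <- function(medium) {
  stopifnot(inherits(medium, "acoustic_medium"))
  2 * pi * medium$frequency / medium$sound_speed_water
}

#' @export
print.acoustic_medium <- function(x, ...) {
  cat(sprintf(
    "acoustic_medium: c_w %.3f m/s, rho_w %.1f kg/m3, c_f %.0f m/s, f %.0f Hz, depth %.0f m\n",
    x$sound_speed_water, x$density_water, x$sound_speed_fish, x$frequency,
    x$depth))
  invisible(x)
}

#' Convert target strength to backscattering cross-section
#'
#' sigma_bs = 10^(TS/10). A TS of `-Inf` (no target) maps to sigma_bs = 0,
#' so downstream sums over taxa remain well defined.
#'
#' @param ts target strength, dB re 1 m2 (vectorised; `-Inf` allowed)
#' @return backscattering cross-section, m2
#' @export
ts_to_sigma_bs <- function(ts) {
  if (any(is.na(ts))) stop("ts contains NA")
  out <- 10^(ts / 10)
  out[is.infinite(ts) & ts < 0] <- 0
  out
}

#' Convert backscattering cross-section to target strength
#'
#' TS = 10 log10(sigma_bs); sigma_bs = 0 maps to `-Inf`.
#'
#' @param sigma_bs backscattering cross-section, m2 (vectorised)
#' @return target strength, dB re 1 m2
#' @export
sigma_bs_to_ts <- function(sigma_bs) {
  if (any(is.na(sigma_bs)) || any(sigma_bs < 0))
    stop("sigma_bs must be non-negative")
  ifelse(sigma_bs == 0, -Inf, 10 * log10(sigma_bs))
}
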