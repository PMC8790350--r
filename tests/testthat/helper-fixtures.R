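# Shared fixtures and independent oracles.

default_medium <- function() acoustic_medium()

# A small fully-specified FC profile
fc_profile <- function(code = "GYR", rho = 1028.94, lwr = 11.91) {
  taxon_profile(code, rho, lwr, "FC", lw_a = 5.7e-6, lw_b = 3,
                gas_bearing = FALSE)
}

ps_profile <- function(code = "KRA", rho = 1038.39, lwr = 12.42,
                       lw_a = 5.287e-6, lw_b = 3) {
  taxon_profile(code, rho, lwr, "PS", lw_a = lw_a, lw_b = lw_b,
                gas_bearing = TRUE)
}

# Independent weak-scatterer oracle for the finite fluid cylinder:
# distorted-wave Born volume integral evaluated in closed form per tilt
# angle and averaged numerically over the same uniform 0-90 degree tilt
# distribution.  Valid only for weak contrasts (|g-1|, |h-1| << 1); shares
# no code with the package's modal-series implementation.
dwba_cylinder_ts <- function(sl_mm, lwr, g, h, medium = default_medium(),
                             n_tilt = 2001) {
  k <- 2 * pi * medium$frequency / medium$sound_speed_water
  L <- sl_mm / 1000
  a <- (sl_mm / lwr / 2) / 1000
  gk <- (1 - g * h^2) / (g * h^2)
  gr <- (g - 1) / g
  th <- seq(0, pi / 2, length.out = n_tilt)
  argL <- k * L * sin(th)
  sinc <- ifelse(argL < 1e-12, 1, sin(argL) / argL)
  x <- 2 * k * a * cos(th)
  jfac <- ifelse(x < 1e-9, 1, 2 * besselJ(x, 1) / x)
  amp <- (k^2 * a^2 * L / 4) * (gk - gr) * jfac * sinc
  10 * log10(mean(amp^2))
}

# Exact composition/grid micro-fixture used by several partition tests
toy_setup <- function() {
  taxa <- c("A", "B", "C")
  sigma <- c(A = 1e-5, B = 2e-6, C = 5e-7)
  n <- c(A = 1, B = 4, C = 10)
  rho <- c(A = 0.01, B = 0.04, C = 0.1)
  list(taxa = taxa, sigma = sigma, n = n, rho = rho,
       nasc_const = 4 * pi * 1852^2)
}

# Small end-to-end synthetic world shared by closure tests
small_world <- function(noise_sd = 0, seed = 1, lat_range = c(-66, -61),
                        lon_range = c(-33, -28)) {
  tax <- scotia_sea_taxa()
  gradient <- default_sst_gradient(tax$profiles)
  comp <- gradient_composition(gradient)
  sim <- simulate_survey_grid(tax$profiles, tax$stats, comp,
                              lat_range = lat_range, lon_range = lon_range,
                              noise_sd = noise_sd, seed = seed)
  list(tax = tax, gradient = gradient, comp = comp, sim = sim)
}

# Direct (non-package) partition chain for one cell: the spreadsheet
# oracle used to cross-check the vectorised implementations.
oracle_cell_rho <- function(nasc, n, sigma) {
  p <- (n * sigma) / sum(n * sigma)
  nasc * p / (sigma * 4 * pi * 1852^2)
}
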