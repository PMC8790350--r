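#' Simulate standard lengths
#'
#' Lognormal lengths whose parameters are solved analytically from the
#' target median and 75th percentile: meanlog = log(median), sdlog =
#' log(p75/median) / qnorm(0.75). Positivity and right skew come for free;
#' the implied 25th percentile is median^2/p75, which approximates (but
#' need not equal) an asymmetric target p25.
#'
#' @param n number of lengths
#' @param stats a [length_stats()] target (only `median` and `p75` are
#'   binding)
#' @param seed RNG seed
#' @return numeric vector of lengths, mm
#' @export
simulate_lengths <- function(n, stats, seed = 1L) {
  if (stats$p25 >= stats$p75)
    stop("infeasible targets: p25 must be < p75")
  meanlog <- log(stats$median)
  sdlog <- log(stats$p75 / stats$median) / stats::qnorm(0.75)
  set.seed(seed)
  stats::rlnorm(n, meanlog, sdlog)
}

#' Default SST-abundance gradient
#'
#' Expected per-taxon abundance as a smooth Gaussian function of SST, with
#' thermal optima placed so that gas-bearing taxa prefer the warmer bins
#' and non-gas taxa the colder bins — the latitudinal community switch the
#' partitioning machinery exists to handle.
#'
#' @param profiles named list of [taxon_profile()] (fish taxa only; an
#'   SDWBA taxon is ignored)
#' @param peak expected abundance at a taxon's optimum
#' @param width Gaussian width, degrees C
#' @return function(sst) returning a named vector of expected abundances
#' @export
default_sst_gradient <- function(profiles, peak = 20, width = 2) {
  fish <- profiles[vapply(profiles, function(p) p$model != "SDWBA",
                          logical(1))]
  gas <- names(fish)[vapply(fish, function(p) p$gas_bearing, logical(1))]
  nongas <- setdiff(names(fish), gas)
  opt <- c(stats::setNames(seq(2.5, 5.5, length.out = max(length(gas), 1)),
                           gas),
           stats::setNames(seq(-0.8, 1.8, length.out = max(length(nongas), 1)),
                           nongas))
  opt <- opt[names(fish)]
  function(sst) {
    stats::setNames(peak * exp(-(sst - opt)^2 / (2 * width^2)), names(fish))
  }
}

#' Simulate net samples along an SST gradient
#'
#' Station counts are negative-binomial draws around the gradient's
#' expected abundances (trawl catches are overdispersed);
#' `dispersion = Inf` gives the Poisson limit. Station SSTs are uniform on
#' `sst_range`, which deliberately extends slightly beyond the -1 to 6
#' analysis window so the exclusion bookkeeping is exercised.
#'
#' @param n_stations number of stations
#' @param gradient a function(sst) -> named expected-abundance vector,
#'   e.g. [default_sst_gradient()]
#' @param sst_range range from which station SSTs are drawn, degrees C
#' @param dispersion negative-binomial size parameter (Inf = Poisson)
#' @param seed RNG seed
#' @return data.frame with `station`, `sst` and one count column per
#'   taxon; the generating gradient is stored in attribute `gradient`
#' @export
simulate_net_samples <- function(n_stations, gradient,
                                 sst_range = c(-1.5, 6.5),
                                 dispersion = 5, seed = 1L) {
  set.seed(seed)
  sst <- stats::runif(n_stations, sst_range[1], sst_range[2])
  mu <- do.call(rbind, lapply(sst, gradient))
  counts <- mu
  for (j in seq_len(ncol(mu))) {
    counts[, j] <- if (is.infinite(dispersion))
      stats::rpois(nrow(mu), mu[, j])
    else stats::rnbinom(nrow(mu), size = dispersion, mu = mu[, j])
  }
  out <- data.frame(station = seq_len(n_stations), sst = sst)
  out <- cbind(out, as.data.frame(counts))
  attr(out, "gradient") <- gradient
  out
}

#' Expected composition table of a gradient
#'
#' The bin-level composition the estimator targets: the gradient evaluated
#' at each SST bin midpoint. Used as exact ground truth in closure tests.
#'
#' @param gradient function(sst) -> named abundance vector
#' @param edges SST bin edges
#' @return a `composition_table`
#' @export
gradient_composition <- function(gradient, edges = -1:6) {
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  mat <- t(vapply(mids, gradient, gradient(mids[1])))
  rownames(mat) <- sst_bin_labels(edges)
  structure(mat, n_samples = rep(1L, nrow(mat)), n_excluded = 0L,
            edges = edges, class = c("composition_table", "matrix"))
}

#' Simulate a survey grid with known truth
#'
#' Builds a 0.25-degree lat-lon grid with a poleward-declining SST surface,
#' assigns each cell true per-taxon areal densities proportional to the
#' composition of its SST bin, forward-computes NASC through the exact
#' conservation relation
#' \deqn{NASC = 4\pi\,1852^2 \sum_i \rho_i \sigma_{bs,i}}
#' and perturbs log_e NASC with Gaussian noise. With `noise_sd = 0` the
#' partition-biomass chain recovers the truth exactly (closure).
#'
#' @param profiles,stats taxon inputs (see [read_taxon_table()])
#' @param composition a `composition_table` giving the per-bin truth
#'   composition (e.g. [gradient_composition()])
#' @param medium an [acoustic_medium()]
#' @param lat_range,lon_range grid extent, degrees (defaults give a
#'   40 x 40 cell grid)
#' @param resolution cell size, degrees
#' @param density_scale total-density scalar s so that true rho_i(cell) =
#'   s * N_i(bin); may be a single number or a function(lat) for spatial
#'   structure
#' @param sl_statistic length statistic at which the true cross-sections
#'   and weights are evaluated ("median" by default)
#' @param noise_sd s.d. of the Gaussian noise added to log_e NASC
#' @param sst_north,sst_south SST at the northern / southern edge (linear
#'   in latitude; the default range extends past the -1..6 analysis window
#'   so masking is exercised)
#' @param aspect_ratio,krill_params model options
#' @param seed RNG seed
#' @return list with `grid` (data.frame `cell, lat, lon, log_e_nasc, sst,
#'   shelf`), `truth` (list: `rho` and `biomass_gm2` matrices cells x
#'   taxa, `totals_mt` per region, `sigma_bs`, `weights_g`, parameters)
#' @export
simulate_survey_grid <- function(profiles, stats, composition,
                                 medium = acoustic_medium(),
                                 lat_range = c(-70, -60),
                                 lon_range = c(-35, -25),
                                 resolution = 0.25,
                                 density_scale = 0.05,
                                 sl_statistic = "median",
                                 noise_sd = 0,
                                 sst_north = 6.4, sst_south = -1.6,
                                 aspect_ratio = 3,
                                 krill_params = krill_parameters(),
                                 seed = 1L) {
  taxa <- colnames(composition)
  lat <- seq(lat_range[1] + resolution / 2, lat_range[2] - resolution / 2,
             by = resolution)
  lon <- seq(lon_range[1] + resolution / 2, lon_range[2] - resolution / 2,
             by = resolution)
  cells <- expand.grid(lon = lon, lat = lat)[, c("lat", "lon")]
  n <- nrow(cells)
  sst <- sst_south + (cells$lat - lat_range[1]) /
    (lat_range[2] - lat_range[1]) * (sst_north - sst_south)

  sig <- numeric(length(taxa)); wg <- numeric(length(taxa))
  names(sig) <- names(wg) <- taxa
  for (nm in taxa) {
    p <- profiles[[nm]]; st <- stats[[nm]]
    sl <- st[[sl_statistic]]
    sig[nm] <- ts_to_sigma_bs(taxon_ts(p, sl, medium,
                                       aspect_ratio = aspect_ratio,
                                       krill_params = krill_params,
                                       seed = seed))
    wg[nm] <- weight_at_length(list(a = p$lw_a, b = p$lw_b), sl)
  }

  bin <- sst_bin_index(sst, attr(composition, "edges"))
  s_of_lat <- if (is.function(density_scale)) density_scale(cells$lat)
              else rep(density_scale, n)
  rho <- matrix(0, n, length(taxa), dimnames = list(NULL, taxa))
  in_range <- !is.na(bin)
  rho[in_range, ] <- s_of_lat[in_range] * composition[bin[in_range], ,
                                                      drop = FALSE]
  nasc <- as.numeric(rho %*% sig) * NASC_CONSTANT
  set.seed(seed)
  log_nasc <- ifelse(nasc > 0, log(nasc), 0) +
    if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  log_nasc[nasc == 0] <- -Inf
  # cells with zero forward NASC are retained with NASC 0
  grid <- data.frame(cell = seq_len(n), lat = cells$lat, lon = cells$lon,
                     log_e_nasc = ifelse(is.infinite(log_nasc),
                                         NA_real_, log_nasc),
                     sst = sst, shelf = FALSE)
  grid$log_e_nasc[is.na(grid$log_e_nasc)] <- -745  # exp() underflows to 0
  biomass <- sweep(rho, 2, wg, `*`)
  list(grid = grid,
       truth = list(rho = rho, biomass_gm2 = biomass,
                    sigma_bs = sig, weights_g = wg,
                    density_scale = s_of_lat, sl_statistic = sl_statistic,
                    noise_sd = noise_sd, seed = seed))
}
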