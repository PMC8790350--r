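#' Sample distinct TS-percentile permutations
#'
#' Draws `n` distinct tuples, uniformly without replacement, from the
#' lattice of per-taxon length-statistic choices {p25, median, p75}^T.
#'
#' @param n number of draws (must not exceed 3^T)
#' @param taxa character vector of taxon codes (length T)
#' @param seed RNG seed
#' @return a character matrix n x T (entries "p25"/"median"/"p75") of class
#'   `percentile_draws`
#' @examples
#' d <- sample_draws(27, c("A", "B", "C"), seed = 1) # exhaustive for T = 3
#' @export
sample_draws <- function(n, taxa, seed = 1L) {
  t_len <- length(taxa)
  n_lattice <- 3^t_len
  if (n > n_lattice)
    stop(sprintf("cannot draw %d distinct tuples from a lattice of %g", n,
                 n_lattice))
  levels <- c("p25", "median", "p75")
  set.seed(seed)
  if (n_lattice <= .Machine$integer.max) {
    idx <- sample.int(n_lattice, n) - 1
  } else {
    # rejection sampling for very many taxa
    idx <- numeric(0)
    while (length(idx) < n) {
      cand <- floor(stats::runif(2 * n, 0, n_lattice))
      idx <- unique(c(idx, cand))[seq_len(min(n, length(unique(c(idx, cand)))))]
    }
  }
  out <- matrix("", nrow = n, ncol = t_len, dimnames = list(NULL, taxa))
  rem <- idx
  for (j in seq_len(t_len)) {
    out[, j] <- levels[(rem %% 3) + 1]
    rem <- rem %/% 3
  }
  class(out) <- c("percentile_draws", class(out))
  out
}

#' Remove krill backscatter from NASC
#'
#' Forward-computes the NASC a fixed areal density of krill would generate,
#' NASC_krill = rho sigma_bs 4 pi 1852^2, subtracts it from each cell and
#' floors at zero. The number of floored cells is reported so the scenario's
#' plausibility can be monitored.
#'
#' @param nasc cell NASC values, m2 nmi^-2 (vectorised)
#' @param krill_density krill areal density, ind. m^-2
#' @param krill_sigma_bs krill backscattering cross-section, m2
#' @return fish-attributable NASC with attributes `nasc_krill` and
#'   `n_floored`
#' @export
krill_adjusted_nasc <- function(nasc, krill_density, krill_sigma_bs) {
  if (krill_density < 0 || krill_sigma_bs < 0)
    stop("krill density and cross-section must be >= 0")
  nasc_krill <- krill_density * krill_sigma_bs * NASC_CONSTANT
  out <- pmax(nasc - nasc_krill, 0)
  attr(out, "nasc_krill") <- nasc_krill
  attr(out, "n_floored") <- sum(nasc < nasc_krill)
  out
}

#' Krill as an explicit scattering taxon
#'
#' Alternative krill-incorporation mechanism: instead of subtracting a
#' forward-computed krill NASC, krill are added to the partition as an
#' extra taxon whose abundance N_k is solved per cell so that its output
#' areal density equals the target density. Solving the partition algebra
#' for the resulting fish-attributable backscatter gives
#' NASC_fish = NASC * S_f / (S_f + N_k sigma_k), which reduces
#' analytically to the subtraction rule NASC - rho_k sigma_k C whenever
#' the target is feasible; both mechanisms are exposed and their
#' equivalence is verified in the test-suite.
#'
#' @param nasc cell NASC values, m2 nmi^-2 (vectorised)
#' @param krill_density target krill areal density, ind. m^-2
#' @param krill_sigma_bs krill cross-section, m2
#' @param fish_backscatter S_f = sum_i N_i sigma_i of the fish composition
#'   (any positive scale)
#' @return fish-attributable NASC (same contract as
#'   [krill_adjusted_nasc()])
#' @export
krill_as_taxon_nasc <- function(nasc, krill_density, krill_sigma_bs,
                                fish_backscatter) {
  if (fish_backscatter <= 0) stop("fish composition has no backscatter")
  headroom <- nasc / NASC_CONSTANT - krill_density * krill_sigma_bs
  n_k <- ifelse(headroom > 0,
                krill_density * fish_backscatter / headroom, Inf)
  out <- ifelse(is.finite(n_k),
                nasc * fish_backscatter /
                  (fish_backscatter + n_k * krill_sigma_bs),
                0)
  attr(out, "n_floored") <- sum(!is.finite(n_k) & krill_density > 0)
  out
}

# Per-bin biomass coefficient: biomass (g m^-2) per unit fish NASC, for a
# chosen taxa subset.  K_b = sum_i N_bi W_i / (C * sum_j N_bj sigma_j).
.bin_biomass_coef <- function(comp_row, sigma, weight, subset) {
  denom <- sum(comp_row * sigma) * NASC_CONSTANT
  if (is.na(denom) || denom <= 0) return(NA_real_)
  sum(comp_row[subset] * weight[subset]) / denom
}

#' TS percentile permutation / krill scenario sensitivity analysis
#'
#' For every permutation draw and krill scenario, rebuilds the taxon
#' cross-sections and weights at the drawn length statistics, removes the
#' scenario's krill backscatter, re-partitions every grid cell and
#' aggregates regional biomass totals; summarises the distribution of
#' totals over draws.
#'
#' @param grid data.frame with columns `lat`, `lon`, `log_e_nasc`, `sst`
#'   (optionally `shelf`, excluded when present)
#' @param composition a [group_mean_abundance()] composition table over the
#'   fish taxa
#' @param profiles,stats named lists from [read_taxon_table()] (must
#'   include the fish taxa of `composition`; a taxon with model "SDWBA"
#'   supplies the krill cross-section)
#' @param medium an [acoustic_medium()]
#' @param n_draws number of percentile permutations (2000 in the standard
#'   protocol)
#' @param seed RNG seed (drives both the draw lattice and the SDWBA
#'   ensemble)
#' @param krill_densities krill scenario densities, ind. m^-2; 0 means the
#'   fish-only scenario (standard set: 0, 32, 64, 128)
#' @param regions named list of region polygon sets (see
#'   [default_regions()])
#' @param taxa_sets named list of taxa subsets to total (defaults: all
#'   fish, and the myctophid subset)
#' @param aspect_ratio,krill_params model options passed through
#' @param draws optionally a precomputed [sample_draws()] matrix (its
#'   column names must cover the fish taxa, plus the krill code when krill
#'   scenarios are requested)
#' @return object of class `sensitivity_summary`: a data.frame with one
#'   row per region x taxa-set x scenario (`mean_mt`, `p25_mt`, `p75_mt`,
#'   `sd_mt`, `area_km2`), with the per-draw totals in attribute `draws_mt`
#' @export
run_sensitivity <- function(grid, composition, profiles, stats,
                            medium = acoustic_medium(),
                            n_draws = 2000, seed = 1L,
                            krill_densities = c(0, 32, 64, 128),
                            regions = default_regions(),
                            taxa_sets = NULL,
                            aspect_ratio = 3,
                            krill_params = krill_parameters(),
                            draws = NULL) {
  fish_taxa <- colnames(composition)
  krill_code <- names(profiles)[vapply(profiles, function(p)
    p$model == "SDWBA", logical(1))]
  if (length(krill_code) > 1) stop("more than one SDWBA taxon supplied")
  need_krill <- any(krill_densities > 0)
  if (need_krill && length(krill_code) == 0)
    stop("krill scenarios requested but no SDWBA taxon in profiles")
  draw_taxa <- c(fish_taxa, if (need_krill) krill_code)
  if (is.null(draws)) draws <- sample_draws(n_draws, draw_taxa, seed = seed)
  if (!all(draw_taxa %in% colnames(draws)))
    stop("draws matrix does not cover the required taxa")
  n_draws <- nrow(draws)
  if (is.null(taxa_sets))
    taxa_sets <- list(all_fish = fish_taxa,
                      myctophids = intersect(myctophid_codes(), fish_taxa))

  stat_names <- c("p25", "median", "p75")
  # TS and weight lookup tables: taxa x statistic, computed once
  sig <- matrix(NA_real_, length(fish_taxa), 3,
                dimnames = list(fish_taxa, stat_names))
  wgt <- sig
  for (nm in fish_taxa) {
    p <- profiles[[nm]]
    if (is.null(p)) stop("no profile for composition taxon ", nm)
    st <- stats[[nm]]
    sl <- c(st$p25, st$median, st$p75)
    sig[nm, ] <- ts_to_sigma_bs(taxon_ts(p, sl, medium,
                                         aspect_ratio = aspect_ratio,
                                         krill_params = krill_params,
                                         seed = seed))
    wgt[nm, ] <- weight_at_length(list(a = p$lw_a, b = p$lw_b), sl)
  }
  sig_krill <- if (length(krill_code) == 1) {
    st <- stats[[krill_code]]
    stats::setNames(ts_to_sigma_bs(
      sdwba_krill_ts(c(st$p25, st$median, st$p75), medium, krill_params,
                     seed = seed)), stat_names)
  } else NULL

  # cell bookkeeping
  keep <- rep(TRUE, nrow(grid))
  if ("shelf" %in% names(grid)) keep <- keep & !grid$shelf
  bin <- sst_bin_index(grid$sst, attr(composition, "edges"))
  usable <- keep & !is.na(bin) & attr(composition, "n_samples")[ifelse(
    is.na(bin), 1L, bin)] > 0
  nasc <- backtransform_nasc(grid$log_e_nasc)
  area <- cell_area(grid$lat)
  n_bins <- nrow(composition)

  # S[r, b] = sum over usable cells of region r, bin b of nasc_fish * area;
  # nasc_fish depends on (scenario, krill statistic) only.
  region_masks <- lapply(regions, function(rg) in_region(grid$lat, grid$lon, rg))
  sum_nasc_area <- function(nasc_fish) {
    vapply(region_masks, function(rm) {
      vapply(seq_len(n_bins), function(b) {
        m <- usable & rm & !is.na(bin) & bin == b
        sum(nasc_fish[m] * area[m])
      }, numeric(1))
    }, numeric(n_bins))  # bins x regions
  }

  scen_names <- paste0("krill_", krill_densities)
  S_tab <- list()
  for (si in seq_along(krill_densities)) {
    dk <- krill_densities[si]
    if (dk == 0) {
      S_tab[[scen_names[si]]] <- list(any = sum_nasc_area(nasc))
    } else {
      S_tab[[scen_names[si]]] <- lapply(sig_krill, function(sk)
        sum_nasc_area(krill_adjusted_nasc(nasc, dk, sk)))
    }
  }

  totals <- array(NA_real_,
                  dim = c(n_draws, length(regions), length(taxa_sets),
                          length(krill_densities)),
                  dimnames = list(NULL, names(regions), names(taxa_sets),
                                  scen_names))
  for (d in seq_len(n_draws)) {
    stat_d <- draws[d, fish_taxa]
    sig_d <- sig[cbind(fish_taxa, stat_d)]
    wgt_d <- wgt[cbind(fish_taxa, stat_d)]
    names(sig_d) <- names(wgt_d) <- fish_taxa
    K <- vapply(names(taxa_sets), function(tsn) {
      subset <- taxa_sets[[tsn]]
      vapply(seq_len(n_bins), function(b)
        .bin_biomass_coef(composition[b, ], sig_d, wgt_d, subset),
        numeric(1))
    }, numeric(n_bins))  # bins x sets
    for (si in seq_along(krill_densities)) {
      S <- if (krill_densities[si] == 0) S_tab[[si]]$any
           else S_tab[[si]][[draws[d, krill_code]]]
      for (tsn in seq_along(taxa_sets)) {
        kb <- K[, tsn]
        ok <- !is.na(kb)
        # g m^-2 (= t km^-2) * km2 / 1e6 -> Mt
        totals[d, , tsn, si] <- colSums(S[ok, , drop = FALSE] * kb[ok]) / 1e6
      }
    }
  }

  rows <- list()
  for (r in names(regions)) for (tsn in names(taxa_sets))
    for (si in seq_along(krill_densities)) {
      v <- totals[, r, tsn, si]
      rows[[length(rows) + 1]] <- data.frame(
        region = r, taxa_set = tsn, krill_density = krill_densities[si],
        mean_mt = mean(v),
        p25_mt = stats::quantile(v, 0.25, names = FALSE),
        p75_mt = stats::quantile(v, 0.75, names = FALSE),
        sd_mt = stats::sd(v),
        area_km2 = sum(area[usable & region_masks[[r]]]),
        stringsAsFactors = FALSE)
    }
  out <- do.call(rbind, rows)
  attr(out, "draws_mt") <- totals
  attr(out, "n_unusable_cells") <- sum(!usable)
  class(out) <- c("sensitivity_summary", "data.frame")
  out
}

#' @export
print.sensitivity_summary <- function(x, ...) {
  cat("Sensitivity summary (biomass totals, Mt)\n")
  y <- x; class(y) <- "data.frame"
  y[c("mean_mt", "p25_mt", "p75_mt", "sd_mt")] <-
    lapply(y[c("mean_mt", "p25_mt", "p75_mt", "sd_mt")], round, 3)
  y$area_km2 <- round(y$area_km2)
  print(y, row.names = FALSE)
  invisible(x)
}
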