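#' Read a survey grid from long-format CSV
#'
#' Long-format CSV is the canonical grid interchange: one row per cell
#' with columns `cell, lat, lon, log_e_nasc, sst` (optional `shelf`).
#' The grid must sit on a regular lattice of the stated resolution;
#' irregular spacing is an error.
#'
#' @param path CSV path
#' @param resolution expected grid resolution, degrees
#' @return validated grid data.frame (adds `shelf = FALSE` when absent)
#' @export
read_grid <- function(path, resolution = 0.25) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell", "lat", "lon", "log_e_nasc", "sst")
  miss <- setdiff(required, names(g))
  if (length(miss) > 0)
    stop("grid missing required column(s): ", paste(miss, collapse = ", "))
  for (axis in c("lat", "lon")) {
    u <- sort(unique(g[[axis]]))
    if (length(u) > 1) {
      d <- diff(u)
      if (any(abs(d / resolution - round(d / resolution)) > 1e-6))
        stop("irregular grid: ", axis,
             " spacing is not a multiple of ", resolution)
    }
    off <- (u - resolution / 2) / resolution
    if (any(abs(off - round(off)) > 1e-6))
      stop("grid ", axis, " centres not aligned to the ", resolution,
           " degree lattice")
  }
  if (!"shelf" %in% names(g)) g$shelf <- FALSE
  g
}

#' Write a survey grid to CSV
#' @param grid grid data.frame
#' @param path output path
#' @export
write_grid <- function(grid, path) {
  utils::write.csv(grid, path, row.names = FALSE, quote = FALSE)
}

#' Pipeline configuration
#'
#' Validated bundle of everything a full run needs. File paths may be NULL
#' when the corresponding synthetic generator is to be used.
#'
#' @param taxon_table path to the taxon parameter CSV (NULL = packaged
#'   Scotia Sea table)
#' @param grid path to a grid CSV (NULL = simulate)
#' @param net_samples path to a net-sample CSV with `sst` + taxon count
#'   columns (NULL = simulate along the default gradient)
#' @param medium an [acoustic_medium()]
#' @param sl_statistic length statistic for the point estimate
#' @param n_draws,krill_densities sensitivity settings
#' @param n_stations stations for the simulated net survey
#' @param noise_sd NASC noise for the simulated grid
#' @param aspect_ratio swimbladder aspect ratio
#' @param seed master seed; per-stage seeds are derived deterministically
#' @param regions region polygon list
#' @param out_dir optional output directory (per-cell CSV + summary JSON +
#'   resolved config are written there)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(taxon_table = NULL, grid = NULL,
                            net_samples = NULL,
                            medium = acoustic_medium(),
                            sl_statistic = c("median", "p25", "mean", "p75"),
                            n_draws = 2000,
                            krill_densities = c(0, 32, 64, 128),
                            n_stations = 140, noise_sd = 0.3,
                            aspect_ratio = 3, seed = 1L,
                            regions = default_regions(), out_dir = NULL) {
  sl_statistic <- match.arg(sl_statistic)
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (any(krill_densities < 0)) stop("krill densities must be >= 0")
  structure(list(taxon_table = taxon_table, grid = grid,
                 net_samples = net_samples, medium = medium,
                 sl_statistic = sl_statistic, n_draws = n_draws,
                 krill_densities = krill_densities,
                 n_stations = n_stations, noise_sd = noise_sd,
                 aspect_ratio = aspect_ratio, seed = as.integer(seed),
                 regions = regions, out_dir = out_dir),
            class = "pipeline_config")
}

# deterministic per-stage seed fan-out from the master seed
.stage_seed <- function(seed, stage) {
  offs <- c(net = 101L, grid = 211L, draws = 307L, sdwba = 401L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full acoustics-to-biomass pipeline
#'
#' Loads (or simulates) the taxon table, net samples and NASC grid, builds
#' the SST-binned composition, evaluates the TS table, partitions every
#' cell at the configured length statistic, aggregates regional biomass,
#' and runs the percentile-permutation / krill-scenario sensitivity
#' analysis. Deterministic for a fixed configuration.
#'
#' @param config a [pipeline_config()]
#' @return list with `ts_table`, `composition`, `cells` (per-cell
#'   densities and biomass, g m^-2), `point_totals` (region x taxa-set
#'   totals at the configured statistic), `sensitivity` (a
#'   [run_sensitivity()] summary), `mask_counts`, and `truth` when the
#'   grid was simulated
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  medium <- config$medium
  tax <- if (is.null(config$taxon_table)) scotia_sea_taxa(medium$density_water)
         else read_taxon_table(config$taxon_table, medium$density_water)
  profiles <- tax$profiles; stats <- tax$stats
  fish_taxa <- names(profiles)[vapply(profiles, function(p)
    p$model != "SDWBA", logical(1))]

  # community composition
  if (is.null(config$net_samples)) {
    gradient <- default_sst_gradient(profiles)
    net <- simulate_net_samples(config$n_stations, gradient,
                                seed = .stage_seed(config$seed, "net"))
  } else {
    net <- utils::read.csv(config$net_samples, stringsAsFactors = FALSE)
  }
  composition <- group_mean_abundance(net, fish_taxa)

  # grid
  truth <- NULL
  if (is.null(config$grid)) {
    sim <- simulate_survey_grid(profiles, stats,
                                if (is.null(config$net_samples))
                                  gradient_composition(gradient)
                                else composition,
                                medium = medium,
                                sl_statistic = config$sl_statistic,
                                noise_sd = config$noise_sd,
                                aspect_ratio = config$aspect_ratio,
                                seed = .stage_seed(config$seed, "grid"))
    grid <- sim$grid; truth <- sim$truth
  } else {
    grid <- read_grid(config$grid)
  }

  ts_tab <- build_ts_table(profiles, stats, medium,
                           aspect_ratio = config$aspect_ratio,
                           seed = .stage_seed(config$seed, "sdwba"))

  # point estimate at the configured statistic
  stat <- config$sl_statistic
  sig <- stats::setNames(ts_to_sigma_bs(ts_tab[[stat]]), ts_tab$taxon)[fish_taxa]
  wgt <- vapply(fish_taxa, function(nm)
    weight_at_length(list(a = profiles[[nm]]$lw_a,
                          b = profiles[[nm]]$lw_b),
                     stats[[nm]][[stat]]), numeric(1))

  bin <- sst_bin_index(grid$sst, attr(composition, "edges"))
  empty_bin <- !grid$shelf & !is.na(bin) &
    attr(composition, "n_samples")[ifelse(is.na(bin), 1L, bin)] == 0
  usable <- !grid$shelf & !is.na(bin) & !empty_bin
  nasc <- backtransform_nasc(grid$log_e_nasc)
  rho <- matrix(NA_real_, nrow(grid), length(fish_taxa),
                dimnames = list(NULL, fish_taxa))
  n_zero_denominator <- 0L
  for (i in which(usable)) {
    p <- partition_backscatter(composition[bin[i], ], sig)
    if (!is.null(attr(p, "reason"))) {
      n_zero_denominator <- n_zero_denominator + 1L
      next
    }
    rho[i, ] <- areal_density(nasc[i], p, sig)
  }
  biomass <- sweep(rho, 2, wgt, `*`)
  cells <- data.frame(cell = grid$cell, lat = grid$lat, lon = grid$lon,
                      sst = grid$sst, area_km2 = cell_area(grid$lat),
                      usable = usable)
  cells <- cbind(cells, as.data.frame(biomass))

  taxa_sets <- list(all_fish = fish_taxa,
                    myctophids = intersect(myctophid_codes(), fish_taxa))
  point_totals <- list()
  for (r in names(config$regions)) for (tsn in names(taxa_sets)) {
    agg <- aggregate_region(cells, taxa_sets[[tsn]],
                            region = config$regions[[r]],
                            mask = usable)
    point_totals[[paste(r, tsn, sep = ".")]] <- agg
  }

  sens <- run_sensitivity(grid, composition, profiles, stats, medium,
                          n_draws = config$n_draws,
                          seed = .stage_seed(config$seed, "draws"),
                          krill_densities = config$krill_densities,
                          regions = config$regions,
                          taxa_sets = taxa_sets,
                          aspect_ratio = config$aspect_ratio)

  # shelf + sst_out_of_range + empty_bin + usable == total_cells;
  # zero_denominator flags a subset of the usable cells
  mask_counts <- c(total_cells = nrow(grid),
                   shelf = sum(grid$shelf),
                   sst_out_of_range = sum(!grid$shelf & is.na(bin)),
                   empty_bin = sum(empty_bin),
                   zero_denominator = n_zero_denominator,
                   usable = sum(usable))

  out <- list(ts_table = ts_tab, composition = composition, cells = cells,
              point_totals = point_totals, sensitivity = sens,
              mask_counts = mask_counts, truth = truth, config = config)
  if (!is.null(config$out_dir)) .write_pipeline_outputs(out, config$out_dir)
  out
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$cells, file.path(out_dir, "cell_biomass.csv"),
                   row.names = FALSE)
  sens <- result$sensitivity
  summary <- list(
    point_totals = result$point_totals,
    sensitivity = lapply(seq_len(nrow(sens)), function(i) as.list(sens[i, ])),
    mask_counts = as.list(result$mask_counts),
    config = list(sl_statistic = result$config$sl_statistic,
                  n_draws = result$config$n_draws,
                  krill_densities = result$config$krill_densities,
                  seed = result$config$seed,
                  noise_sd = result$config$noise_sd,
                  aspect_ratio = result$config$aspect_ratio))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
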