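EARTH_RADIUS_KM <- 6371

#' Area of a latitude-longitude grid cell
#'
#' Spherical cap-band formula for a square cell of the given angular
#' resolution centred at `lat_center`:
#' \deqn{A = R^2 \, \Delta\lambda \, (\sin\varphi_2 - \sin\varphi_1)}
#' with R = 6371 km. At 0.25 degree aggregation the spherical Earth model
#' is accurate to well below the precision of the biomass totals.
#'
#' @param lat_center cell-centre latitude, degrees (vectorised)
#' @param resolution cell edge, degrees
#' @return area, km2
#' @examples
#' cell_area(0) # ~773 km2
#' @export
cell_area <- function(lat_center, resolution = 0.25) {
  if (any(abs(lat_center) > 90)) stop("|lat| must be <= 90")
  rad <- pi / 180
  phi1 <- pmax(lat_center - resolution / 2, -90) * rad
  phi2 <- pmin(lat_center + resolution / 2, 90) * rad
  EARTH_RADIUS_KM^2 * (resolution * rad) * (sin(phi2) - sin(phi1))
}

#' Cell biomass from areal density
#'
#' biomass_i = rho_i * W_i, with the weight evaluated at the same length
#' statistic as the TS used to obtain rho (length-consistency across the
#' acoustic and weight chains).
#'
#' @param rho_a per-taxon areal densities, ind. m^-2 (named)
#' @param weights per-taxon individual weights, g (named; must cover every
#'   taxon with positive density)
#' @return per-taxon biomass, g m^-2
#' @export
cell_biomass <- function(rho_a, weights) {
  need <- names(rho_a)[!is.na(rho_a) & rho_a > 0]
  miss <- setdiff(need, names(weights))
  if (length(miss) > 0)
    stop("missing weight for taxa: ", paste(miss, collapse = ", "))
  w <- weights[names(rho_a)]
  out <- rho_a * as.numeric(w)
  out[!is.na(rho_a) & rho_a == 0] <- 0
  names(out) <- names(rho_a)
  out
}

#' Region definitions
#'
#' Named rectangular (lat/lon box) region masks. The Southern Ocean is the
#' region south of 50 degrees S; the Scotia Sea is approximated by boxes
#' covering CCAMLR subareas 48.2 and 48.3 (approximate polygons are a
#' configuration input here, not an assertion of the official geodesy).
#'
#' @return named list of regions, each a list of boxes with `lat` and
#'   `lon` ranges
#' @export
default_regions <- function() {
  list(
    southern_ocean = list(list(lat = c(-90, -50), lon = c(-180, 180))),
    scotia_sea = list(list(lat = c(-64, -59), lon = c(-30, -20)),   # ~48.2
                      list(lat = c(-59, -50), lon = c(-42, -20))))  # ~48.3
}

#' Cell membership of a region
#'
#' @param lat,lon cell-centre coordinates, degrees (vectorised)
#' @param region one element of [default_regions()]
#' @return logical vector
#' @export
in_region <- function(lat, lon, region) {
  hit <- rep(FALSE, length(lat))
  for (box in region) {
    hit <- hit | (lat >= box$lat[1] & lat <= box$lat[2] &
                    lon >= box$lon[1] & lon <= box$lon[2])
  }
  hit
}

#' Aggregate cell biomass to a regional total
#'
#' Sums per-cell biomass surfaces over a region mask, converting
#' g m^-2 x km2 to megatonnes (1 g m^-2 = 1000 t km^-2; 1 Mt = 1e6 t).
#'
#' @param cells data.frame with columns `lat`, `lon`, `area_km2`, plus one
#'   biomass column (g m^-2) per taxon
#' @param taxa taxa to include in the total (e.g. all fish, or the
#'   myctophid subset)
#' @param region region polygon list (see [default_regions()]); NULL means
#'   every cell
#' @param mask optional additional logical mask over rows of `cells`
#'   (e.g. shelf exclusion)
#' @return list with `total_mt`, `area_km2` (area of the contributing
#'   cells) and `n_cells`
#' @export
aggregate_region <- function(cells, taxa, region = NULL, mask = NULL) {
  miss <- setdiff(taxa, names(cells))
  if (length(miss) > 0)
    stop("missing biomass column(s): ", paste(miss, collapse = ", "))
  keep <- rep(TRUE, nrow(cells))
  if (!is.null(region)) keep <- keep & in_region(cells$lat, cells$lon, region)
  if (!is.null(mask)) keep <- keep & mask
  if (!any(keep)) {
    warning("empty region")
    return(list(total_mt = 0, area_km2 = 0, n_cells = 0L))
  }
  sub <- cells[keep, , drop = FALSE]
  gm2 <- rowSums(sub[, taxa, drop = FALSE], na.rm = TRUE)
  # 1 g m^-2 = 1 t km^-2; x km2 -> t; /1e6 -> Mt
  total_mt <- sum(gm2 * sub$area_km2) / 1e6
  list(total_mt = total_mt, area_km2 = sum(sub$area_km2),
       n_cells = sum(keep))
}
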