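# m2 per (nautical mile)^2 spreading constant of the NASC definition
# (1852 m per nautical mile, exact)
NASC_CONSTANT <- 4 * pi * 1852^2

#' Back-transform log_e NASC
#'
#' Plain exponential back-transform of predicted log_e NASC; no
#' retransformation (smearing) bias correction is applied.
#'
#' @param log_e_nasc natural-log NASC (vectorised)
#' @return NASC, m2 nmi^-2
#' @export
backtransform_nasc <- function(log_e_nasc) {
  if (any(!is.finite(log_e_nasc))) stop("log_e_nasc must be finite")
  exp(log_e_nasc)
}

#' Partition backscatter among taxa
#'
#' The proportion of total backscatter attributable to each taxon:
#' \deqn{P_i = N_i \sigma_{bs,i} / \sum_j N_j \sigma_{bs,j}}
#' where N is the (relative) abundance vector and sigma the linear
#' backscattering cross-sections. Scale-invariant in N.
#'
#' @param n_abundance abundance vector N (>= 0)
#' @param sigma_bs backscattering cross-sections, m2 (>= 0)
#' @return named numeric vector P summing to 1, or all-NA with attribute
#'   `reason = "zero_backscatter"` when the denominator vanishes
#' @export
partition_backscatter <- function(n_abundance, sigma_bs) {
  if (length(n_abundance) != length(sigma_bs))
    stop("abundance and sigma_bs lengths differ")
  if (any(n_abundance < 0) || any(sigma_bs < 0))
    stop("abundances and cross-sections must be non-negative")
  tot <- n_abundance * sigma_bs
  s <- sum(tot)
  if (s <= 0) {
    out <- rep(NA_real_, length(tot))
    names(out) <- names(n_abundance)
    attr(out, "reason") <- "zero_backscatter"
    return(out)
  }
  tot / s
}

#' Areal density from partitioned NASC
#'
#' Converts a cell's NASC and partition vector into per-taxon areal
#' densities (individuals per m2):
#' \deqn{\rho_{a,i} = NASC \; P_i / (\sigma_{bs,i} \; 4 \pi \; 1852^2)}
#'
#' @param nasc NASC, m2 nmi^-2 (scalar)
#' @param p partition vector (sums to 1)
#' @param sigma_bs cross-sections, m2; must be positive wherever `p > 0`
#' @return areal densities, ind. m^-2 (same names as `p`)
#' @export
areal_density <- function(nasc, p, sigma_bs) {
  if (length(p) != length(sigma_bs)) stop("p and sigma_bs lengths differ")
  if (nasc < 0) stop("nasc must be >= 0")
  bad <- !is.na(p) & p > 0 & sigma_bs <= 0
  if (any(bad))
    stop("unpartitionable: positive proportion with zero cross-section for ",
         paste(names(p)[bad], collapse = ", "))
  out <- ifelse(is.na(p) | p == 0, ifelse(is.na(p), NA_real_, 0),
                nasc * p / (sigma_bs * NASC_CONSTANT))
  names(out) <- names(p)
  out
}
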