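#' Fit a length-weight regression
#'
#' Ordinary least squares of log(W) on log(SL); coefficients are returned on
#' the natural scale of the power law W = a SL^b (W in g, SL in mm). No
#' back-transformation bias correction is applied by default, matching
#' standard fisheries practice for point prediction; set
#' `bias_correction = TRUE` to multiply `a` by exp(s^2/2).
#'
#' @param sl standard lengths, mm
#' @param weight wet weights, g
#' @param bias_correction apply the lognormal back-transform correction?
#' @return list of class `length_weight_fit` with elements `a`, `b`, `n`,
#'   `r_squared`, `n_rejected`
#' @examples
#' fit <- fit_length_weight(c(40, 50, 60, 70), 1e-5 * c(40, 50, 60, 70)^3)
#' c(fit$a, fit$b) # 1e-5, 3
#' @export
fit_length_weight <- function(sl, weight, bias_correction = FALSE) {
  if (length(sl) != length(weight)) stop("sl and weight lengths differ")
  ok <- is.finite(sl) & is.finite(weight) & sl > 0 & weight > 0
  n_rejected <- sum(!ok)
  if (n_rejected > 0)
    message(n_rejected, " record(s) with non-positive or missing values rejected")
  sl <- sl[ok]; weight <- weight[ok]
  if (length(sl) < 3) stop("need at least 3 positive (sl, weight) records")
  fit <- stats::lm(log(weight) ~ log(sl))
  b <- unname(stats::coef(fit)[2])
  a <- exp(unname(stats::coef(fit)[1]))
  if (bias_correction) a <- a * exp(stats::sigma(fit)^2 / 2)
  if (b < 2 || b > 4)
    warning(sprintf("length-weight exponent b = %.2f outside plausible 2-4 window", b))
  structure(list(a = a, b = b, n = length(sl),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_rejected = n_rejected),
            class = "length_weight_fit")
}

#' Predicted weight at length
#'
#' W = a SL^b from a length-weight fit (or any list with elements `a`, `b`).
#'
#' @param fit a [fit_length_weight()] result or `list(a =, b =)`
#' @param sl standard length, mm (vectorised)
#' @return weight, g
#' @export
weight_at_length <- function(fit, sl) {
  if (any(sl <= 0)) stop("sl must be > 0")
  fit$a * sl^fit$b
}

#' Standard-length percentiles
#'
#' The four length statistics (25th percentile, arithmetic mean, median,
#' 75th percentile) of a sample of standard lengths. Percentiles use linear
#' interpolation between order statistics (R's default quantile type 7);
#' the convention is fixed here so tabulated TS values are reproducible.
#'
#' @param sl standard lengths, mm
#' @return a [length_stats()] object
#' @export
length_percentiles <- function(sl) {
  sl <- sl[is.finite(sl)]
  if (length(sl) == 0) stop("no finite lengths supplied")
  q <- stats::quantile(sl, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  length_stats(p25 = q[1], mean = mean(sl), median = q[2], p75 = q[3],
               n = length(sl))
}

#' Assign tissue density by measurement or group mean
#'
#' Taxa with a measured mean tissue density keep it; unmeasured taxa are
#' assigned the unweighted mean of all measured taxa in the same
#' swimbladder group (gas-bearing or non-gas).
#'
#' @param taxon taxon code
#' @param measured named numeric vector of measured mean densities, kg/m3
#' @param gas_bearing is the taxon gas-bearing?
#' @param group_membership named logical vector saying, for each measured
#'   taxon, whether it is gas-bearing
#' @return list with `tissue_density` (kg/m3) and `provenance`
#'   ("measured" or "group_mean")
#' @export
assign_tissue_density <- function(taxon, measured, gas_bearing,
                                  group_membership) {
  if (taxon %in% names(measured))
    return(list(tissue_density = unname(measured[[taxon]]),
                provenance = "measured"))
  if (!setequal(names(measured), names(group_membership)))
    stop("group_membership must cover exactly the measured taxa")
  grp <- measured[group_membership[names(measured)] == gas_bearing]
  if (length(grp) == 0)
    stop("no measured taxa in the ",
         if (gas_bearing) "gas-bearing" else "non-gas", " group")
  list(tissue_density = mean(unlist(grp)), provenance = "group_mean")
}

#' E. antarctica size class
#'
#' Electrona antarctica loses swimbladder gas with size: individuals below
#' 51.378 mm standard length are treated as gas-bearing (PS model), those
#' at or above the threshold as non-gas (FC model). The threshold is
#' inclusive on the large side.
#'
#' @param sl standard length, mm (vectorised)
#' @param threshold split point, mm
#' @return character vector: "gas_small" or "nongas_large"
#' @examples
#' electrona_class(c(46, 74)) # "gas_small" "nongas_large"
#' @export
electrona_class <- function(sl, threshold = 51.378) {
  if (any(sl <= 0)) stop("sl must be > 0")
  ifelse(sl < threshold, "gas_small", "nongas_large")
}
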