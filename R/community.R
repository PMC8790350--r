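#' SST bin index
#'
#' Assigns sea-surface temperatures to the seven 1-degree bins spanning -1
#' to 6 degrees C. Bins are left-closed (`[-1,0), [0,1), ..., [5,6]`) with
#' the final upper edge inclusive. Values outside the range return NA.
#'
#' @param sst degrees C (vectorised)
#' @param edges bin edges (default -1:6)
#' @return integer bin index (1-based) or NA
#' @export
sst_bin_index <- function(sst, edges = -1:6) {
  idx <- findInterval(sst, edges, rightmost.closed = TRUE)
  idx[idx == 0 | idx == length(edges) | !is.finite(sst)] <- NA_integer_
  idx
}

#' Labels of the SST bins
#' @param edges bin edges
#' @return character vector like "[-1,0)"
#' @export
sst_bin_labels <- function(edges = -1:6) {
  n <- length(edges) - 1
  vapply(seq_len(n), function(i)
    sprintf("[%g,%g%s", edges[i], edges[i + 1], if (i == n) "]" else ")"),
    character(1))
}

#' Bin net samples by sea-surface temperature
#'
#' Splits net samples into the 1-degree SST groups. Samples outside the
#' -1 to 6 degree range are excluded and counted.
#'
#' @param samples data.frame with a column `sst` and one abundance column
#'   per taxon (any additional columns such as `station` are carried along)
#' @param edges bin edges
#' @return list with `binned` (the samples plus a `bin` column, exclusions
#'   dropped) and `n_excluded`
#' @export
bin_by_sst <- function(samples, edges = -1:6) {
  if (!"sst" %in% names(samples)) stop("samples need an 'sst' column")
  idx <- sst_bin_index(samples$sst, edges)
  n_excluded <- sum(is.na(idx))
  keep <- samples[!is.na(idx), , drop = FALSE]
  keep$bin <- idx[!is.na(idx)]
  list(binned = keep, n_excluded = n_excluded)
}

#' Mean community composition per SST bin
#'
#' Arithmetic mean abundance of every taxon within each SST bin. Because
#' the partitioning equation normalises the composition vector, relative
#' abundances are sufficient; absolute standardised densities are equally
#' acceptable.
#'
#' @param samples data.frame of net samples (`sst` plus taxon columns)
#' @param taxa character vector naming the taxon columns
#' @param edges SST bin edges
#' @return object of class `composition_table`: a matrix bins x taxa of
#'   mean abundances, with attributes `n_samples` (per bin) and
#'   `n_excluded`
#' @export
group_mean_abundance <- function(samples, taxa, edges = -1:6) {
  miss <- setdiff(taxa, names(samples))
  if (length(miss) > 0)
    stop("missing taxon column(s): ", paste(miss, collapse = ", "))
  if (any(sapply(samples[taxa], function(x) any(x < 0, na.rm = TRUE))))
    stop("negative abundances")
  bb <- bin_by_sst(samples, edges)
  nb <- length(edges) - 1
  if (nrow(bb$binned) == 0) stop("all samples fall outside the SST range")
  mat <- matrix(NA_real_, nrow = nb, ncol = length(taxa),
                dimnames = list(sst_bin_labels(edges), taxa))
  nsamp <- integer(nb)
  for (b in seq_len(nb)) {
    rows <- bb$binned[bb$binned$bin == b, taxa, drop = FALSE]
    nsamp[b] <- nrow(rows)
    if (nrow(rows) > 0) mat[b, ] <- colMeans(rows)
  }
  structure(mat, n_samples = nsamp, n_excluded = bb$n_excluded,
            edges = edges, class = c("composition_table", "matrix"))
}

#' Composition vector for a grid cell
#'
#' Returns the mean-abundance vector of the SST bin the cell falls in.
#' Cells outside the -1 to 6 degree range, or in a bin with no net samples,
#' are unusable and return NA with a reason code.
#'
#' @param sst cell sea-surface temperature, degrees C
#' @param table a [group_mean_abundance()] result
#' @return list with `composition` (named numeric or NULL) and `reason`
#'   ("ok", "sst_out_of_range" or "empty_bin")
#' @export
composition_for_cell <- function(sst, table) {
  stopifnot(inherits(table, "composition_table"))
  idx <- sst_bin_index(sst, attr(table, "edges"))
  if (is.na(idx))
    return(list(composition = NULL, reason = "sst_out_of_range"))
  if (attr(table, "n_samples")[idx] == 0)
    return(list(composition = NULL, reason = "empty_bin"))
  list(composition = table[idx, ], reason = "ok")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("SST-binned mean community composition\n")
  y <- x; attributes(y) <- attributes(x)[c("dim", "dimnames")]
  print(cbind(round(y, 3), n = attr(x, "n_samples")))
  cat(attr(x, "n_excluded"), "sample(s) outside the SST range excluded\n")
  invisible(x)
}
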