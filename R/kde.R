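#' Normal-reference bandwidth
#'
#' The rule-of-thumb bandwidth used for the 2D kernels, applied per axis:
#' `4 * 1.06 * min(sd, IQR/1.34) * n^(-1/5)`, with the sample standard
#' deviation (n-1 denominator) and linear-interpolation ("type 7")
#' quartiles. Delegates to [MASS::bandwidth.nrd()], whose definition this
#' is, and turns the degenerate all-equal case into an informative error.
#'
#' @param values Numeric vector (`NA`s dropped), at least two distinct values.
#' @return A positive bandwidth on the scale of `values`.
#' @examples
#' nrd_bandwidth(1:10)  # ~ 8.10
#' @export
nrd_bandwidth <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop_wkde("need >= 2 values for a bandwidth")
  h <- MASS::bandwidth.nrd(values)
  if (!is.finite(h) || h <= 0)
    stop_wkde("degenerate bandwidth (values nearly constant); ",
              "remove the invariant CpG before kernel fitting")
  h
}

new_density_kernel <- function(cpg_id, density, bandwidths, n = NA_integer_) {
  structure(list(cpg_id = cpg_id, density = density,
                 bandwidths = bandwidths, n = n),
            class = "density_kernel")
}

#' @export
print.density_kernel <- function(x, ...) {
  cat(sprintf("density kernel for %s: %d x %d grid, bandwidths (age %.3g, DNAm %.3g), n = %s\n",
              x$cpg_id, nrow(x$density), ncol(x$density),
              x$bandwidths[1], x$bandwidths[2], x$n))
  invisible(x)
}

#' Fit a 2D density kernel for one CpG
#'
#' Estimates the bivariate Gaussian kernel density of (age, DNAm) training
#' pairs on the evaluation grid, via [MASS::kde2d()]. At grid point
#' (age g_i, DNAm g_j) the density is
#' `(1/n) * sum_l dnorm(g_i - age_l, sd = h_age/4) * dnorm(g_j - dnam_l, sd = h_dnam/4)`;
#' the bandwidth argument is quartered internally, matching the kde2d
#' convention, and defaults to [nrd_bandwidth()] per axis. The returned
#' matrix is stored with DNAm on the rows and age on the columns.
#'
#' @param ages Ages in years.
#' @param dnam DNAm in percent, same length as `ages`; pairs with a missing
#'   member are dropped.
#' @param grid A [grid_spec()].
#' @param bandwidths Optional fixed `c(h_age, h_dnam)`, both > 0; `NULL`
#'   selects the normal-reference rule per axis.
#' @param cpg_id Identifier stored in the kernel.
#' @return A `"density_kernel"`.
#' @export
fit_cpg_kernel <- function(ages, dnam, grid = grid_spec(), bandwidths = NULL,
                           cpg_id = "cpg") {
  stopifnot(length(ages) == length(dnam))
  ok <- !is.na(ages) & !is.na(dnam)
  ages <- ages[ok]; dnam <- dnam[ok]
  n <- length(ages)
  if (n < 2) stop_wkde("CpG '", cpg_id, "': need >= 2 complete (age, DNAm) pairs")
  if (is.null(bandwidths)) {
    bandwidths <- tryCatch(c(nrd_bandwidth(ages), nrd_bandwidth(dnam)),
                           error = function(e)
                             stop_wkde("CpG '", cpg_id, "': ", conditionMessage(e)))
  }
  if (length(bandwidths) != 2 || any(!is.finite(bandwidths)) || any(bandwidths <= 0))
    stop_wkde("CpG '", cpg_id, "': bandwidths must be two positive numbers")
  fit <- MASS::kde2d(ages, dnam, h = bandwidths, n = grid$n_points,
                     lims = c(grid$age_min, grid$age_max,
                              grid$dnam_min, grid$dnam_max))
  density <- t(fit$z)  # rows = DNAm, columns = age
  dimnames(density) <- list(grid_dnam(grid), grid_ages(grid))
  new_density_kernel(cpg_id, density, bandwidths, n = n)
}

#' Normalize a kernel by the training age histogram
#'
#' Divides each age column of the density matrix by the number of training
#' samples with that rounded age, ignoring samples older than `cap` years
#' (whose scarcity would otherwise blow up the corrected densities).
#' Columns with zero count are set to zero density, which excludes those
#' ages from any later argmax.
#'
#' @param kernel A `"density_kernel"` fitted on `samples`.
#' @param samples Sample table with the training ages.
#' @param cap Maximum age (years) considered for the histogram.
#' @param grid The [grid_spec()] the kernel was fitted on.
#' @return The normalized `"density_kernel"`.
#' @export
normalize_kernel_by_age_histogram <- function(kernel, samples, cap = 85,
                                              grid = grid_spec()) {
  ages <- samples$age[samples$age <= cap]
  nodes <- grid_ages(grid)
  counts <- tabulate(match(round_half_up(ages), nodes), nbins = length(nodes))
  if (all(counts == 0)) stop_wkde("no training samples at or below the age cap")
  density <- kernel$density
  nz <- counts > 0
  density[, nz] <- sweep(density[, nz, drop = FALSE], 2, counts[nz], `/`)
  density[, !nz] <- 0
  kernel$density <- density
  kernel
}
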