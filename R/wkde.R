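#' Fit a kernel-density epigenetic clock
#'
#' Builds a probabilistic age predictor from a percent-scale methylation
#' matrix and sample ages. For every signature CpG a 2D kernel density of
#' chronological age versus DNAm is estimated on the evaluation grid
#' (101 x 101 by default). Training-set age imbalance is countered either
#' by uniform-age subsampling (the default: 15 samples per 5-year bin, 19
#' bins) or, alternatively, by dividing each kernel by the training age
#' histogram -- the two corrections are mutually exclusive. All CpG weights
#' start at 1; [optimize_weights()] tunes them afterwards.
#'
#' @param betas Percent-scale methylation matrix (CpG x sample), as from
#'   [read_beta_matrix()] or [simulate_cohort()].
#' @param samples Sample table with `sample_id` and `age` covering the
#'   matrix columns.
#' @param signature Character vector of CpG ids to use. `NULL` selects CpGs
#'   by [age_correlation()] with `r2 > r2_threshold`.
#' @param r2_threshold Selection threshold when `signature` is `NULL`.
#' @param subsample Use uniform-age subsampling for kernel fitting.
#' @param per_bin,bin_width Subsampling parameters, see
#'   [uniform_age_subsample()].
#' @param histogram_normalize Use age-histogram normalization instead of
#'   subsampling.
#' @param hist_age_cap Age cap (years) for the histogram counts.
#' @param grid Evaluation [grid_spec()].
#' @param bandwidths Optional fixed `c(h_age, h_dnam)` shared by all CpGs;
#'   default: normal-reference rule per CpG and axis.
#' @param seed Seed for the subsampling draw.
#' @return An object of class `"wkde"`: list with elements `grid`,
#'   `kernels` (named list of `"density_kernel"`), `weights` (named, all 1
#'   after fitting) and `provenance`.
#' @examples
#' cohort <- simulate_cohort(n_samples = 250, n_cpgs = 6, n_informative = 5,
#'                           seed = 1)
#' clock <- wkde(cohort$betas, cohort$samples, r2_threshold = 0.6, seed = 1)
#' clock
#' @seealso [predict.wkde()], [optimize_weights()], [save_wkde()]
#' @export
wkde <- function(betas, samples, signature = NULL, r2_threshold = 0.7,
                 subsample = TRUE, per_bin = 15, bin_width = 5,
                 histogram_normalize = FALSE, hist_age_cap = 85,
                 grid = grid_spec(), bandwidths = NULL, seed = NULL) {
  validate_beta_matrix(betas)
  samples <- validate_sample_table(samples)
  if (subsample && histogram_normalize)
    stop_wkde("uniform subsampling and histogram normalization are ",
              "alternative corrections; enable at most one")
  samples <- samples[samples$sample_id %in% colnames(betas), , drop = FALSE]
  if (nrow(samples) == 0) stop_wkde("no overlap between matrix and sample table")

  selected <- is.null(signature)
  if (selected) {
    r2 <- age_correlation(betas, samples)
    signature <- select_signature(r2, r2_threshold)
  } else {
    missing_cpgs <- setdiff(signature, rownames(betas))
    if (length(missing_cpgs) > 0)
      stop_wkde("signature CpG(s) absent from the matrix: ",
                paste(missing_cpgs, collapse = ", "))
  }

  fit_samples <- if (subsample)
    uniform_age_subsample(samples, bin_width = bin_width, per_bin = per_bin,
                          seed = seed)
  else samples
  cols <- match(fit_samples$sample_id, colnames(betas))

  kernels <- lapply(signature, function(cg) {
    k <- fit_cpg_kernel(fit_samples$age, betas[cg, cols], grid = grid,
                        bandwidths = bandwidths, cpg_id = cg)
    if (histogram_normalize)
      k <- normalize_kernel_by_age_histogram(k, fit_samples,
                                             cap = hist_age_cap, grid = grid)
    k
  })
  names(kernels) <- signature
  weights <- stats::setNames(rep(1, length(signature)), signature)

  model <- new_wkde(
    grid = grid, kernels = kernels, weights = weights,
    provenance = list(n_samples = nrow(samples),
                      n_kernel_samples = nrow(fit_samples),
                      seed = seed,
                      r2_threshold = if (selected) r2_threshold else NA,
                      subsample = subsample,
                      histogram_normalize = histogram_normalize))
  validate_wkde(model)
}

new_wkde <- function(grid, kernels, weights, provenance = list(), ga = NULL) {
  structure(list(grid = grid, kernels = kernels, weights = weights,
                 provenance = provenance, ga = ga),
            class = "wkde")
}

#' Validate a wkde model's invariants
#'
#' Checks kernel/weight alignment by CpG id, weight bounds \[-10, 10\],
#' grid dimensions and non-negative densities with at least one positive
#' entry per kernel.
#'
#' @param model A `"wkde"` object.
#' @return The model, invisibly on success.
#' @export
validate_wkde <- function(model) {
  stopifnot(inherits(model, "wkde"))
  n <- model$grid$n_points
  if (length(model$kernels) == 0) stop_wkde("model has no kernels")
  if (!identical(names(model$kernels), names(model$weights)))
    stop_wkde("kernels and weights are not aligned by CpG id")
  if (any(!is.finite(model$weights)) ||
      any(model$weights < -10 | model$weights > 10))
    stop_wkde("weights must lie within [-10, 10]")
  for (k in model$kernels) {
    if (!all(dim(k$density) == c(n, n)))
      stop_wkde("kernel for ", k$cpg_id, " is not ", n, " x ", n)
    if (any(k$density < 0) || !any(k$density > 0))
      stop_wkde("kernel for ", k$cpg_id,
                " must be non-negative with a positive entry")
  }
  invisible(model)
}

#' @export
print.wkde <- function(x, ...) {
  cat("Weighted 2D kernel density clock\n")
  print(x$grid)
  cat(sprintf("signature: %d CpGs; weights in [%.3g, %.3g]%s\n",
              length(x$kernels), min(x$weights), max(x$weights),
              if (is.null(x$ga)) " (unoptimized)" else " (GA-optimized)"))
  if (!is.null(x$provenance$n_kernel_samples))
    cat(sprintf("kernels fitted on %d samples (of %d)\n",
                x$provenance$n_kernel_samples, x$provenance$n_samples))
  invisible(x)
}

#' @export
summary.wkde <- function(object, ...) {
  out <- data.frame(
    cpg_id = names(object$kernels),
    weight = unname(object$weights),
    h_age = vapply(object$kernels, function(k) k$bandwidths[1], 0),
    h_dnam = vapply(object$kernels, function(k) k$bandwidths[2], 0),
    row.names = NULL)
  class(out) <- c("summary.wkde", "data.frame")
  out
}

#' @export
coef.wkde <- function(object, ...) object$weights

#' Plot a fitted kernel
#'
#' Draws the density map of one signature CpG with age on the x-axis and
#' DNAm on the y-axis.
#'
#' @param x A `"wkde"` model.
#' @param cpg CpG id or index.
#' @param ... Passed to [graphics::image()].
#' @export
plot.wkde <- function(x, cpg = 1, ...) {
  k <- x$kernels[[cpg]]
  graphics::image(grid_ages(x$grid), grid_dnam(x$grid), t(k$density),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "age (years)", ylab = "DNAm (%)",
                  main = k$cpg_id, ...)
  invisible(x)
}

#' Export kernels in long format for plotting
#'
#' @param model A `"wkde"` model.
#' @return data.frame with columns cpg_id, age, dnam, density.
#' @export
kernel_long_format <- function(model) {
  do.call(rbind, lapply(model$kernels, function(k) {
    data.frame(cpg_id = k$cpg_id,
               age = rep(grid_ages(model$grid), each = model$grid$n_points),
               dnam = rep(grid_dnam(model$grid), model$grid$n_points),
               density = as.vector(k$density), row.names = NULL)
  }))
}
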