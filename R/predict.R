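#' Density row for a measured DNAm value
#'
#' Returns the kernel row at the grid node nearest to the measured DNAm
#' percentage (round-half-up on the default unit grid): a vector of one
#' density per age node.
#'
#' @param kernel A `"density_kernel"`.
#' @param dnam DNAm in percent; `NA` returns `NULL` so callers can skip
#'   the CpG.
#' @param grid The model's [grid_spec()].
#' @return Numeric vector of length `grid$n_points`, or `NULL` for missing
#'   input.
#' @export
density_row <- function(kernel, dnam, grid = grid_spec()) {
  if (is.na(dnam)) return(NULL)
  step <- grid_dnam_step(grid)
  idx <- floor((dnam - grid$dnam_min) / step + 0.5) + 1
  idx <- min(max(idx, 1L), grid$n_points)
  kernel$density[idx, ]
}

#' Joint density profile of a sample
#'
#' Sums the per-CpG density rows selected by the sample's DNAm values over
#' the age grid, optionally scaled by the per-CpG weights. CpGs with
#' missing DNAm are skipped and counted.
#'
#' @param model A `"wkde"` model.
#' @param sample_dnam Named vector of DNAm percentages (names = CpG ids).
#' @param use_weights Multiply each row by its CpG weight.
#' @return Numeric vector over the age grid with attribute `n_cpgs_used`.
#' @export
joint_density_profile <- function(model, sample_dnam, use_weights = TRUE) {
  profile <- numeric(model$grid$n_points)
  n_used <- 0L
  for (cg in names(model$kernels)) {
    dn <- if (cg %in% names(sample_dnam)) sample_dnam[[cg]] else NA_real_
    row <- density_row(model$kernels[[cg]], dn, model$grid)
    if (is.null(row)) next
    profile <- profile + if (use_weights) model$weights[[cg]] * row else row
    n_used <- n_used + 1L
  }
  if (n_used == 0L)
    stop_wkde("all signature CpGs are missing for this sample")
  attr(profile, "n_cpgs_used") <- n_used
  profile
}

#' Predicted age of a sample
#'
#' The age-grid node maximizing the (weighted) joint density profile; ties
#' are broken toward the smallest age, so the prediction is deterministic.
#' The argmax is taken on the raw weighted sum -- negative weighted
#' densities are not floored here.
#'
#' @inheritParams joint_density_profile
#' @return Age in years (a grid node).
#' @export
predict_age <- function(model, sample_dnam, use_weights = TRUE) {
  profile <- joint_density_profile(model, sample_dnam, use_weights)
  if (all(profile == 0))
    stop_wkde("joint density profile is identically zero")
  grid_ages(model$grid)[which.max(profile)]
}

#' Age-probability vector of a sample
#'
#' Normalizes the joint density profile to sum 1. When weighting produces
#' negative entries they are floored at zero before renormalization and
#' the result is flagged (`attr(p, "floored")`); the argmax reported by
#' [predict_age()] is unaffected by the flooring.
#'
#' @inheritParams joint_density_profile
#' @return Probability vector over the age grid (sums to 1), with
#'   attributes `floored` and `n_cpgs_used`.
#' @export
probability_vector <- function(model, sample_dnam, use_weights = TRUE) {
  profile <- joint_density_profile(model, sample_dnam, use_weights)
  n_used <- attr(profile, "n_cpgs_used")
  floored <- FALSE
  if (use_weights && any(profile < 0)) {
    profile[profile < 0] <- 0
    floored <- TRUE
  }
  total <- sum(profile)
  if (total <= 0)
    stop_wkde("profile has no positive mass after flooring negative entries")
  p <- as.vector(profile) / total
  attr(p, "floored") <- floored
  attr(p, "n_cpgs_used") <- n_used
  p
}

#' Interpolate a probability vector onto the 0.1-year grid
#'
#' Linear interpolation of the 101 age-probabilities onto ages 0, 0.1,
#' ..., 100 (1001 points, index x = 0..1000 with age = x/10). By default
#' the interpolated values are renormalized to a proper probability mass
#' function; `renormalize = FALSE` returns the raw interpolated values
#' (which pass through the knots).
#'
#' @param p Probability vector over integer ages 0..100.
#' @param renormalize Rescale to sum 1.
#' @return Numeric vector of length 1001.
#' @export
fine_probability <- function(p, renormalize = TRUE) {
  stopifnot(length(p) >= 2)
  knots <- seq(0, 100, length.out = length(p))
  f <- stats::approx(knots, p, xout = seq(0, 100, by = 0.1))$y
  if (renormalize) f <- f / sum(f)
  f
}

#' Variation score of an age-probability distribution
#'
#' Summarizes the spread of a sample's (unweighted) age-probability
#' distribution: after interpolating to 0.1-year resolution, the mean,
#' variance and standard deviation of the distribution are computed; the
#' standard deviation is the variation score, an estimate of how
#' heterogeneous the age signals of the signature CpGs are for this
#' sample. In `"consistent"` mode (default) the moments are taken under
#' the renormalized fine pmf: `mean = sum f(x) * (x/10)`,
#' `variance = sum f(x) * (x/10 - mean)^2`. The `"literal"` mode applies
#' 0.1 prefactors to the unrenormalized interpolated vector
#' (`mean = 0.1 * sum f(x) * x`, `variance = 0.1 * sum f(x) * (0.1 x - mean)^2`)
#' and is retained for comparison only -- its two formulas are on
#' different scales unless the vector happens to sum to 1.
#'
#' @param p Probability vector over integer ages (use the unweighted
#'   vector; [predict.wkde()] enforces this).
#' @param predicted_age Optional point prediction used to report the
#'   coverage interval `predicted_age +/- score`.
#' @param mode `"consistent"` or `"literal"`.
#' @return List with `mean`, `variance`, `variation_score` and, when
#'   `predicted_age` is given, `interval = c(lo, hi)`.
#' @export
variation_score <- function(p, predicted_age = NULL,
                            mode = c("consistent", "literal")) {
  mode <- match.arg(mode)
  x <- 0:1000
  if (mode == "consistent") {
    f <- fine_probability(p, renormalize = TRUE)
    m <- sum(f * (x / 10))
    v <- sum(f * (x / 10 - m)^2)
  } else {
    f <- fine_probability(p, renormalize = FALSE)
    m <- 0.1 * sum(f * x)
    v <- 0.1 * sum(f * (0.1 * x - m)^2)
  }
  score <- sqrt(v)
  out <- list(mean = m, variance = v, variation_score = score)
  if (!is.null(predicted_age))
    out$interval <- c(predicted_age - score, predicted_age + score)
  out
}

#' Fraction of samples covered by their prediction interval
#'
#' Fraction of predictions whose chronological age lies within
#' `predicted_age +/- variation_score`, i.e.
#' `|delta_age| <= variation_score`.
#'
#' @param results Prediction table from [predict.wkde()] with known
#'   chronological ages.
#' @return Fraction in \[0, 1\].
#' @export
coverage_fraction <- function(results) {
  if (NROW(results) == 0) stop_wkde("empty prediction table")
  if (anyNA(results$delta_age))
    stop_wkde("coverage needs chronological ages for every sample")
  mean(abs(results$delta_age) <= results$variation_score)
}

#' Predict epigenetic age, probabilities and variation scores
#'
#' Applies a fitted clock to new samples. Every signature CpG must be
#' present as a row of `newdata` (an error names any absent CpG); per-sample
#' missing values are skipped and counted. The variation score is always
#' computed from the unweighted probability vector, regardless of the
#' model's weights.
#'
#' @param object A `"wkde"` model.
#' @param newdata Percent-scale methylation matrix (CpG x sample).
#' @param samples Optional sample table supplying chronological ages for
#'   delta-age and coverage.
#' @param use_weights Use the model's CpG weights for the point prediction
#'   and probability vector.
#' @param mode Variation-score mode, see [variation_score()].
#' @param type `"table"` returns the per-sample summary data.frame;
#'   `"prob"` returns the matrix of age-probability vectors
#'   (ages x samples).
#' @param ... Unused.
#' @return See `type`. The table holds sample_id, predicted_age,
#'   chronological_age, delta_age, variation_score, interval_lo,
#'   interval_hi, n_cpgs_used and floored.
#' @export
predict.wkde <- function(object, newdata, samples = NULL, use_weights = TRUE,
                         mode = c("consistent", "literal"),
                         type = c("table", "prob"), ...) {
  mode <- match.arg(mode)
  type <- match.arg(type)
  validate_beta_matrix(newdata)
  absent <- setdiff(names(object$kernels), rownames(newdata))
  if (length(absent) > 0)
    stop_wkde("signature CpG(s) absent from input: ",
              paste(absent, collapse = ", "))
  ids <- colnames(newdata)
  ages <- rep(NA_real_, length(ids))
  if (!is.null(samples))
    ages <- samples$age[match(ids, samples$sample_id)]

  sig <- names(object$kernels)
  if (type == "prob") {
    pm <- vapply(ids, function(l) {
      dn <- stats::setNames(newdata[sig, l], sig)
      as.vector(probability_vector(object, dn, use_weights))
    }, numeric(object$grid$n_points))
    rownames(pm) <- grid_ages(object$grid)
    return(pm)
  }

  rows <- lapply(seq_along(ids), function(j) {
    dn <- stats::setNames(newdata[sig, ids[j]], sig)
    pred <- predict_age(object, dn, use_weights = use_weights)
    p_w <- probability_vector(object, dn, use_weights = use_weights)
    p_u <- if (use_weights) probability_vector(object, dn, use_weights = FALSE)
           else p_w
    vs <- variation_score(p_u, predicted_age = pred, mode = mode)
    data.frame(sample_id = ids[j], predicted_age = pred,
               chronological_age = ages[j],
               delta_age = pred - ages[j],
               variation_score = vs$variation_score,
               interval_lo = vs$interval[1], interval_hi = vs$interval[2],
               n_cpgs_used = attr(p_w, "n_cpgs_used"),
               floored = attr(p_w, "floored"))
  })
  do.call(rbind, rows)
}
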