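#' Multivariable linear regression clock
#'
#' Ordinary least squares of chronological age on the signature's DNAm
#' values: the conventional comparator for the kernel clock. Prediction is
#' `intercept + sum(slopes * DNAm)` and requires every signature CpG to be
#' measured.
#'
#' @param betas Percent-scale methylation matrix (CpG x sample).
#' @param samples Sample table with ages.
#' @param signature CpG ids used as predictors.
#' @return A `"linear_clock"` of kind `"multivariable"`.
#' @export
fit_multivariable_clock <- function(betas, samples, signature) {
  X <- t(betas[signature, samples$sample_id, drop = FALSE])
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  age <- samples$age[ok]
  if (nrow(X) < length(signature) + 1)
    stop_wkde("need at least ", length(signature) + 1, " complete samples")
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), age)
  if (fit$rank < length(signature) + 1) {
    dropped <- names(fit$coefficients)[is.na(fit$coefficients)]
    stop_wkde("collinear signature CpG(s): ", paste(dropped, collapse = ", "))
  }
  coefs <- fit$coefficients
  structure(list(kind = "multivariable", intercept = unname(coefs[1]),
                 slopes = coefs[-1], cpgs = signature),
            class = "linear_clock")
}

#' Averaged single-CpG regression clock
#'
#' Fits one simple regression of age on DNAm per signature CpG; the clock
#' prediction for a sample is the mean of the per-CpG predictions over the
#' CpGs measured in that sample. CpGs with zero DNAm variance are excluded
#' with a warning.
#'
#' @inheritParams fit_multivariable_clock
#' @return A `"linear_clock"` of kind `"single_cpg_average"` with
#'   per-CpG `intercepts` and `slopes`.
#' @export
fit_single_cpg_average_clock <- function(betas, samples, signature) {
  ab <- lapply(signature, function(cg) {
    x <- betas[cg, samples$sample_id]
    ok <- !is.na(x)
    if (sum(ok) < 3) stop_wkde("CpG '", cg, "': need >= 3 complete pairs")
    if (stats::var(x[ok]) == 0) {
      warning("CpG '", cg, "' has zero DNAm variance and was excluded",
              call. = FALSE)
      return(NULL)
    }
    b <- stats::cov(x[ok], samples$age[ok]) / stats::var(x[ok])
    a <- mean(samples$age[ok]) - b * mean(x[ok])
    c(a = a, b = b)
  })
  keep <- !vapply(ab, is.null, TRUE)
  if (!any(keep)) stop_wkde("no usable CpG for the single-CpG clock")
  ab <- do.call(rbind, ab[keep])
  structure(list(kind = "single_cpg_average",
                 intercepts = stats::setNames(ab[, "a"], signature[keep]),
                 slopes = stats::setNames(ab[, "b"], signature[keep]),
                 cpgs = signature[keep]),
            class = "linear_clock")
}

#' @export
print.linear_clock <- function(x, ...) {
  cat(sprintf("linear clock (%s), %d CpG(s)\n", x$kind, length(x$cpgs)))
  invisible(x)
}

#' @export
coef.linear_clock <- function(object, ...) {
  if (object$kind == "multivariable")
    c(`(Intercept)` = object$intercept, object$slopes)
  else rbind(intercept = object$intercepts, slope = object$slopes)
}

#' Predict ages with a linear clock
#'
#' @param object A `"linear_clock"`.
#' @param newdata Percent-scale methylation matrix (CpG x sample).
#' @param ... Unused.
#' @return Named vector of predicted ages. The multivariable clock refuses
#'   samples with missing signature values; the averaged clock averages
#'   over the CpGs available per sample.
#' @export
predict.linear_clock <- function(object, newdata, ...) {
  absent <- setdiff(object$cpgs, rownames(newdata))
  if (length(absent) > 0)
    stop_wkde("signature CpG(s) absent from input: ",
              paste(absent, collapse = ", "))
  X <- newdata[object$cpgs, , drop = FALSE]
  if (object$kind == "multivariable") {
    if (anyNA(X)) {
      bad <- colnames(X)[colSums(is.na(X)) > 0]
      stop_wkde("multivariable clock needs every signature CpG; missing ",
                "values in sample(s): ", paste(bad, collapse = ", "))
    }
    drop(object$intercept + crossprod(X, object$slopes)[, 1])
  } else {
    per_cpg <- object$intercepts + object$slopes * X  # recycled by column
    colMeans(per_cpg, na.rm = TRUE)
  }
}

#' Squared Pearson correlation between prediction and truth
#'
#' @param pred,truth Equal-length numeric vectors (>= 3 complete pairs,
#'   neither constant).
#' @return r-squared in \[0, 1\].
#' @export
pearson_r2 <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  ok <- !is.na(pred) & !is.na(truth)
  if (sum(ok) < 3) stop_wkde("need >= 3 complete pairs")
  if (stats::var(pred[ok]) == 0 || stats::var(truth[ok]) == 0)
    stop_wkde("correlation undefined for a constant vector")
  stats::cor(pred[ok], truth[ok])^2
}

#' Median absolute error
#'
#' The clock benchmark error: the *median* of `|pred - truth|` (an even
#' count averages the two central values).
#'
#' @inheritParams pearson_r2
#' @return MAE in years.
#' @export
median_abs_error <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  ok <- !is.na(pred) & !is.na(truth)
  if (!any(ok)) stop_wkde("no complete pairs")
  stats::median(abs(pred[ok] - truth[ok]))
}
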