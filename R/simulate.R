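#' Simulate a DNA methylation cohort
#'
#' Generates a beta-value cohort with the statistical structure the kernel
#' clock assumes: per-CpG age trajectories (logarithmic by default, the
#' shape dominating strong age-associated blood CpGs), bounded Gaussian
#' noise, per-study batch offsets at individual CpGs, and an optional
#' disease mode that decouples affected CpGs by adding independent
#' per-sample, per-CpG shifts. Values are clipped to \[0, 100\]%, which
#' reproduces the saturation seen at CpGs converging to fully (un)methylated
#' states.
#'
#' The default scenario mirrors the scale of a multi-study blood training
#' set: 1000 samples, 30 CpGs of which 27 carry a strong age signal and 3
#' are pure noise, a skewed (adult-heavy) age mixture, 2 studies with
#' batch-offset sd 2% and per-CpG noise sd drawn from \[2, 5\]%.
#'
#' @param n_samples Number of samples.
#' @param n_cpgs Total CpGs; the first `n_informative` follow age
#'   trajectories, the rest are flat noise.
#' @param n_informative Number of age-associated CpGs (default: all but
#'   three, matching the standard 30-CpG scenario's 27).
#' @param age_distribution `"skewed"` (20% uniform 0--20 children, 50%
#'   N(50, 15) and 30% N(72, 9) adults, truncated to \[0, 100\]) or
#'   `"uniform"` on \[0, 100\].
#' @param shape Trajectory shape for informative CpGs:
#'   `mu = b0 +/- b1 * log(age + 1)` or `mu = b0 +/- b1 * age`.
#' @param baseline_range Baseline `b0` range (percent) for increasing
#'   CpGs; decreasing CpGs mirror it at `100 - b0`.
#' @param slope_range Range of `b1` (percent per log-year, or percent per
#'   year for linear shape).
#' @param noise_sd_range Per-CpG noise sd range (percent).
#' @param n_studies Number of studies; each (study, CpG) pair gets an
#'   offset drawn from N(0, `batch_sd`).
#' @param batch_sd Between-study offset sd (percent).
#' @param disease_sd Disease heterogeneity sd (percent); 0 disables the
#'   disease mode and makes the generator identical to the healthy one.
#' @param disease_fraction Fraction of CpGs affected by the disease mode.
#' @param group Group label written to the sample table.
#' @param trajectories Optional trajectory table from a previous cohort
#'   (columns cpg_id, baseline, slope, direction, noise_sd, shape) to reuse
#'   the same biology with fresh samples/offsets.
#' @param seed Seed; the whole cohort is reproducible given it.
#' @return List with `betas` (CpG x sample percent matrix), `samples`
#'   (sample_id, age, sex, study, group) and `params` (the drawn
#'   trajectories, study offsets and disease settings) for oracle checks.
#' @examples
#' cohort <- simulate_cohort(n_samples = 50, n_cpgs = 5, seed = 1)
#' dim(cohort$betas)
#' @export
simulate_cohort <- function(n_samples = 1000, n_cpgs = 30,
                            n_informative = max(1L, n_cpgs - 3L),
                            age_distribution = c("skewed", "uniform"),
                            shape = c("logarithmic", "linear"),
                            baseline_range = c(5, 25), slope_range = c(9, 15),
                            noise_sd_range = c(2, 5), n_studies = 2,
                            batch_sd = 2, disease_sd = 0,
                            disease_fraction = 0.5, group = "healthy",
                            trajectories = NULL, seed = NULL) {
  age_distribution <- match.arg(age_distribution)
  shape <- match.arg(shape)
  stopifnot(n_samples >= 1, n_cpgs >= 1, n_informative <= n_cpgs,
            batch_sd >= 0, disease_sd >= 0, all(noise_sd_range >= 0))
  with_seed(seed, {
    ages <- switch(age_distribution,
      uniform = stats::runif(n_samples, 0, 100),
      skewed = {
        comp <- sample.int(3, n_samples, replace = TRUE,
                           prob = c(0.2, 0.5, 0.3))
        a <- numeric(n_samples)
        a[comp == 1] <- stats::runif(sum(comp == 1), 0, 20)
        a[comp == 2] <- stats::rnorm(sum(comp == 2), 50, 15)
        a[comp == 3] <- stats::rnorm(sum(comp == 3), 72, 9)
        pmin(pmax(a, 0), 100)
      })
    cpg_ids <- sprintf("cpg_%03d", seq_len(n_cpgs))
    if (is.null(trajectories)) {
      informative <- seq_len(n_cpgs) <= n_informative
      direction <- ifelse(stats::runif(n_cpgs) < 0.5, 1, -1)
      slope <- ifelse(informative,
                      stats::runif(n_cpgs, slope_range[1], slope_range[2]), 0)
      b0_up <- stats::runif(n_cpgs, baseline_range[1], baseline_range[2])
      b0_flat <- stats::runif(n_cpgs, 20, 80)
      baseline <- ifelse(!informative, b0_flat,
                         ifelse(direction > 0, b0_up, 100 - b0_up))
      noise_sd <- stats::runif(n_cpgs, noise_sd_range[1], noise_sd_range[2])
      trajectories <- data.frame(cpg_id = cpg_ids, baseline = baseline,
                                 slope = slope, direction = direction,
                                 noise_sd = noise_sd, shape = shape,
                                 stringsAsFactors = FALSE)
    } else {
      stopifnot(nrow(trajectories) == n_cpgs)
      cpg_ids <- trajectories$cpg_id
    }
    study <- sample.int(n_studies, n_samples, replace = TRUE)
    offsets <- matrix(stats::rnorm(n_studies * n_cpgs, 0, batch_sd),
                      nrow = n_studies,
                      dimnames = list(paste0("study_", seq_len(n_studies)),
                                      cpg_ids))

    age_term <- switch(trajectories$shape[1],
                       logarithmic = log(outer(rep(1, n_cpgs), ages) + 1),
                       linear = outer(rep(1, n_cpgs), ages))
    mu <- trajectories$baseline +
      trajectories$direction * trajectories$slope * age_term
    if (any(mu < 0 | mu > 100))
      wkde_log("trajectory means leave [0, 100]; clipping will saturate ",
               "those CpGs at the range limits")
    values <- mu + t(offsets[study, , drop = FALSE]) +
      matrix(stats::rnorm(n_cpgs * n_samples, 0,
                          rep(trajectories$noise_sd, n_samples)),
             nrow = n_cpgs)
    affected <- character(0)
    if (disease_sd > 0) {
      n_aff <- ceiling(disease_fraction * n_cpgs)
      affected <- sort(sample(cpg_ids, n_aff))
      shift <- matrix(stats::rnorm(n_aff * n_samples, 0, disease_sd),
                      nrow = n_aff)
      values[match(affected, cpg_ids), ] <-
        values[match(affected, cpg_ids), ] + shift
    }
    values <- pmin(pmax(values, 0), 100)
    sample_ids <- sprintf("S%04d", seq_len(n_samples))
    dimnames(values) <- list(cpg_ids, sample_ids)
    samples <- data.frame(
      sample_id = sample_ids, age = ages,
      sex = sample(c("female", "male"), n_samples, replace = TRUE),
      study = paste0("study_", study), group = group,
      stringsAsFactors = FALSE)
    list(betas = values, samples = samples,
         params = list(trajectories = trajectories, offsets = offsets,
                       batch_sd = batch_sd, disease_sd = disease_sd,
                       affected_cpgs = affected, seed = seed))
  })
}

#' Simulate a diseased cohort
#'
#' Convenience wrapper around [simulate_cohort()] with the disease mode
#' on: a configured fraction of CpGs receives independent per-sample
#' shifts of sd `disease_sd`, inflating the heterogeneity of age signals
#' (what the variation score detects) while chronological ages stay
#' untouched. With `disease_sd = 0` the output is identical to the healthy
#' generator under the same seed.
#'
#' @inheritParams simulate_cohort
#' @param ... Passed on to [simulate_cohort()].
#' @return As [simulate_cohort()], with `group = "diseased"`.
#' @export
simulate_disease_cohort <- function(disease_sd = 20, disease_fraction = 0.5,
                                    group = "diseased", ...) {
  simulate_cohort(disease_sd = disease_sd,
                  disease_fraction = disease_fraction, group = group, ...)
}

#' Write a simulated cohort to disk
#'
#' Emits the standard beta-matrix TSV and sample-table TSV consumed by
#' [read_beta_matrix()] / [read_sample_table()], plus a `params.json`
#' sidecar recording every drawn parameter for downstream checks.
#'
#' @param cohort A list from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(cohort$betas, file.path(dir, "betas.tsv"))
  write_sample_table(cohort$samples, file.path(dir, "samples.tsv"))
  params <- cohort$params
  params$offsets <- as.data.frame(params$offsets)
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
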