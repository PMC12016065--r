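#' Genetic-algorithm settings
#'
#' Defaults follow the standard clock recipe: 150 candidate weight vectors,
#' 100 generations, the top 40% surviving each generation, a 10% per-gene
#' mutation rate and weights bounded to \[-10, 10\].
#'
#' @param population_size Number of candidate weight vectors.
#' @param iterations Generations to run (the algorithm always completes
#'   them all).
#' @param keep_fraction Fraction of the population surviving by rank.
#' @param mutation_rate Per-gene probability of a uniform reset.
#' @param bounds Lower/upper bound for every weight.
#' @param elitism Track and return the best-ever individual.
#' @param seed Seed for the whole optimization.
#' @return A list of class `"ga_control"`.
#' @export
ga_control <- function(population_size = 150, iterations = 100,
                       keep_fraction = 0.4, mutation_rate = 0.1,
                       bounds = c(-10, 10), elitism = TRUE, seed = NULL) {
  stopifnot(population_size >= 4, iterations >= 1,
            keep_fraction > 0, keep_fraction < 1,
            mutation_rate >= 0, mutation_rate <= 1,
            length(bounds) == 2, bounds[1] < bounds[2])
  structure(list(population_size = as.integer(population_size),
                 iterations = as.integer(iterations),
                 keep_fraction = keep_fraction,
                 mutation_rate = mutation_rate, bounds = bounds,
                 elitism = isTRUE(elitism), seed = seed),
            class = "ga_control")
}

#' Precomputed density rows for the training set
#'
#' Caches, for every training sample and signature CpG, the kernel density
#' row selected by the sample's DNAm value, so that each objective
#' evaluation is a single matrix product instead of a model traversal.
#'
#' @param model A `"wkde"` model.
#' @param betas Percent-scale matrix containing all signature CpGs;
#'   samples with a missing signature value must be dropped beforehand.
#' @param sample_ids Columns to cache (default: all).
#' @return A `"density_cache"`: list with `mat` (a
#'   `(n_points * n_samples) x n_cpgs` matrix; the 101-block of sample l
#'   in column k is that sample's density row for CpG k), `age_grid`,
#'   `cpg_ids`, `sample_ids`.
#' @export
density_cache <- function(model, betas, sample_ids = colnames(betas)) {
  sig <- names(model$kernels)
  absent <- setdiff(sig, rownames(betas))
  if (length(absent) > 0)
    stop_wkde("signature CpG(s) absent from input: ", paste(absent, collapse = ", "))
  sub <- betas[sig, sample_ids, drop = FALSE]
  if (anyNA(sub))
    stop_wkde("density cache requires complete signature DNAm; drop ",
              "samples with missing values first")
  np <- model$grid$n_points
  L <- length(sample_ids)
  mat <- matrix(0, nrow = np * L, ncol = length(sig))
  step <- grid_dnam_step(model$grid)
  for (k in seq_along(sig)) {
    idx <- floor((sub[k, ] - model$grid$dnam_min) / step + 0.5) + 1
    idx <- pmin(pmax(idx, 1L), np)
    rows <- model$kernels[[k]]$density[idx, , drop = FALSE]  # L x np
    mat[, k] <- as.vector(t(rows))
  }
  structure(list(mat = mat, n_samples = L, age_grid = grid_ages(model$grid),
                 cpg_ids = sig, sample_ids = sample_ids),
            class = "density_cache")
}

#' Training objective for a weight vector
#'
#' Total absolute prediction error (years): for every cached sample the
#' weighted density rows are summed and the argmax age taken (ties to the
#' smallest age), and `sum(|age_l - prediction_l|)` returned.
#'
#' @param weights Weight vector, one per signature CpG.
#' @param cache A [density_cache()].
#' @param ages Chronological ages aligned with the cache's samples.
#' @return Total absolute error in years.
#' @export
ga_objective <- function(weights, cache, ages) {
  stopifnot(length(weights) == length(cache$cpg_ids),
            length(ages) == cache$n_samples)
  np <- length(cache$age_grid)
  profiles <- matrix(cache$mat %*% weights, nrow = np)
  preds <- cache$age_grid[max.col(t(profiles), ties.method = "first")]
  sum(abs(ages - preds))
}

#' Optimize CpG weights with a genetic algorithm
#'
#' Searches for per-CpG weights minimizing the total absolute training
#' error of the clock's argmax predictions. The population is initialized
#' uniformly within the bounds, with the unit vector (1, ..., 1) injected
#' so the optimized clock can never underperform the unweighted clock on
#' the training data. Each generation ranks individuals, keeps the top
#' `keep_fraction`, refills by arithmetic crossover of two distinct
#' randomly chosen survivors (fresh uniform blend per gene) and mutates
#' offspring genes with probability `mutation_rate` by uniform resampling
#' within the bounds. The search runs for exactly `iterations` generations.
#'
#' @param model A `"wkde"` model (weights are replaced in the result).
#' @param betas Training methylation matrix (percent scale).
#' @param samples Training sample table with chronological ages. Samples
#'   with missing signature DNAm are dropped with a log message.
#' @param control A [ga_control()].
#' @return The model with optimized weights; `model$ga` holds the
#'   per-generation fitness `trace` (generation, best, median), the final
#'   `objective`, the `unweighted_objective` and the control settings.
#' @export
optimize_weights <- function(model, betas, samples, control = ga_control()) {
  validate_wkde(model)
  sig <- names(model$kernels)
  samples <- samples[samples$sample_id %in% colnames(betas), , drop = FALSE]
  complete <- colSums(is.na(betas[sig, samples$sample_id, drop = FALSE])) == 0
  if (!all(complete))
    wkde_log("dropping ", sum(!complete),
             " training sample(s) with missing signature DNAm")
  samples <- samples[complete, , drop = FALSE]
  if (nrow(samples) == 0) stop_wkde("no complete training samples")
  cache <- density_cache(model, betas, samples$sample_id)
  ages <- samples$age
  K <- length(sig)
  lo <- control$bounds[1]; hi <- control$bounds[2]

  res <- with_seed(control$seed, {
    pop <- matrix(stats::runif(control$population_size * K, lo, hi),
                  nrow = control$population_size)
    pop[1, ] <- 1  # unweighted clock as a guaranteed starting point
    fitness <- apply(pop, 1, ga_objective, cache = cache, ages = ages)
    best_ever <- pop[which.min(fitness), ]
    best_fit <- min(fitness)
    trace <- data.frame(generation = integer(0), best = numeric(0),
                        median = numeric(0))
    n_keep <- max(2L, round(control$keep_fraction * control$population_size))
    for (gen in seq_len(control$iterations)) {
      ord <- order(fitness)
      keep <- ord[seq_len(n_keep)]
      survivors <- pop[keep, , drop = FALSE]
      surv_fit <- fitness[keep]
      n_off <- control$population_size - n_keep
      offspring <- matrix(0, nrow = n_off, ncol = K)
      for (o in seq_len(n_off)) {
        parents <- sample.int(n_keep, 2)
        alpha <- stats::runif(K)
        child <- alpha * survivors[parents[1], ] +
          (1 - alpha) * survivors[parents[2], ]
        mut <- stats::runif(K) < control$mutation_rate
        if (any(mut)) child[mut] <- stats::runif(sum(mut), lo, hi)
        offspring[o, ] <- child
      }
      off_fit <- apply(offspring, 1, ga_objective, cache = cache, ages = ages)
      pop <- rbind(survivors, offspring)
      fitness <- c(surv_fit, off_fit)
      if (min(fitness) < best_fit) {
        best_fit <- min(fitness)
        best_ever <- pop[which.min(fitness), ]
      }
      trace <- rbind(trace, data.frame(generation = gen, best = best_fit,
                                       median = stats::median(fitness)))
    }
    list(weights = best_ever, objective = best_fit, trace = trace)
  })

  weights <- stats::setNames(pmin(pmax(res$weights, lo), hi), sig)
  model$weights <- weights
  model$ga <- list(trace = res$trace, objective = res$objective,
                   unweighted_objective = ga_objective(rep(1, K), cache, ages),
                   n_training_samples = nrow(samples),
                   control = control)
  validate_wkde(model)
  model
}
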