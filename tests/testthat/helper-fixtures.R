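# Shared fixtures and independent oracles, built in code at test time.

# hand-built kernel with an arbitrary density matrix (101 x 101 default)
make_kernel <- function(cpg_id, density = NULL, grid = grid_spec()) {
  n <- grid$n_points
  if (is.null(density)) density <- matrix(1 / n^2, n, n)
  dimnames(density) <- list(grid_dnam(grid), grid_ages(grid))
  structure(list(cpg_id = cpg_id, density = density,
                 bandwidths = c(4, 4), n = NA_integer_),
            class = "density_kernel")
}

# hand-built model from a named list of density matrices
make_model <- function(densities, weights = NULL, grid = grid_spec()) {
  kernels <- lapply(names(densities), function(cg)
    make_kernel(cg, densities[[cg]], grid))
  names(kernels) <- names(densities)
  if (is.null(weights)) weights <- setNames(rep(1, length(kernels)), names(kernels))
  structure(list(grid = grid, kernels = kernels, weights = weights,
                 provenance = list(), ga = NULL), class = "wkde")
}

# density matrix with a single Gaussian-free bump at (age, dnam)
peak_density <- function(age, dnam, grid = grid_spec(), height = 1) {
  n <- grid$n_points
  d <- matrix(1e-8, n, n)
  d[dnam + 1, age + 1] <- height
  d
}

# independent double-loop Gaussian-sum KDE oracle (kde2d convention: sd = h/4)
kde_oracle <- function(ages, dnam, h, grid = grid_spec()) {
  ga <- grid_ages(grid); gd <- grid_dnam(grid)
  n <- length(ages)
  out <- matrix(0, length(gd), length(ga))
  for (j in seq_along(gd)) {
    for (i in seq_along(ga)) {
      s <- 0
      for (l in seq_len(n))
        s <- s + dnorm(ga[i] - ages[l], sd = h[1] / 4) *
          dnorm(gd[j] - dnam[l], sd = h[2] / 4)
      out[j, i] <- s / n
    }
  }
  out
}

# brute-force moments of a 101-point pmf after linear interpolation to the
# 0.1-year grid, written independently of the package's variation_score()
fine_moments_oracle <- function(p) {
  ages <- seq(0, 100, by = 0.1)
  f <- numeric(length(ages))
  for (i in seq_along(ages)) {
    a <- ages[i]
    lo <- floor(a); hi <- ceiling(a)
    f[i] <- if (lo == hi) p[lo + 1]
            else p[lo + 1] * (hi - a) + p[hi + 1] * (a - lo)
  }
  f <- f / sum(f)
  m <- sum(f * ages)
  v <- sum(f * (ages - m)^2)
  list(mean = m, variance = v, sd = sqrt(v))
}

# small fitted clock shared across test files (memoized per test run)
.fixture_env <- new.env(parent = emptyenv())
small_fitted_model <- function() {
  if (is.null(.fixture_env$model)) {
    cohort <- simulate_cohort(n_samples = 400, n_cpgs = 8, n_informative = 6,
                              age_distribution = "uniform", seed = 42)
    model <- suppressWarnings(
      wkde(cohort$betas, cohort$samples, r2_threshold = 0.6, seed = 43))
    .fixture_env$model <- model
    .fixture_env$cohort <- cohort
  }
  list(model = .fixture_env$model, cohort = .fixture_env$cohort)
}
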