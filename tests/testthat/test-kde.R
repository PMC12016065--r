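test_that("normal-reference bandwidth matches its closed form", {
  x <- 1:10
  # direct evaluation: 4 * 1.06 * min(sd, IQR/1.34) * n^(-1/5), type-7 quartiles
  h_oracle <- 4 * 1.06 * min(sd(x), (quantile(x, 0.75, type = 7) -
                                       quantile(x, 0.25, type = 7)) / 1.34) *
    length(x)^(-1 / 5)
  expect_equal(nrd_bandwidth(x), unname(h_oracle), tolerance = 1e-12)
  expect_equal(nrd_bandwidth(x), 8.10, tolerance = 1e-3)

  expect_error(nrd_bandwidth(rep(3, 8)), "constant")
  expect_error(nrd_bandwidth(5), ">= 2")

  # homogeneity: scaling values by c > 0 scales h by c
  for (c in c(0.1, 2, 37)) {
    y <- c(1, 4, 4.5, 9, 12)
    expect_equal(nrd_bandwidth(c * y), c * nrd_bandwidth(y), tolerance = 1e-12)
  }
})

test_that("a single training point yields a Gaussian peak of height 1/(2*pi)", {
  k <- fit_cpg_kernel(ages = c(40, 40), dnam = c(50, 50), bandwidths = c(4, 4))
  # sd = h/4 = 1 on both axes; peak density = 1/(2*pi)
  peak <- which(k$density == max(k$density), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(51, 41))  # row DNAm 50, column age 40
  expect_equal(max(k$density), 1 / (2 * pi), tolerance = 1e-12)
})

test_that("fitted densities equal the double-loop Gaussian-sum oracle", {
  set.seed(3)
  ages <- runif(5, 10, 90)
  dnam <- runif(5, 10, 90)
  h <- c(6, 9)
  k <- fit_cpg_kernel(ages, dnam, bandwidths = h)
  oracle <- kde_oracle(ages, dnam, h)
  expect_lt(max(abs(k$density - oracle)), 1e-12)
})

test_that("grid orientation: entry (j, i) is density at (DNAm g_j, age g_i)", {
  ages <- c(20, 70); dnam <- c(80, 30)
  k <- fit_cpg_kernel(ages, dnam, bandwidths = c(8, 8))
  oracle <- kde_oracle(ages, dnam, c(8, 8))
  for (probe in list(c(31, 21), c(81, 71), c(1, 101)))
    expect_equal(k$density[probe[1], probe[2]], oracle[probe[1], probe[2]],
                 tolerance = 1e-14)
  # the two training points sit at their own (dnam, age) coordinates
  expect_gt(k$density[81, 21], k$density[31, 21])
})

test_that("kernel mass integrates to the in-window fraction of the density", {
  set.seed(4)
  ages <- runif(30, 30, 70); dnam <- runif(30, 30, 70)
  k <- fit_cpg_kernel(ages, dnam, bandwidths = c(4, 4))
  mass <- sum(k$density) * 1 * 1  # Riemann sum, unit cells
  expect_lte(mass, 1 + 1e-6)
  expect_equal(mass, 1, tolerance = 1e-3)  # tight bandwidth, central points

  wide <- fit_cpg_kernel(ages, dnam, bandwidths = c(200, 200))
  expect_lt(sum(wide$density), mass)  # mass leaks outside the window
})

test_that("kernel fit is invariant to sample order and dataset duplication", {
  set.seed(5)
  ages <- runif(12, 0, 100); dnam <- runif(12, 0, 100)
  h <- c(10, 12)
  k1 <- fit_cpg_kernel(ages, dnam, bandwidths = h)
  ord <- sample(12)
  k2 <- fit_cpg_kernel(ages[ord], dnam[ord], bandwidths = h)
  expect_equal(k1$density, k2$density, tolerance = 1e-15)

  k3 <- fit_cpg_kernel(rep(ages, 2), rep(dnam, 2), bandwidths = h)
  expect_equal(k1$density, k3$density, tolerance = 1e-12)  # 1/n scaling

  expect_error(fit_cpg_kernel(40, 50), ">= 2")
  expect_error(fit_cpg_kernel(c(40, 41), c(50, 50)), "constant|bandwidth")
})

test_that("age-histogram normalization divides columns by rounded-age counts", {
  k <- make_kernel("cg1", matrix(1, 101, 101))
  samples <- data.frame(sample_id = sprintf("s%d", 1:11),
                        age = c(rep(40.2, 10), 41.4))  # c_40 = 10, c_41 = 1
  norm <- normalize_kernel_by_age_histogram(k, samples)
  expect_equal(norm$density[5, 42] / norm$density[5, 41], 10)
  # zero-count ages get exactly zero density
  expect_true(all(norm$density[, 43:101] == 0))
  expect_true(all(norm$density[, 1:40] == 0))

  # uniform counts leave the kernel unchanged up to a global scale
  samples2 <- data.frame(sample_id = sprintf("t%d", 1:101),
                         age = 0:100)
  fx <- small_fitted_model()
  raw <- fx$model$kernels[[1]]
  norm2 <- normalize_kernel_by_age_histogram(raw, samples2, cap = 100)
  expect_equal(norm2$density, raw$density / 1, tolerance = 1e-12)
  expect_identical(which.max(norm2$density), which.max(raw$density))

  # samples above the cap are ignored; all above cap -> error
  old <- data.frame(sample_id = "x", age = 99)
  expect_error(normalize_kernel_by_age_histogram(k, old, cap = 85), "age cap")
})

test_that("model fitting assembles aligned kernels with unit weights", {
  fx <- small_fitted_model()
  model <- fx$model
  expect_s3_class(model, "wkde")
  expect_identical(names(model$kernels), names(model$weights))
  expect_true(all(model$weights == 1))
  for (k in model$kernels) expect_equal(dim(k$density), c(101, 101))

  # refit with identical inputs and seed is bit-identical
  refit <- suppressWarnings(
    wkde(fx$cohort$betas, fx$cohort$samples, r2_threshold = 0.6, seed = 43))
  for (cg in names(model$kernels))
    expect_identical(refit$kernels[[cg]]$density, model$kernels[[cg]]$density)

  expect_error(wkde(fx$cohort$betas, fx$cohort$samples,
                    signature = c("cpg_001", "nope"), seed = 1),
               "nope")
})
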