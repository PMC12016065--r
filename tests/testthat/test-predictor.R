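test_that("density row lookup rounds to the nearest grid node, half up", {
  d <- matrix(seq_len(101 * 101), 101)
  k <- make_kernel("cg1", d)
  expect_identical(unname(density_row(k, 49.6)), d[51, ])  # node 50
  expect_identical(unname(density_row(k, 49.4)), d[50, ])
  expect_identical(unname(density_row(k, 49.5)), d[51, ])  # half rounds up
  expect_identical(unname(density_row(k, 0)), d[1, ])
  expect_identical(unname(density_row(k, 100)), d[101, ])
  expect_null(density_row(k, NA))
})

test_that("joint profile is the weighted sum of per-CpG rows", {
  d1 <- peak_density(40, 30); d2 <- peak_density(60, 70)
  model <- make_model(list(a = d1, b = d2))

  # single CpG: profile equals that CpG's density row
  p <- joint_density_profile(model, c(a = 30, b = NA))
  expect_equal(as.vector(p), unname(d1[31, ]))
  expect_identical(attr(p, "n_cpgs_used"), 1L)

  # two identical rows with weights {2, -1} collapse to one row
  model2 <- make_model(list(a = d1, b = d1), weights = c(a = 2, b = -1))
  p2 <- joint_density_profile(model2, c(a = 30, b = 30))
  expect_equal(as.vector(p2), unname(d1[31, ]), tolerance = 1e-15)

  expect_error(joint_density_profile(model, c(a = NA, b = NA)), "missing")
})

test_that("joint profile matches a brute-force loop on a fitted clock", {
  fx <- small_fitted_model()
  model <- fx$model
  model$weights[] <- seq(-2, 3, length.out = length(model$weights))
  set.seed(9)
  dn <- setNames(runif(length(model$kernels), 0, 100), names(model$kernels))
  profile <- joint_density_profile(model, dn, use_weights = TRUE)
  brute <- numeric(101)
  for (i in 1:101)
    for (cg in names(model$kernels)) {
      row_idx <- floor(dn[[cg]] + 0.5) + 1
      brute[i] <- brute[i] +
        model$weights[[cg]] * model$kernels[[cg]]$density[row_idx, i]
    }
  expect_lt(max(abs(profile - brute)), 1e-12)
})

test_that("predicted age is the argmax with ties toward the youngest age", {
  model <- make_model(list(a = peak_density(40, 30)))
  expect_equal(predict_age(model, c(a = 30)), 40)
  # flat profile -> smallest age
  flat <- make_model(list(a = matrix(0.5, 101, 101)))
  expect_equal(predict_age(flat, c(a = 10)), 0)

  # weight sign flip moves the argmax from the peak to the minimum
  toy <- matrix(1e-3, 101, 101); toy[31, 41] <- 1; toy[31, 91] <- 1e-4
  m <- make_model(list(a = toy), weights = c(a = 1))
  expect_equal(predict_age(m, c(a = 30)), 40)
  m$weights[["a"]] <- -1
  expect_equal(predict_age(m, c(a = 30)), 90)  # argmax of -profile = old min

  # positive rescaling of all weights changes nothing
  fx <- small_fitted_model()
  mod <- fx$model
  mod$weights[] <- runif(length(mod$weights), 0.5, 3)
  dn <- setNames(runif(length(mod$kernels), 10, 90), names(mod$kernels))
  before <- predict_age(mod, dn)
  scaled <- mod; scaled$weights <- mod$weights * 2.5
  expect_equal(predict_age(scaled, dn), before)
  expect_equal(probability_vector(scaled, dn), probability_vector(mod, dn))
})

test_that("probability vectors normalize to 1 and floor negative mass", {
  fx <- small_fitted_model()
  dn <- setNames(rep(50, length(fx$model$kernels)), names(fx$model$kernels))
  p <- probability_vector(fx$model, dn)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_false(attr(p, "floored"))

  # engineered negative region: strong negative weight on a side peak
  d1 <- peak_density(40, 30, height = 1)
  d2 <- peak_density(80, 30, height = 1)
  m <- make_model(list(a = d1, b = d2), weights = c(a = 1, b = -5))
  pr <- joint_density_profile(m, c(a = 30, b = 30))
  expect_true(any(pr < 0))
  p2 <- probability_vector(m, c(a = 30, b = 30))
  expect_true(attr(p2, "floored"))
  expect_equal(sum(p2), 1, tolerance = 1e-12)
  expect_equal(p2[81], 0)  # the negative age has probability exactly 0
  expect_true(all(p2 >= 0))

  # unweighted equals weights-all-1
  mod <- fx$model
  expect_equal(probability_vector(mod, dn, use_weights = TRUE),
               probability_vector(mod, dn, use_weights = FALSE))
})

test_that("fine interpolation passes through knots and renormalizes", {
  p <- rep(1 / 101, 101)
  f <- fine_probability(p)
  expect_length(f, 1001)
  expect_equal(f, rep(1 / 1001, 1001), tolerance = 1e-12)

  set.seed(12)
  p2 <- runif(101); p2 <- p2 / sum(p2)
  f2 <- fine_probability(p2)
  expect_equal(sum(f2), 1, tolerance = 1e-9)
  # values at integer ages proportional to the coarse pmf
  expect_equal(f2[1 + 10 * (0:100)] / sum(f2[1 + 10 * (0:100)]),
               p2, tolerance = 1e-12)

  # point mass becomes a tent concentrated around its age
  p3 <- c(rep(0, 40), 1, rep(0, 60))
  f3 <- fine_probability(p3)
  expect_equal(sum(f3), 1, tolerance = 1e-12)
  expect_true(all(f3[c(1:390, 412:1001)] == 0))
})

test_that("variation score moments agree with a brute-force oracle", {
  cases <- list(point = c(rep(0, 40), 1, rep(0, 60)),
                two_point = {p <- rep(0, 101); p[c(21, 61)] <- 0.5; p},
                uniform = rep(1 / 101, 101),
                random = {set.seed(2); p <- runif(101); p / sum(p)})
  for (nm in names(cases)) {
    vs <- variation_score(cases[[nm]])
    oracle <- fine_moments_oracle(cases[[nm]])
    expect_equal(vs$mean, oracle$mean, tolerance = 1e-6)
    expect_equal(vs$variance, oracle$variance, tolerance = 1e-6)
    expect_equal(vs$variation_score, oracle$sd, tolerance = 1e-6)
  }

  # nominal values: degenerate, two-point and uniform distributions
  vs_point <- variation_score(cases$point)
  expect_equal(vs_point$mean, 40, tolerance = 1e-9)
  expect_lte(vs_point$variation_score, sqrt(1 / 6) + 1e-9)  # tent smoothing cap
  vs_two <- variation_score(cases$two_point)
  expect_equal(vs_two$mean, 40, tolerance = 1e-9)
  expect_equal(vs_two$variation_score, 20, tolerance = 0.01)
  vs_unif <- variation_score(cases$uniform)
  # discrete uniform on 1001 points of step 0.1: sd = 0.1 * sqrt((1001^2-1)/12)
  expect_equal(vs_unif$variation_score, 0.1 * sqrt((1001^2 - 1) / 12),
               tolerance = 1e-9)
  expect_equal(vs_unif$variation_score, 28.90, tolerance = 1e-3)
})

test_that("literal mode reproduces the printed prefactor arithmetic", {
  set.seed(13)
  p <- runif(101); p <- p / sum(p)
  f <- approx(0:100, p, xout = seq(0, 100, by = 0.1))$y  # unrenormalized
  x <- 0:1000
  m_lit <- 0.1 * sum(f * x)
  v_lit <- 0.1 * sum(f * (0.1 * x - m_lit)^2)
  vs <- variation_score(p, mode = "literal")
  expect_equal(vs$mean, m_lit, tolerance = 1e-12)
  expect_equal(vs$variance, v_lit, tolerance = 1e-12)
})

test_that("variation score ignores the model's weights", {
  fx <- small_fitted_model()
  cohort <- fx$cohort
  betas <- cohort$betas[names(fx$model$kernels), 1:20]
  base <- predict(fx$model, betas)
  rew <- fx$model
  set.seed(21)
  rew$weights[] <- runif(length(rew$weights), -3, 8)
  again <- predict(rew, betas)
  expect_equal(again$variation_score, base$variation_score, tolerance = 1e-12)
})

test_that("coverage fraction counts samples inside predicted +/- score", {
  res <- data.frame(delta_age = c(0, 0, 0, 0), variation_score = c(1, 1, 1, 1))
  expect_equal(coverage_fraction(res), 1)
  res$delta_age <- c(0, 2, 0, 5); res$variation_score <- c(1, 3, 1, 4)
  expect_equal(coverage_fraction(res), 0.75)
  # adding an exactly-covered sample cannot decrease coverage
  res2 <- rbind(res, data.frame(delta_age = 0, variation_score = 0))
  expect_gte(coverage_fraction(res2) * 5, coverage_fraction(res) * 4)
  expect_error(coverage_fraction(res[0, ]), "empty")
})

test_that("predict.wkde produces a coherent per-sample table", {
  fx <- small_fitted_model()
  model <- fx$model
  cohort <- fx$cohort
  betas <- cohort$betas[, 1:30]
  res <- predict(model, betas, samples = cohort$samples)
  expect_equal(nrow(res), 30)
  expect_true(all(res$predicted_age >= 0 & res$predicted_age <= 100))
  expect_equal(res$delta_age, res$predicted_age - res$chronological_age)
  expect_equal(res$interval_lo, res$predicted_age - res$variation_score)
  expect_true(all(res$n_cpgs_used == length(model$kernels)))

  # argmax of the probability vector equals the point prediction (no flooring)
  pm <- predict(model, betas, type = "prob")
  expect_equal(dim(pm), c(101, 30))
  expect_equal(as.numeric(rownames(pm))[apply(pm, 2, which.max)],
               res$predicted_age)

  # missing values are skipped per sample; absent signature CpGs error
  betas2 <- betas
  betas2[names(model$kernels)[1], 3] <- NA
  res2 <- predict(model, betas2)
  expect_equal(res2$n_cpgs_used[3], length(model$kernels) - 1L)
  keep <- setdiff(rownames(betas), names(model$kernels)[1])
  expect_error(predict(model, betas[keep, ]), names(model$kernels)[1])
})
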