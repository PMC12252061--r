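# Brute-force 1-D SSE grid search: the independent oracle for the
# closed-form least-squares identification.
grid_search_sigma <- function(phi, tau, coeffs, mu_thread, upper,
                              n_grid = 1e4) {
  grid <- seq(0, upper, length.out = n_grid)
  x <- coeffs$G1 + mu_thread * coeffs$G2 * (phi - coeffs$alpha / 2)
  sse <- vapply(grid, function(s) sum((tau - s * x)^2), numeric(1))
  list(sigma = grid[which.min(sse)], step = grid[2] - grid[1])
}

coeffs_a0 <- function(geom = screw_geometry()) {
  insertion_coefficients(geom, alpha_policy = "explicit-value", alpha = 0)
}

test_that("forward model reproduces frozen worked values", {
  co <- coeffs_a0()
  tau <- predict_insertion_torque(c(10, 20, 30), 2.02866, co,
                                  mu_thread = 0.2)
  expect_equal(tau, c(91.355, 177.883, 264.410), tolerance = 1e-4)
})

test_that("forward model is clamped below the engagement offset", {
  co <- insertion_coefficients(screw_geometry())   # alpha ~ 2.18 rad
  sigma <- 5
  # at phi = alpha/2 the friction term vanishes exactly
  expect_equal(predict_insertion_torque(co$alpha / 2, sigma, co),
               sigma * co$G1, tolerance = 1e-14)
  # below alpha/2 the (negative) friction term is clamped, cutting retained
  expect_equal(predict_insertion_torque(co$alpha / 4, sigma, co),
               sigma * co$G1, tolerance = 1e-14)
  # zero strength gives zero torque everywhere
  expect_equal(predict_insertion_torque(c(0, 5, 50), 0, co), c(0, 0, 0))
})

test_that("closed-form identification reproduces the frozen worked example", {
  co <- coeffs_a0()
  fit <- identify_strength(c(10, 20, 30), c(100, 180, 260), co,
                           mu_thread = 0.2)
  expect_equal(fit$sigma_ucs, 2.0287, tolerance = 1e-4)
  expect_equal(fit$sigma_ucs, 2.0286668, tolerance = 1e-7)
  expect_equal(fit$n_samples, 3L)
  expect_false(fit$negative)
  # the oracle grid search agrees to within one grid step
  gs <- grid_search_sigma(c(10, 20, 30), c(100, 180, 260), co, 0.2,
                          upper = 10, n_grid = 1e5)
  expect_lt(abs(fit$sigma_ucs - gs$sigma), gs$step)
})

test_that("predict -> identify round trip is the identity in sigma", {
  set.seed(202)
  for (i in 1:20) {
    geom <- screw_geometry(pitch = runif(1, 1, 4),
                           mu_thread = runif(1, 0.05, 1))
    alpha <- runif(1, 0, 4)
    co <- insertion_coefficients(geom, alpha_policy = "explicit-value",
                                 alpha = alpha)
    sigma <- runif(1, 0.1, 20)
    phi <- sort(runif(50, alpha / 2 + 0.1, 70))
    tau <- predict_insertion_torque(phi, sigma, co, geom$mu_thread)
    fit <- identify_strength(phi, tau, co, geom$mu_thread)
    expect_equal(fit$sigma_ucs, sigma, tolerance = 1e-9)
    expect_lt(fit$sse / sum(tau^2), 1e-18)
  }
})

test_that("identification is homogeneous and monotone in the torques", {
  co <- coeffs_a0()
  phi <- seq(1, 60, by = 0.5)
  tau <- predict_insertion_torque(phi, 3, co) + rnorm(length(phi), 0, 5)
  s1 <- identify_strength(phi, tau, co)$sigma_ucs
  s2 <- identify_strength(phi, 2 * tau, co)$sigma_ucs
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  # adding a positive constant never decreases the estimate (x > 0)
  for (shift in c(0.1, 1, 50)) {
    expect_gte(identify_strength(phi, tau + shift, co)$sigma_ucs, s1)
  }
})

test_that("closed form matches the brute-force grid on random noisy segments", {
  set.seed(303)
  co <- coeffs_a0()
  for (i in 1:10) {
    sigma <- runif(1, 0.5, 8)
    phi <- sort(runif(60, 2, 70))
    tau <- predict_insertion_torque(phi, sigma, co) +
      rnorm(60, 0, 10)
    fit <- identify_strength(phi, tau, co)
    gs <- grid_search_sigma(phi, tau, co, 0.2, upper = 16, n_grid = 2e4)
    expect_lt(abs(fit$sigma_ucs - gs$sigma), gs$step)
  }
})

test_that("the estimator is unbiased under zero-mean torque noise", {
  co <- coeffs_a0()
  sigma <- 4
  phi <- seq(2, 60, length.out = 200)
  clean <- predict_insertion_torque(phi, sigma, co)
  x <- co$G1 + 0.2 * co$G2 * phi
  noise_sd <- 25
  set.seed(404)
  est <- replicate(1000, {
    identify_strength(phi, clean + rnorm(200, 0, noise_sd), co)$sigma_ucs
  })
  se_theory <- noise_sd / sqrt(sum(x^2))
  expect_lt(abs(mean(est) - sigma), 3 * se_theory / sqrt(1000))
})

test_that("degenerate fit inputs raise; negative estimates are flagged", {
  co <- coeffs_a0()
  expect_error(identify_strength(numeric(0), numeric(0), co), "empty")
  expect_error(identify_strength(1:3, 1:2, co), "equal length")
  # samples all below alpha/2 are excluded -> empty segment
  co_a <- insertion_coefficients(screw_geometry())
  expect_error(identify_strength(rep(0.1, 5), rep(1, 5), co_a), "alpha/2")
  fit <- identify_strength(c(10, 20), c(-100, -200), co)
  expect_true(fit$negative)
  expect_lt(fit$sigma_ucs, 0)
})

test_that("tidy and glance expose the fit in broom form", {
  co <- coeffs_a0()
  fit <- identify_strength(c(10, 20, 30), c(100, 180, 260), co)
  td <- tidy(fit)
  expect_equal(td$term, "sigma_ucs")
  expect_equal(td$estimate, fit$sigma_ucs)
  gl <- glance(fit)
  expect_equal(gl$n_samples, 3L)
  expect_equal(gl$fit_min, 10)
  expect_equal(gl$fit_max, 30)
})
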