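test_that("single-species dynamics match the logistic closed form", {
  grid <- seq(0.5, 8, length.out = 25)
  params <- glv_params(r = 1, K = 1, B = matrix(0, 1, 1), A0 = 0.1,
                       theta_grid = grid)
  tr <- simulate_glv_gradient(params)
  closed <- 1 / (1 + ((1 - 0.1) / 0.1) * exp(-grid))
  expect_equal(unname(tr$abundance$values[, 1]), closed, tolerance = 1e-6)
})

test_that("starting at carrying capacity stays at equilibrium", {
  grid <- seq(0.2, 5, length.out = 12)
  params <- glv_params(r = c(1, 0.5), K = c(2, 3), B = matrix(0, 2, 2),
                       A0 = c(2, 3), theta_grid = grid)
  tr <- simulate_glv_gradient(params)
  expect_equal(unname(tr$abundance$values[, 1]), rep(2, 12), tolerance = 1e-6)
  expect_equal(unname(tr$abundance$values[, 2]), rep(3, 12), tolerance = 1e-6)
  expect_true(all(abs(tr$true_p) < 1e-6))
})

test_that("weak mutualism converges to the analytic equilibrium", {
  grid <- seq(1, 60, length.out = 30)
  B <- matrix(c(0, 0.1, 0.1, 0), 2, 2)
  params <- glv_params(r = c(1, 1), K = c(1, 1), B = B, A0 = c(0.5, 0.5),
                       theta_grid = grid)
  tr <- simulate_glv_gradient(params)
  eq <- (1 + 0.1) / (1 - 0.01)     # (K + b*K) / (1 - b^2)
  expect_equal(unname(tr$abundance$values[30, ]), rep(eq, 2), tolerance = 1e-4)
})

test_that("the effective interaction convention scales B by r/K", {
  params <- glv_params(r = c(1.2, 0.8), K = c(1, 2),
                       B = matrix(c(0, 0.8, -0.8, 0), 2, 2, byrow = TRUE),
                       A0 = c(1, 1), theta_grid = c(0.5, 1, 1.5))
  tr <- simulate_glv_gradient(params)
  expect_equal(tr$true_beta[1, 2], 1.2 * 0.8 / 1)
  expect_equal(tr$true_beta[2, 1], 0.8 * -0.8 / 2)
  expect_equal(tr$true_beta_sign[1, 2], 1)
  expect_equal(tr$true_beta_sign[2, 1], -1)
})

test_that("analytic datasets carry their gradients and round-trip through estimation", {
  coef <- matrix(c(2, 0, 1, 3), 2, 2)
  tr <- make_analytic_dataset(coef, intercept = c(8, 8), n_samples = 25, seed = 5)
  expect_true(all(tr$true_p[1, 1, ] == 2))
  pre <- preprocess(tr$abundance, tr$environment)
  p <- estimate_p(pre$abundance, pre$environment)
  expect_lt(max(abs(p$p - truth_slope_field(tr)$p)), 1e-6)

  expect_error(make_analytic_dataset(coef, intercept = c(8, 8), n_samples = 4),
               "n_samples")
  expect_error(make_analytic_dataset(-5 * coef, intercept = c(1, 1),
                                     n_samples = 25, seed = 5),
               "nonpositive")
})

test_that("closure normalizes rows, is idempotent, and rejects zero rows", {
  a <- make_abund(rbind(c(1, 1, 2), c(2, 2, 4)))
  x <- closure(a)
  expect_equal(unname(x$values[1, ]), c(0.25, 0.25, 0.5))
  expect_equal(x$mode, "relative")
  expect_equal(closure(x)$values, x$values, tolerance = 1e-12)
  expect_equal(rowSums(x$values), c(s1 = 1, s2 = 1), tolerance = 1e-12)

  z <- make_abund(rbind(c(0, 0), c(1, 1)))
  expect_error(closure(z), "zero row sum")
})

test_that("the study emulation has the survey shape and passes preprocessing", {
  st <- suppressWarnings(emulate_study(seed = 3))
  expect_equal(dim(st$abundance$values), c(150, 17))
  expect_equal(dim(st$environment$values), c(150, 13))
  expect_true(all(st$abundance$values > 0))
  expect_equal(st$abundance$mode, "relative")
  expect_lt(max(st$abundance$values), 0.15)    # high-diversity community

  zf <- drop_zero_taxa(st$abundance)
  expect_length(zf$dropped, 0)
  pre <- suppressWarnings(preprocess(st$abundance, st$environment))
  expect_equal(pre$report$dimension_status, "ok")
  expect_equal(ncol(pre$environment$values), 13)

  st2 <- suppressWarnings(emulate_study(seed = 4))
  expect_equal(dim(st2$abundance$values), dim(st$abundance$values))
  expect_false(identical(st2$abundance$values, st$abundance$values))
})

test_that("two-seeded runs of a generator differ in values but share shape", {
  t1 <- simulate_predator_prey(seed = 1)
  t1b <- simulate_predator_prey(seed = 1)
  t2 <- simulate_predator_prey(seed = 2)
  expect_identical(t1$abundance$values, t1b$abundance$values)
  expect_false(identical(t1$abundance$values, t2$abundance$values))
  expect_equal(dim(t1$abundance$values), dim(t2$abundance$values))
})

test_that("the closure derivative approximation is tracked by a finite-difference oracle", {
  # dense noise-free trajectory: central differences of the closed fractions
  grid <- seq(0.5, 6, length.out = 80)
  B <- matrix(c(0, 0.2, -0.2, 0, 0.1, 0, 0, -0.1, 0), 3, 3, byrow = TRUE)
  params <- glv_params(r = c(1, 0.8, 0.9), K = c(1, 1.2, 0.9), B = B,
                       A0 = c(0.4, 0.5, 0.6), theta_grid = grid)
  tr <- simulate_glv_gradient(params)
  x <- closure(tr$abundance)$values
  y <- tr$abundance$values
  S <- rowSums(y)
  mid <- 2:79
  fd <- (x[mid + 1, 1] - x[mid - 1, 1]) / (grid[mid + 1] - grid[mid - 1])
  p <- tr$true_p[, 1, ]
  exact <- (p[1, mid] * S[mid] - y[mid, 1] * colSums(p)[mid]) / S[mid]^2
  # the quotient-rule derivative must agree with central differences
  expect_lt(median(abs(exact - fd) / pmax(abs(fd), 1e-8)), 1e-2)
})
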