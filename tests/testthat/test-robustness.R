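test_that("multiplicative perturbation respects its bounds and is centered", {
  m <- matrix(10, 5, 5)
  expect_identical(perturb(m, 0), m)
  set.seed(1)
  p <- perturb(m, 0.5)
  expect_true(all(p >= 5 & p <= 15))
  set.seed(2)
  big <- perturb(rep(1, 1e5), 0.2)
  expect_lt(abs(mean(big) - 1), 0.01)
})

test_that("subsampling keeps matched samples without replacement", {
  set.seed(3)
  a <- make_abund(matrix(runif(150 * 2, 1, 2), 150, 2))
  e <- make_env(matrix(rnorm(150), 150, 1), samples = rownames(a$values))
  sub <- subsample(a, e, fraction = 0.9)
  expect_equal(nrow(sub$abundance$values), 135)
  expect_identical(rownames(sub$abundance$values), rownames(sub$environment$values))
  expect_false(anyDuplicated(rownames(sub$abundance$values)) > 0)

  full <- subsample(a, e, fraction = 1.0)
  expect_equal(nrow(full$abundance$values), 150)
  expect_equal(full$abundance$values[rownames(a$values), ], a$values)

  a20 <- make_abund(matrix(runif(20 * 19, 1, 2), 20, 19))
  e20 <- make_env(matrix(rnorm(20), 20, 1), samples = rownames(a20$values))
  expect_error(subsample(a20, e20, fraction = 0.9), "19 regression variables")
})

test_that("a zero error level reproduces the base value with zero-width intervals", {
  tr <- simulate_predator_prey(seed = 2)
  sf <- truth_slope_field(tr)
  spec <- perturbation_spec("abundance", error_level = 0, n_iter = 5, seed = 1)
  rep <- suppressWarnings(
    robustness_run(tr$abundance, tr$environment, spec, prune = FALSE,
                   slope_field = sf))
  det <- rep$pairs[!is.na(rep$pairs$mean), ]
  expect_gt(nrow(det), 0)
  expect_equal(det$mean, det$base, tolerance = 1e-12)
  expect_equal(det$ci_high - det$ci_low, rep(0, nrow(det)))
  expect_equal(det$n_valid, rep(5L, nrow(det)))
})

test_that("a single iteration is rejected and identical seeds reproduce reports", {
  tr <- make_squared_pair_dataset(n_samples = 30, seed = 11)
  expect_error(perturbation_spec("abundance", n_iter = 0), "n_iter")
  spec1 <- perturbation_spec("abundance", error_level = 0.05, n_iter = 1, seed = 1)
  expect_error(robustness_run(tr$abundance, tr$environment, spec1), "at least 2")

  spec <- perturbation_spec("abundance", error_level = 0.05, n_iter = 4, seed = 7)
  r1 <- suppressWarnings(robustness_run(tr$abundance, tr$environment, spec, prune = FALSE))
  r2 <- suppressWarnings(robustness_run(tr$abundance, tr$environment, spec, prune = FALSE))
  expect_identical(r1$iterations, r2$iterations)
})

test_that("the recovered predator-prey benefit keeps its sign with a CI excluding zero", {
  tr <- simulate_predator_prey(seed = 2)
  sf <- truth_slope_field(tr)
  spec <- perturbation_spec("abundance", error_level = 0.05, n_iter = 30, seed = 5)
  rep <- suppressWarnings(
    robustness_run(tr$abundance, tr$environment, spec, prune = FALSE,
                   slope_field = sf))
  row <- rep$pairs[rep$pairs$taxon_i == "sp1" & rep$pairs$taxon_j == "sp2", ]
  expect_gt(row$n_valid, 20)
  expect_gt(row$ci_low, 0)        # excludes zero with the true (positive) sign
  expect_lt(row$p_value, 0.01)
})

test_that("confidence intervals widen with the error level", {
  tr <- simulate_predator_prey(seed = 2)
  sf <- truth_slope_field(tr)
  widths <- vapply(c(0.0001, 0.05, 0.10), function(e) {
    spec <- perturbation_spec("abundance", error_level = e, n_iter = 25, seed = 9)
    rep <- suppressWarnings(
      robustness_run(tr$abundance, tr$environment, spec, prune = FALSE,
                     slope_field = sf))
    row <- rep$pairs[rep$pairs$taxon_i == "sp1" & rep$pairs$taxon_j == "sp2", ]
    row$ci_high - row$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))
})

test_that("subsampled sites preserve the interaction signs of the predator-prey pair", {
  tr <- simulate_predator_prey(seed = 2)
  sf <- truth_slope_field(tr)
  spec <- perturbation_spec("subsample", subsample_fraction = 0.9,
                            n_iter = 10, seed = 3)
  rep <- suppressWarnings(
    robustness_run(tr$abundance, tr$environment, spec, prune = FALSE,
                   slope_field = sf))
  v12 <- rep$iterations["sp1", "sp2", ]
  v21 <- rep$iterations["sp2", "sp1", ]
  expect_gte(mean(sign(v12[!is.na(v12)]) == sign(rep$global$beta["sp1", "sp2"])), 0.9)
  expect_gte(mean(sign(v21[!is.na(v21)]) == sign(rep$global$beta["sp2", "sp1"])), 0.9)
})
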