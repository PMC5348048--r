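make_field <- function(beta) {
  structure(list(beta = beta, model_variant = "reduced"),
            class = "local_interaction_field")
}

test_that("weighted combination across parameters is a plain linear combination", {
  b <- array(0, c(1, 1, 2, 1))
  b[1, 1, 1, 1] <- 1
  b[1, 1, 2, 1] <- 2
  fld <- make_field(b)
  expect_equal(as.vector(weight_combine(fld, c(2, 0.5))), 3)
  expect_equal(as.vector(weight_combine(fld, c(0, 1))), 2)   # one-hot selects a slice
  expect_error(weight_combine(fld, c(0, 0)), "positive")
  expect_error(weight_combine(fld, c(1, 1, 1)), "expected 2 weights")
})

test_that("norm collapse follows the Euclidean definition", {
  expect_equal(norm_collapse(array(c(3, 4), 2), 1), 5)
  zero <- array(0, c(2, 2, 3))
  expect_equal(norm_collapse(zero, 3), matrix(0, 2, 2))
  ones <- array(1, c(2, 2, 13, 4))
  expect_equal(unique(as.vector(norm_collapse(ones, 3))), sqrt(13))
  expect_error(norm_collapse(ones, integer(0)), "no axes")
})

test_that("the norm summary chain is consistent and absolutely homogeneous", {
  set.seed(5)
  b <- array(rnorm(2 * 2 * 3 * 4), c(2, 2, 3, 4),
             dimnames = list(c("A", "B"), c("A", "B"), paste0("p", 1:3),
                             paste0("s", 1:4)))
  ns <- norm_summary(make_field(b))
  expect_equal(ns$beta_ij[1, 2], sqrt(sum(b[1, 2, , ]^2)))
  # beta_ik excludes self-interaction
  expect_equal(ns$beta_ik[1, 2], sqrt(sum(ns$beta_ijk[1, 2, 2]^2)))
  # homogeneity: scaling the field scales every norm by |c|
  ns3 <- norm_summary(make_field(-3 * b))
  expect_equal(ns3$beta_i, 3 * ns$beta_i)
})

test_that("basic summaries use the midpoint-median convention", {
  x <- array(c(1, 2, 3, 4), c(1, 4))
  expect_equal(basic_summary(x, "median", 2), 2.5)
  expect_equal(basic_summary(array(c(1, 2, 3), 3), "median", 1), 2)
  expect_equal(basic_summary(x, "max", 2), 4)
  expect_equal(basic_summary(x, "mean", 2), 2.5)
})

test_that("peak median classifies by sign majority and finds the dominant mode", {
  const <- peak_median(rep(0.3, 10))
  expect_equal(const$direction, "positive")
  expect_equal(const$M, 0.3)

  split <- peak_median(c(rep(1, 6), rep(-1, 4)))
  expect_equal(split$direction, "excluded")
  expect_equal(split$reason, "no_sign_majority")

  few <- peak_median(c(0.1, 0.2, 0.3))
  expect_equal(few$direction, "excluded")
  expect_equal(few$reason, "too_few_values")

  set.seed(77)
  vals <- c(rnorm(850, 1, 0.1), rnorm(150, 3, 0.1))
  pk <- peak_median(vals)
  expect_equal(pk$direction, "positive")
  expect_lt(abs(pk$M - 1.0), 0.05)      # dominant-mode median, not the mean (~1.3)
  expect_gt(abs(mean(vals) - pk$M), 0.2)
})

test_that("peak median of a unimodal symmetric sample approaches the sample median", {
  set.seed(88)
  x <- rnorm(10000, 2, 1)
  pk <- peak_median(x)
  expect_lt(abs(pk$M - median(x)), 0.02)
})

test_that("global values follow the majority and magnitude-ratio rules", {
  unanimous <- global_beta(c(0.5, 0.5, 0.5), rep("positive", 3))
  expect_equal(unanimous$value, 0.5)
  expect_equal(unanimous$status, "determinate")

  ratio10 <- global_beta(c(1.0, -0.1), c("positive", "negative"))
  expect_equal(ratio10$value, 1.0)
  expect_equal(ratio10$status, "determinate")

  balanced <- global_beta(c(1.0, -1.0), c("positive", "negative"))
  expect_equal(balanced$status, "indeterminate")

  # ratio exactly two stays indeterminate (strict inequality)
  tie <- global_beta(c(1.0, -0.5), c("positive", "negative"))
  expect_equal(tie$status, "indeterminate")

  none <- global_beta(c(NA, NA), c("excluded", "excluded"))
  expect_equal(none$status, "no_qualifying_parameter")

  # order invariance
  M <- c(0.4, -0.1, 0.5, 0.45)
  dir <- c("positive", "negative", "positive", "positive")
  perm <- c(3, 1, 4, 2)
  expect_equal(global_beta(M, dir), global_beta(M[perm], dir[perm]))
})

test_that("loosening the majority threshold only moves results toward determinacy", {
  set.seed(123)
  for (rep in 1:20) {
    vals <- rnorm(30, mean = runif(1, -0.5, 0.5))
    p8 <- peak_median(vals, majority = 0.8)
    p5 <- peak_median(vals, majority = 0.5)
    if (p8$direction != "excluded") expect_equal(p5$direction, p8$direction)
  }
  for (rep in 1:20) {
    m <- 5
    M <- rnorm(m)
    dir <- ifelse(M > 0, "positive", "negative")
    g8 <- global_beta(M, dir, majority = 0.8)
    g5 <- global_beta(M, dir, majority = 0.5)
    if (g8$status == "determinate") expect_equal(g5$status, "determinate")
  }
})

test_that("field-level summarization assembles peaks into a status matrix", {
  set.seed(9)
  d <- 2; m <- 3; N <- 30
  b <- array(NA_real_, c(d, d, m, N),
             dimnames = list(c("A", "B"), c("A", "B"), paste0("p", 1:m),
                             paste0("s", 1:N)))
  b[1, 1, , ] <- abs(rnorm(m * N)) + 0.1          # consistently positive
  b[1, 2, , ] <- -(abs(rnorm(m * N)) + 0.1)       # consistently negative
  b[2, 1, , ] <- rnorm(m * N)                     # no majority anywhere
  b[2, 2, , ] <- rep(c(1, -1), length.out = m * N) * 0.5
  g <- summarize_interactions(make_field(b))
  expect_equal(g$status[1, 1], "determinate")
  expect_gt(g$beta[1, 1], 0)
  expect_equal(g$status[1, 2], "determinate")
  expect_lt(g$beta[1, 2], 0)
  expect_equal(g$status[2, 1], "no_qualifying_parameter")
  expect_true(is.na(g$beta[2, 1]))

  # weighted path collapses parameters before peak extraction
  gw <- summarize_interactions(make_field(b), weights = c(1, 0, 0))
  expect_equal(gw$status[1, 1], "determinate")
})
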