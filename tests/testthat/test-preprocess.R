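test_that("zero filtering keeps exactly the taxa present everywhere", {
  a <- make_abund(rbind(c(1, 2, 3), c(4, 0, 6), c(7, 8, 9)),
                  taxa = c("A", "B", "C"))
  z <- drop_zero_taxa(a)
  expect_equal(colnames(z$abundance$values), c("A", "C"))
  expect_equal(z$dropped, "B")

  nozero <- make_abund(matrix(1:9, 3, 3))
  z2 <- drop_zero_taxa(nozero)
  expect_identical(z2$abundance$values, nozero$values)
  expect_length(z2$dropped, 0)

  single <- make_abund(matrix(c(1, 0, 2), 3, 1))
  expect_error(drop_zero_taxa(single), "no taxon")
})

test_that("unit-variance scaling divides by sample sd without centering", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(10, 20, 30))
  s <- scale_unit_variance(m)
  expect_equal(s$values[, "a"], c(1, 2, 3))     # sd already 1
  expect_equal(s$values[, "b"], c(1, 2, 3))     # sd = 2
  expect_equal(unname(s$scale_factors), c(1, 2, 10))
  expect_equal(apply(s$values, 2, var), c(a = 1, b = 1, c = 1), tolerance = 1e-12)
  expect_error(scale_unit_variance(cbind(ok = 1:3, bad = c(5, 5, 5))), "bad")
})

test_that("scaling preserves signs and zero patterns", {
  set.seed(7)
  m <- matrix(rnorm(40), 10, 4)
  m[sample(40, 6)] <- 0
  s <- scale_unit_variance(m)
  expect_identical(sign(s$values), sign(m))
})

test_that("collinearity pruning reaches full rank, verified against an SVD oracle", {
  set.seed(11)
  full <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("c1", "c2", "c3")))
  pr <- collinearity_prune(full, seed = 1)
  expect_length(pr$removed, 0)
  expect_identical(pr$values, full)

  dup <- cbind(c1 = rnorm(6), c2 = rnorm(6))
  dup <- cbind(dup, c3 = 2 * dup[, "c1"])
  svd_rank <- sum(svd(dup)$d > max(dim(dup)) * .Machine$double.eps * max(svd(dup)$d))
  pr2 <- collinearity_prune(dup, seed = 3)
  expect_length(pr2$removed, 1)
  expect_true(pr2$removed %in% c("c1", "c3"))
  expect_equal(ncol(pr2$values), svd_rank)
  expect_equal(pr2$rank_after, svd_rank)
})

test_that("pruning is deterministic, idempotent, and rank-stable across seeds", {
  set.seed(21)
  base <- matrix(rnorm(40), 10, 4,
                 dimnames = list(NULL, paste0("v", 1:4)))
  m <- cbind(base, v5 = base[, 1] - base[, 2], v6 = 3 * base[, 3])

  p1 <- collinearity_prune(m, seed = 5)
  p1b <- collinearity_prune(m, seed = 5)
  expect_identical(p1$removed, p1b$removed)

  # idempotence: the pruned matrix passes a second test unchanged
  p2 <- collinearity_prune(p1$values, seed = 99)
  expect_length(p2$removed, 0)

  # different seeds may remove different labels but identical rank
  ranks <- vapply(1:5, function(s) ncol(collinearity_prune(m, seed = s)$values),
                  integer(1))
  expect_true(all(ranks == ranks[1]))
})

test_that("centered pruning catches affine collinearity that difference designs see", {
  set.seed(31)
  base <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- cbind(base, d = 5 + 2 * base[, "a"])   # affine, not proportional
  expect_length(collinearity_prune(m, seed = 1)$removed, 0)
  prc <- collinearity_prune(m, seed = 1, center = TRUE)
  expect_length(prc$removed, 1)
  expect_true(prc$removed %in% c("a", "d"))
})

test_that("dimension checks grade sample size against variable count", {
  expect_equal(check_dimensions(150, 30), "ok")
  expect_error(check_dimensions(10, 10), "must exceed")
  expect_warning(st <- check_dimensions(25, 13), "twice")
  expect_equal(st, "warning")
})

test_that("the preprocessing pipeline composes and reports its actions", {
  set.seed(5)
  av <- matrix(runif(40, 1, 10), 10, 4)
  av[3, 2] <- 0                                # taxon t2 unobserved once
  a <- make_abund(av)
  ev <- cbind(matrix(rnorm(20), 10, 2), 0)
  ev[, 3] <- 4 * ev[, 1]                       # collinear parameter
  e <- make_env(ev, params = c("pH", "moist", "pH4x"))
  pre <- preprocess(a, e, seed = 2)
  expect_equal(pre$report$dropped_taxa, "t2")
  expect_equal(nrow(pre$report$removed_collinear), 1)
  expect_true(pre$report$removed_collinear$label %in% c("pH", "pH4x"))
  expect_equal(ncol(pre$environment$values), 2)
  expect_equal(apply(pre$abundance$values, 2, var),
               c(t1 = 1, t3 = 1, t4 = 1), tolerance = 1e-12)
})
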