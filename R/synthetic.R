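#' Parameters of a generalized Lotka-Volterra gradient simulation
#'
#' The community follows coupled logistic dynamics along a scalar
#' environmental gradient theta (playing the role of time):
#' `dA_i/dtheta = r_i * A_i * (1 - A_i/K_i + sum_j B_ij * A_j / K_i)`.
#' The effective directed interaction coefficient of taxon j on taxon i, in
#' the normalization used by the interaction estimator, is
#' `beta*_ij = r_i * B_ij / K_i` (off-diagonal) and `-r_i / K_i` for the
#' self-limitation term.
#'
#' @param r per-species growth rates (per unit theta).
#' @param K per-species carrying capacities (> 0).
#' @param B d x d interaction matrix (dimensionless; diagonal ignored, the
#'   self term is the logistic `-A_i/K_i`).
#' @param A0 initial abundances (> 0).
#' @param theta_grid strictly increasing gradient values at which samples are
#'   taken.
#' @return A `glv_params` list.
#' @export
glv_params <- function(r, K, B, A0, theta_grid) {
  d <- length(r)
  B <- as.matrix(B)
  stopifnot(length(K) == d, length(A0) == d, all(dim(B) == d),
            all(K > 0), all(A0 > 0),
            length(theta_grid) >= 2, all(diff(theta_grid) > 0))
  structure(list(r = r, K = K, B = B, A0 = A0, theta_grid = theta_grid),
            class = "glv_params")
}

glv_rhs <- function(t, A, parms) {
  with(parms, list(r * A * (1 - A / K + as.vector(B %*% A) / K)))
}

glv_effective_beta <- function(params) {
  eff <- params$B * (params$r / params$K)
  diag(eff) <- -params$r / params$K
  eff
}

#' Simulate community abundances along an environmental gradient
#'
#' Integrates the generalized Lotka-Volterra system with an adaptive
#' Runge-Kutta scheme (relative tolerance 1e-8) and records the community
#' state at each gradient value. With `site_jitter > 0` every sample is an
#' independent site: its initial abundances are jittered multiplicatively
#' (`A0 * (1 + u * site_jitter)`, `u ~ Uniform(-1, 1)`) before integrating to
#' the sample's gradient position, emulating cross-sectional field designs in
#' which plots differ in their starting communities. `site_jitter = 0` gives
#' one shared trajectory. The true slope of every taxon at every sample (the
#' right-hand side of the dynamics, evaluated at the sampled state before any
#' noise) and the effective interaction matrix are stored as ground truth.
#'
#' @param params a [glv_params()] object.
#' @param noise multiplicative uniform measurement noise applied to the
#'   sampled abundances (see [perturb()]); 0 for none.
#' @param seed integer seed (site jitter and noise).
#' @param site_jitter relative half-width of the per-site initial-abundance
#'   jitter.
#' @return A `synthetic_truth` list: `abundance` (absolute mode),
#'   `environment` (single parameter `theta`), `true_p` (d x 1 x N array of
#'   noise-free slopes), `true_beta` (effective interaction matrix),
#'   `true_beta_sign`, `params` and `seed`.
#' @export
simulate_glv_gradient <- function(params, noise = 0, seed = 1L, site_jitter = 0) {
  stopifnot(inherits(params, "glv_params"), noise >= 0, noise < 1,
            site_jitter >= 0, site_jitter < 1)
  d <- length(params$r)
  grid <- params$theta_grid
  N <- length(grid)
  taxa <- if (!is.null(colnames(params$B))) colnames(params$B)
          else paste0("sp", seq_len(d))
  A <- matrix(NA_real_, N, d, dimnames = list(paste0("s", seq_len(N)), taxa))
  truep <- array(NA_real_, dim = c(d, 1, N),
                 dimnames = list(taxa, "theta", rownames(A)))
  pl <- list(r = params$r, K = params$K, B = params$B)
  integrate_to <- function(a0, times) {
    deSolve::ode(y = a0, times = times, func = glv_rhs, parms = pl,
                 method = "ode45", rtol = 1e-8, atol = 1e-10)
  }
  with_preserved_seed(seed, {
    if (site_jitter > 0) {
      for (k in seq_len(N)) {
        a0 <- params$A0 * (1 + stats::runif(d, -1, 1) * site_jitter)
        out <- integrate_to(a0, unique(c(0, grid[k])))
        A[k, ] <- out[nrow(out), -1]
      }
    } else {
      prepend <- grid[1] > 0
      out <- integrate_to(params$A0, if (prepend) c(0, grid) else grid)
      A[, ] <- out[if (prepend) -1 else seq_len(N), -1]
    }
    if (any(!is.finite(A)) || any(A <= 0)) {
      stop("gLV integration produced nonpositive or non-finite abundances")
    }
    for (k in seq_len(N)) truep[, 1, k] <- unlist(glv_rhs(grid[k], A[k, ], pl))
    if (noise > 0) A[, ] <- perturb(A, noise)
  })
  eff <- glv_effective_beta(params)
  dimnames(eff) <- list(taxa, taxa)
  structure(list(
    abundance = abundance_table(A, mode = "absolute"),
    environment = environment_table(matrix(grid, ncol = 1,
                                           dimnames = list(rownames(A), "theta"))),
    true_p = truep,
    true_beta = eff,
    true_beta_sign = sign(eff),
    params = params, seed = seed, generator = "glv_gradient"),
    class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth (%s): %d samples x %d taxa, %d parameter(s)\n",
              x$generator, nrow(x$abundance$values), ncol(x$abundance$values),
              ncol(x$environment$values)))
  invisible(x)
}

#' Two-species ground-truth presets
#'
#' Frozen study conditions for parameter-recovery experiments, chosen so that
#' the sampled sites carry identifiable variation (site-to-site initial
#' variability, gradient window covering the transient dynamics):
#'
#' * `simulate_predator_prey()`: taxon 2 (prey) benefits taxon 1 (predator),
#'   `B12 = +0.8`; the predator suppresses the prey, `B21 = -0.8`;
#'   `r = (1.2, 0.8)`, `K = (1, 1)`, `A0 = (0.3, 1.2)`, 60 sites at gradient
#'   positions drawn uniformly on (0.2, 6), site jitter 0.5. Effective
#'   coefficients `beta*_12 = +0.96`, `beta*_21 = -0.64`.
#' * `simulate_mutualism()`: reciprocal facilitation `B12 = B21 = +0.9`,
#'   `r = (1, 0.7)`, `K = (1, 1)`, `A0 = (0.3, 0.5)`, 60 sites on (0.1, 2),
#'   site jitter 0.8. Effective coefficients `+0.90` and `+0.63`.
#'
#' @param seed integer seed (gradient positions, site jitter, noise).
#' @param noise multiplicative measurement noise level.
#' @param n_samples number of sites.
#' @return A `synthetic_truth` (see [simulate_glv_gradient()]).
#' @export
simulate_predator_prey <- function(seed = 1L, noise = 0, n_samples = 60L) {
  grid <- with_preserved_seed(seed, sort(stats::runif(n_samples, 0.2, 6)))
  params <- glv_params(r = c(1.2, 0.8), K = c(1, 1),
                       B = matrix(c(0, 0.8, -0.8, 0), 2, 2, byrow = TRUE),
                       A0 = c(0.3, 1.2), theta_grid = grid)
  simulate_glv_gradient(params, noise = noise, seed = seed + 1L, site_jitter = 0.5)
}

#' @rdname simulate_predator_prey
#' @export
simulate_mutualism <- function(seed = 1L, noise = 0, n_samples = 60L) {
  grid <- with_preserved_seed(seed, sort(stats::runif(n_samples, 0.1, 2)))
  params <- glv_params(r = c(1, 0.7), K = c(1, 1),
                       B = matrix(c(0, 0.9, 0.9, 0), 2, 2, byrow = TRUE),
                       A0 = c(0.3, 0.5), theta_grid = grid)
  simulate_glv_gradient(params, noise = noise, seed = seed + 1L, site_jitter = 0.8)
}

#' Ground-truth slope field of a synthetic dataset, in estimation units
#'
#' Converts the generator's true abundance slopes into a `local_slope_field`
#' on the same scale as estimates obtained after unit-variance scaling of the
#' tables: slopes are multiplied by `sd(theta) / sd(A_i)`. Useful for
#' validating the interaction stage in isolation from slope estimation.
#'
#' @param truth a `synthetic_truth` with `true_p`.
#' @param scaled logical; convert to the unit-variance scale (default) or
#'   keep raw units.
#' @return A `local_slope_field`.
#' @export
truth_slope_field <- function(truth, scaled = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"), !is.null(truth$true_p))
  p <- truth$true_p
  if (scaled) {
    sd_a <- apply(truth$abundance$values, 2, stats::sd)
    sd_th <- apply(truth$environment$values, 2, stats::sd)
    for (al in seq_len(dim(p)[2])) {
      p[, al, ] <- p[, al, ] * sd_th[al] / sd_a
    }
  }
  structure(list(p = p, cross_slopes = NULL, model_variant = "truth"),
            class = "local_slope_field")
}

#' Analytic multilinear dataset with closed-form slopes
#'
#' Abundances are explicit affine functions of independently drawn
#' environmental parameters, `A_i = intercept_i + sum_a coef[i, a] * Theta_a`
#' (optionally with multiplicative noise), so the true slope field is the
#' constant coefficient matrix and there are no taxon-taxon interactions.
#'
#' @param coef d x m matrix of linear coefficients.
#' @param intercept length-d vector keeping all abundances positive.
#' @param n_samples number of samples (must exceed `m + d`).
#' @param noise multiplicative noise level.
#' @param seed integer seed.
#' @param theta_range range from which each parameter is drawn uniformly.
#' @return A `synthetic_truth` with constant `true_p`.
#' @export
make_analytic_dataset <- function(coef, intercept, n_samples, noise = 0,
                                  seed = 1L, theta_range = c(0, 1)) {
  coef <- as.matrix(coef)
  d <- nrow(coef); m <- ncol(coef)
  stopifnot(length(intercept) == d, n_samples > m + d)
  taxa <- paste0("t", seq_len(d))
  pars <- paste0("theta", seq_len(m))
  samples <- paste0("s", seq_len(n_samples))
  truth <- with_preserved_seed(seed, {
    Th <- matrix(stats::runif(n_samples * m, theta_range[1], theta_range[2]),
                 n_samples, m, dimnames = list(samples, pars))
    A <- rep(intercept, each = n_samples) + Th %*% t(coef)
    dimnames(A) <- list(samples, taxa)
    if (any(A <= 0)) stop("analytic dataset has nonpositive abundances; increase intercepts")
    if (noise > 0) A <- perturb(A, noise)
    list(Th = Th, A = A)
  })
  truep <- array(NA_real_, dim = c(d, m, n_samples),
                 dimnames = list(taxa, pars, samples))
  for (k in seq_len(n_samples)) truep[, , k] <- coef
  structure(list(
    abundance = abundance_table(truth$A, mode = "absolute"),
    environment = environment_table(truth$Th),
    true_p = truep,
    true_beta = matrix(0, d, d, dimnames = list(taxa, taxa)),
    true_beta_sign = matrix(0, d, d, dimnames = list(taxa, taxa)),
    params = list(coef = coef, intercept = intercept), seed = seed,
    generator = "analytic_linear"),
    class = "synthetic_truth")
}

#' Quadratic-coupling dataset with a known interaction derivative
#'
#' A two-taxon construction on a single gradient with a closed-form
#' interaction: `A_j = theta` and `A_i = theta^2`, so taxon i's slope is
#' `p_i = 2 * theta = 2 * A_j` and the derivative of `p_i` with respect to
#' `A_j` equals exactly 2 everywhere (and `p_j = 1`, constant). The gradient
#' is sampled away from zero to keep abundances strictly positive.
#'
#' @param n_samples number of samples.
#' @param theta_range positive gradient range.
#' @param seed integer seed.
#' @return A `synthetic_truth`; `params$dp_dA` records the constant
#'   derivative (2) of taxon i's slope with respect to taxon j's abundance.
#' @export
make_squared_pair_dataset <- function(n_samples = 80L, theta_range = c(0.5, 2),
                                      seed = 1L) {
  stopifnot(theta_range[1] > 0)
  samples <- paste0("s", seq_len(n_samples))
  th <- with_preserved_seed(seed, sort(stats::runif(n_samples, theta_range[1], theta_range[2])))
  A <- cbind(ti = th^2, tj = th)
  rownames(A) <- samples
  Th <- matrix(th, ncol = 1, dimnames = list(samples, "theta"))
  truep <- array(NA_real_, dim = c(2, 1, n_samples),
                 dimnames = list(c("ti", "tj"), "theta", samples))
  truep[1, 1, ] <- 2 * th
  truep[2, 1, ] <- 1
  structure(list(
    abundance = abundance_table(A, mode = "absolute"),
    environment = environment_table(Th),
    true_p = truep,
    true_beta = NULL, true_beta_sign = NULL,
    params = list(dp_dA = 2), seed = seed,
    generator = "squared_pair"),
    class = "synthetic_truth")
}

#' Closure of absolute abundances to relative fractions
#'
#' Divides each sample's abundances by the sample total, producing rows that
#' sum to one. Idempotent.
#'
#' @param a an `abundance_table` (any mode) with positive row sums.
#' @return A relative-mode `abundance_table`.
#' @export
closure <- function(a) {
  stopifnot(inherits(a, "abundance_table"))
  rs <- rowSums(a$values)
  if (any(rs <= 0)) {
    stop(sprintf("zero row sum for sample '%s'", rownames(a$values)[which.min(rs)]))
  }
  abundance_table(sweep(a$values, 1, rs, "/"), mode = "relative")
}

#' Study-shaped synthetic community emulation
#'
#' Generates a dataset with the shape of a 150-plot grassland soil survey:
#' 150 samples, 17 taxa and 13 environmental parameters by default. The
#' community is a generalized Lotka-Volterra assembly whose carrying
#' capacities follow Gaussian niche responses along a latent environmental
#' gradient (species optima spread over the gradient, niche floor 0.8 of the
#' maximum), with total community capacity held constant along the gradient
#' and a uniform baseline resource competition (-0.12) that regulates total
#' biomass -- the regime in which overall microbial cell numbers change
#' little while composition turns over, which is the stated premise for
#' analysing relative abundances. Sparse signed pairwise interactions
#' (default ~20% of off-diagonal entries, magnitudes 0.05-0.2) are layered on
#' top; candidate interaction matrices are redrawn until the community
#' permits full coexistence along the whole gradient. Every sample is an
#' independent site started at the local competitive equilibrium with a
#' total-preserving compositional jitter and integrated to its gradient
#' position.
#'
#' The environmental parameters are smooth monotone functions of the latent
#' gradient in realistic soil ranges (pH 4-8, moisture 10-45%, nutrient and
#' carbon pools) plus independent measurement scatter. With
#' `collinear_pair = TRUE` a 14th parameter is added with nitrate exactly
#' proportional to ammonium, so the environment matrix has numerical rank 13.
#'
#' The modeled taxa are the abundant subset of a larger community:
#' `n_background` additional background species are simulated and enter the
#' closure denominator but are not reported, as when abundant phylum-level
#' groups are extracted from a survey. Relative-abundance rows therefore sum
#' to slightly less than one, and the reported composition is not exactly
#' closed (a fully closed composition makes the abundance-difference
#' regression design exactly singular).
#'
#' @param seed integer seed.
#' @param n_samples,n_taxa,n_params dataset shape (parameters cover up to 13
#'   named soil variables).
#' @param collinear_pair add the exactly collinear nitrate/ammonium pair.
#' @param interaction_density fraction of nonzero off-diagonal extra
#'   interactions.
#' @param interaction_range magnitude range of the extra interactions.
#' @param n_background unreported background species in the closure.
#' @return A `synthetic_truth`; `abundance` is relative-mode (reported taxa
#'   only), `absolute` the matching absolute table, `absolute_full` /
#'   `true_p_full` the whole community, `true_p` the absolute-scale slopes of
#'   the reported taxa, `true_beta_sign` the sign pattern of the pairwise
#'   interaction terms, and `latent_gradient` the per-sample gradient
#'   positions.
#' @export
emulate_study <- function(seed = 1L, n_samples = 150L, n_taxa = 17L,
                          n_params = 13L, collinear_pair = FALSE,
                          interaction_density = 0.2,
                          interaction_range = c(0.05, 0.2),
                          n_background = 3L) {
  if (n_params > 13L) stop("at most 13 independent parameters are defined")
  d <- n_taxa + n_background
  taxa <- c(paste0("taxon", sprintf("%02d", seq_len(n_taxa))),
            paste0("bg", seq_len(n_background)))
  c_base <- 0.12; sigma <- 2; niche_floor <- 0.8
  tmin <- 0; tmax <- 6; burn <- 0.5; site_jitter <- 0.25
  gen <- with_preserved_seed(seed, {
    r <- stats::runif(d, 0.95, 1.05)
    Kb <- stats::runif(d, 1.0, 1.3)
    mu <- sample(seq(tmin - 0.5, tmax + 0.5, length.out = d) +
                   stats::runif(d, -0.2, 0.2))
    Ktot <- sum(Kb) * (niche_floor + (1 - niche_floor) * 0.6)
    Kfun <- function(t) {
      k <- Kb * (niche_floor + (1 - niche_floor) * exp(-(t - mu)^2 / (2 * sigma^2)))
      k * Ktot / sum(k)
    }
    # redraw the sparse interactions until all species coexist everywhere
    feasible <- FALSE
    B <- NULL
    for (try in seq_len(200L)) {
      B <- matrix(-c_base, d, d); diag(B) <- 0
      off <- which(row(B) != col(B))
      nz <- off[stats::runif(length(off)) < interaction_density]
      B[nz] <- B[nz] + sample(c(-1, 1), length(nz), replace = TRUE) *
        stats::runif(length(nz), interaction_range[1], interaction_range[2])
      feasible <- TRUE
      for (tt in seq(tmin - burn, tmax, by = 1)) {
        eq <- tryCatch(solve(diag(d) - B, Kfun(tt)), error = function(e) NULL)
        if (is.null(eq) || any(eq < 0.06 * mean(eq))) { feasible <- FALSE; break }
      }
      if (feasible) break
    }
    if (!feasible) stop("no feasible community found for this seed")
    grid <- sort(stats::runif(n_samples, tmin + 0.2, tmax))
    A_eq <- solve(diag(d) - B, Kfun(tmin - burn))
    S_eq <- sum(A_eq)
    rhs <- function(t, A, parms) {
      K <- Kfun(t)
      list(r * A * (1 - A / K + as.vector(B %*% A) / K))
    }
    A <- matrix(NA_real_, n_samples, d,
                dimnames = list(paste0("s", seq_len(n_samples)), taxa))
    truep <- array(NA_real_, dim = c(d, 1, n_samples),
                   dimnames = list(taxa, "latent", rownames(A)))
    for (k in seq_len(n_samples)) {
      a0 <- A_eq * (1 + stats::runif(d, -1, 1) * site_jitter)
      a0 <- a0 * S_eq / sum(a0)
      out <- deSolve::ode(y = a0, times = c(tmin - burn, grid[k]), func = rhs,
                          parms = NULL, method = "ode45",
                          rtol = 1e-8, atol = 1e-10)
      A[k, ] <- out[nrow(out), -1]
      truep[, 1, k] <- unlist(rhs(grid[k], A[k, ], NULL))
    }
    if (any(!is.finite(A)) || any(A <= 0)) {
      stop("emulation produced nonpositive abundances")
    }
    K_mid <- Kfun((tmin + tmax) / 2)
    eff <- B * (r / K_mid)
    diag(eff) <- -r / K_mid
    dimnames(eff) <- list(taxa, taxa)
    list(A = A, truep = truep, grid = grid, B = B, r = r, eff = eff)
  })
  g <- gen$grid
  g01 <- (g - min(g)) / (max(g) - min(g))
  param_defs <- list(
    pH            = function(x) 4 + 4 * x,
    moisture      = function(x) 10 + 35 * x^0.8,
    NH4           = function(x) 2 + 18 * (1 - x)^1.2,
    Nmin          = function(x) 5 + 40 * (1 - 0.7 * x),
    microbial_C   = function(x) 200 + 800 * sqrt(x),
    organic_C     = function(x) 15 + 45 * x,
    inorganic_C   = function(x) 1 + 9 * (1 - x),
    root_biomass  = function(x) 0.2 + 1.3 * x * (1.5 - x),
    root_N        = function(x) 0.8 + 1.2 * x,
    root_C        = function(x) 38 + 8 * (1 - x),
    soil_CN       = function(x) 9 + 7 * (1 - x)^0.5,
    microbial_CN  = function(x) 5 + 6 * x^1.5,
    root_CN       = function(x) 20 + 25 * (1 - 0.6 * x))
  env <- with_preserved_seed(seed + 2000L, {
    cols <- lapply(param_defs[seq_len(min(n_params, length(param_defs)))],
                   function(f) {
      base <- f(g01)
      base * (1 + stats::runif(n_samples, -1, 1) * 0.08)
    })
    do.call(cbind, cols)
  })
  rownames(env) <- rownames(gen$A)
  if (collinear_pair) {
    env <- cbind(env, NO3 = 2.5 * env[, "NH4"])
  }
  absolute_full <- abundance_table(gen$A, mode = "absolute")
  relative_full <- closure(absolute_full)
  keep <- seq_len(n_taxa)
  relative <- relative_full
  relative$values <- relative_full$values[, keep, drop = FALSE]
  absolute <- absolute_full
  absolute$values <- absolute_full$values[, keep, drop = FALSE]
  structure(list(
    abundance = relative,
    absolute = absolute,
    absolute_full = absolute_full,
    environment = environment_table(env),
    latent_gradient = g,
    true_p = gen$truep[keep, , , drop = FALSE],
    true_p_full = gen$truep,
    true_beta = gen$eff[keep, keep],
    true_beta_sign = sign(gen$eff[keep, keep]),
    params = list(r = gen$r, B = gen$B, c_base = c_base, sigma = sigma,
                  niche_floor = niche_floor),
    seed = seed,
    generator = "emulate_study"),
    class = "synthetic_truth")
}

#' Compositional approximation error of the closure derivative
#'
#' For a synthetic dataset with known absolute-scale slopes, compares the
#' exact gradient of the relative abundances,
#' `dx_i/dtheta = (p_i * S - y_i * sum_j p_j) / S^2` with `S = sum_j y_j`,
#' against the high-diversity approximation `p_i / S` that underpins using
#' relative abundances in the interaction analysis. The relative error is
#' computed directly as `|approx - exact| / |exact|`.
#'
#' @param truth a `synthetic_truth` carrying an absolute abundance table
#'   (field `absolute`, or an absolute-mode `abundance`) and `true_p`.
#' @return A d x N matrix of relative errors (NA where the exact derivative
#'   is zero).
#' @export
closure_approximation_error <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"), !is.null(truth$true_p))
  y <- if (!is.null(truth$absolute_full)) truth$absolute_full$values
       else if (!is.null(truth$absolute)) truth$absolute$values
       else truth$abundance$values
  p <- if (!is.null(truth$true_p_full)) truth$true_p_full[, 1, ]
       else truth$true_p[, 1, ]      # d x N, absolute-scale slopes
  yT <- t(y)                         # d x N
  S <- colSums(yT)
  psum <- colSums(p)
  exact <- sweep(p, 2, S, "*") - sweep(yT, 2, psum, "*")
  exact <- sweep(exact, 2, S^2, "/")
  approx <- sweep(p, 2, S, "/")
  err <- abs(approx - exact) / abs(exact)
  err[exact == 0] <- NA_real_
  err
}
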