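#' Robust no-intercept linear fit (Huber M-estimator)
#'
#' Iteratively reweighted least squares with the Huber loss (tuning constant
#' `k = 1.345`, the classical 95%-efficiency default) and MAD residual scale.
#' There is no intercept: differences of identical samples are exactly zero,
#' so the difference regressions of this package pass through the origin. The
#' fit coincides with ordinary least squares when the residuals are zero, and
#' an all-zero response returns all-zero coefficients.
#'
#' @param X design matrix (q x v), full column rank, q > v.
#' @param y response vector of length q.
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on the coefficient change.
#' @param k Huber tuning constant.
#' @return Numeric coefficient vector of length v.
#' @export
robust_fit_no_intercept <- function(X, y, max_iter = 100L, tol = 1e-6, k = 1.345) {
  fit <- fit_core(X, y, max_iter = max_iter, tol = tol, k = k)
  if (!fit$converged) {
    warning("robust fit did not converge within max_iter; returning last iterate",
            call. = FALSE)
  }
  fit$coefficients
}

# Shared validation + dispatch to the compiled IRLS core; returns the
# coefficient vector with a convergence flag so tensor-scale callers can
# aggregate non-convergence warnings instead of emitting one per fit.
fit_core <- function(X, y, max_iter = 100L, tol = 1e-6, k = 1.345) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  q <- nrow(X)
  v <- ncol(X)
  if (q <= v) {
    stop(sprintf("underdetermined fit: %d observations for %d coefficients", q, v))
  }
  y <- as.numeric(y)
  if (all(y == 0)) {
    return(list(coefficients = numeric(v), converged = TRUE))
  }
  res <- .irls_huber(X, y, as.integer(max_iter), tol, k)
  list(coefficients = as.vector(res$coefficients), converged = res$converged)
}

#' Estimate the per-sample abundance slope field p
#'
#' For each taxon i and base sample k, the abundance differences to all other
#' samples are regressed (robustly, without intercept) on the corresponding
#' environmental-parameter differences. The fitted coefficients are the local
#' rates of change `p[i, alpha, k]` of taxon i's abundance along parameter
#' alpha at sample k. The `"full"` variant adds the abundance differences of
#' the other taxa as regressors and stores their coefficients as
#' `cross_slopes[i, j, k]`.
#'
#' @param a preprocessed `abundance_table`.
#' @param e aligned, preprocessed `environment_table`.
#' @param variant `"reduced"` (environment differences only) or `"full"`.
#' @param max_iter,tol passed to [robust_fit_no_intercept()].
#' @return A `local_slope_field`: list with `p` (d x m x N array),
#'   `cross_slopes` (d x d x N array, full variant only) and `model_variant`.
#' @export
estimate_p <- function(a, e, variant = c("reduced", "full"),
                       max_iter = 100L, tol = 1e-6) {
  variant <- match.arg(variant)
  stopifnot(inherits(a, "abundance_table"), inherits(e, "environment_table"))
  A <- a$values
  Th <- e$values
  if (!identical(rownames(A), rownames(Th))) {
    stop("tables are not aligned; run align_tables()/preprocess() first")
  }
  N <- nrow(A); d <- ncol(A); m <- ncol(Th)
  v <- if (variant == "reduced") m else m + d - 1
  if (N - 1 <= v) {
    stop(sprintf("too few samples (%d) for %d regressors", N, v))
  }
  p <- array(NA_real_, dim = c(d, m, N),
             dimnames = list(colnames(A), colnames(Th), rownames(A)))
  cross <- if (variant == "full") {
    array(NA_real_, dim = c(d, d, N),
          dimnames = list(colnames(A), colnames(A), rownames(A)))
  }
  n_nonconv <- 0L
  for (k in seq_len(N)) {
    dTh <- Th[-k, , drop = FALSE] - rep(Th[k, ], each = N - 1)
    dA <- A[-k, , drop = FALSE] - rep(A[k, ], each = N - 1)
    for (i in seq_len(d)) {
      X <- if (variant == "reduced") dTh else cbind(dTh, dA[, -i, drop = FALSE])
      fit <- fit_core(X, dA[, i], max_iter = max_iter, tol = tol)
      if (!fit$converged) n_nonconv <- n_nonconv + 1L
      cf <- fit$coefficients
      p[i, , k] <- cf[seq_len(m)]
      if (variant == "full" && d > 1) cross[i, -i, k] <- cf[-seq_len(m)]
    }
  }
  if (n_nonconv > 0) {
    warning(sprintf("%d of %d slope fits did not fully converge; last iterates used",
                    n_nonconv, d * N), call. = FALSE)
  }
  structure(list(p = p, cross_slopes = cross, model_variant = variant),
            class = "local_slope_field")
}

#' Estimate the per-sample, per-gradient interaction field beta
#'
#' For each taxon i, parameter alpha and base sample k, the differences of the
#' slope field `p[i, alpha, ]` to all other samples are regressed on the
#' abundance differences of all taxa (including taxon i itself, whose
#' coefficient carries the self-interaction). The interaction coefficient is
#' the fitted abundance coefficient divided by taxon i's abundance in the base
#' sample: `beta[i, j, alpha, k] = coef(A_j) / A[k, i]`. The `"full"` variant
#' adds the environment differences as regressors and stores their
#' coefficients as the environmental sensitivity of the slope field.
#'
#' @param p a `local_slope_field` estimated (or constructed from simulator
#'   truth) on the same tables.
#' @param a preprocessed `abundance_table` (all abundances strictly positive).
#' @param e aligned `environment_table`.
#' @param variant `"reduced"` (abundance differences only) or `"full"`.
#' @param max_iter,tol passed to [robust_fit_no_intercept()].
#' @return A `local_interaction_field`: list with `beta`
#'   (d x d x m x N array), `env_sensitivity` (d x m x m x N, full variant
#'   only) and `model_variant`.
#' @export
estimate_beta <- function(p, a, e, variant = c("reduced", "full"),
                          max_iter = 100L, tol = 1e-6) {
  variant <- match.arg(variant)
  stopifnot(inherits(p, "local_slope_field"),
            inherits(a, "abundance_table"), inherits(e, "environment_table"))
  A <- a$values
  Th <- e$values
  N <- nrow(A); d <- ncol(A); m <- ncol(Th)
  if (!identical(dim(p$p), c(d, m, N))) {
    stop("slope field dimensions do not match the tables")
  }
  if (any(A <= 0)) stop("all abundances must be strictly positive (drop_zero_taxa)")
  v <- if (variant == "reduced") d else d + m
  if (N - 1 <= v) {
    stop(sprintf("too few samples (%d) for %d regressors", N, v))
  }
  beta <- array(NA_real_, dim = c(d, d, m, N),
                dimnames = list(colnames(A), colnames(A), colnames(Th), rownames(A)))
  env_sens <- if (variant == "full") {
    array(NA_real_, dim = c(d, m, m, N),
          dimnames = list(colnames(A), colnames(Th), colnames(Th), rownames(A)))
  }
  n_nonconv <- 0L
  for (k in seq_len(N)) {
    dA <- A[-k, , drop = FALSE] - rep(A[k, ], each = N - 1)
    X <- if (variant == "reduced") dA
         else cbind(dA, Th[-k, , drop = FALSE] - rep(Th[k, ], each = N - 1))
    for (i in seq_len(d)) {
      for (al in seq_len(m)) {
        y <- p$p[i, al, -k] - p$p[i, al, k]
        fit <- tryCatch(
          fit_core(X, y, max_iter = max_iter, tol = tol),
          error = function(err) {
            stop(sprintf("interaction fit failed for taxon '%s', parameter '%s', sample '%s': %s",
                         colnames(A)[i], colnames(Th)[al], rownames(A)[k],
                         conditionMessage(err)), call. = FALSE)
          })
        if (!fit$converged) n_nonconv <- n_nonconv + 1L
        cf <- fit$coefficients
        beta[i, , al, k] <- cf[seq_len(d)] / A[k, i]
        if (variant == "full") env_sens[i, al, , k] <- cf[d + seq_len(m)]
      }
    }
  }
  if (n_nonconv > 0) {
    warning(sprintf("%d of %d interaction fits did not fully converge; last iterates used",
                    n_nonconv, d * m * N), call. = FALSE)
  }
  structure(list(beta = beta, env_sensitivity = env_sens, model_variant = variant),
            class = "local_interaction_field")
}

#' @export
print.local_slope_field <- function(x, ...) {
  d <- dim(x$p)
  cat(sprintf("local_slope_field (%s variant): %d taxa x %d parameters x %d samples\n",
              x$model_variant, d[1], d[2], d[3]))
  invisible(x)
}

#' @export
print.local_interaction_field <- function(x, ...) {
  d <- dim(x$beta)
  cat(sprintf("local_interaction_field (%s variant): %d x %d taxa x %d parameters x %d samples\n",
              x$model_variant, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Long-format export of slope and interaction fields
#'
#' Tensors are serialized as long-format tables: `(taxon, parameter, sample,
#' value)` for the slope field and `(taxon_i, taxon_j, parameter, sample,
#' value)` for the interaction field.
#'
#' @param x a `local_slope_field` or `local_interaction_field`.
#' @return A data frame in long format.
#' @export
field_long <- function(x) {
  if (inherits(x, "local_slope_field")) {
    dn <- dimnames(x$p)
    out <- expand.grid(taxon = dn[[1]], parameter = dn[[2]], sample = dn[[3]],
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out$value <- as.vector(x$p)
    out
  } else if (inherits(x, "local_interaction_field")) {
    dn <- dimnames(x$beta)
    out <- expand.grid(taxon_i = dn[[1]], taxon_j = dn[[2]], parameter = dn[[3]],
                       sample = dn[[4]], KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    out$value <- as.vector(x$beta)
    out
  } else {
    stop("field_long expects a local_slope_field or local_interaction_field")
  }
}

#' @rdname field_long
#' @param path output TSV path.
#' @export
write_field_tsv <- function(x, path) {
  utils::write.table(field_long(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
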