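#' Linear combination of the interaction field across parameters
#'
#' Collapses `beta[i, j, alpha, k]` into `beta[i, j, k]` by a weighted sum
#' over the environmental parameters. Weights are user-supplied prior
#' knowledge (e.g. ordination eigenvalues); they must be finite, nonnegative
#' and not all zero.
#'
#' @param field a `local_interaction_field`.
#' @param weights numeric vector, one nonnegative weight per parameter.
#' @return A d x d x N array of combined interaction values.
#' @export
weight_combine <- function(field, weights) {
  stopifnot(inherits(field, "local_interaction_field"))
  b <- field$beta
  m <- dim(b)[3]
  if (length(weights) != m) {
    stop(sprintf("expected %d weights, got %d", m, length(weights)))
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and nonnegative")
  }
  if (all(weights == 0)) stop("at least one weight must be positive")
  d <- dim(b)[1]; N <- dim(b)[4]
  out <- array(0, dim = c(d, d, N),
               dimnames = dimnames(b)[c(1, 2, 4)])
  for (al in seq_len(m)) {
    slab <- b[, , al, , drop = FALSE]
    dim(slab) <- c(d, d, N)
    out <- out + weights[al] * slab
  }
  out
}

#' Euclidean-norm collapse of an interaction tensor
#'
#' Applies the standard Euclidean norm over the collapsed axes, supporting the
#' summarization chain: `beta_ijk` (norm over parameters), `beta_ij` (then
#' over samples), `beta_ik` (over the influencing taxa j, excluding i itself)
#' and `beta_i` (over samples). All outputs are nonnegative; direction
#' information is deliberately lost.
#'
#' @param x a numeric array (or a `local_interaction_field`, whose `beta`
#'   tensor is used).
#' @param axes integer axes of `x` to collapse (summed over, in quadrature).
#' @param exclude_self for square taxon x taxon arrays: drop the diagonal
#'   (j = i) terms from the collapse.
#' @return An array with the collapsed axes removed (or a scalar).
#' @export
norm_collapse <- function(x, axes, exclude_self = FALSE) {
  if (inherits(x, "local_interaction_field")) x <- x$beta
  stopifnot(is.numeric(x))
  if (is.null(dim(x))) x <- array(x, dim = length(x))
  nd <- length(dim(x))
  if (length(axes) == 0) stop("no axes selected to collapse")
  if (any(axes < 1 | axes > nd)) stop("axis out of range")
  if (exclude_self) {
    stopifnot(nd >= 2, dim(x)[1] == dim(x)[2])
    for (i in seq_len(dim(x)[1])) {
      idx <- as.list(rep(TRUE, nd))
      idx[[1]] <- i; idx[[2]] <- i
      x <- do.call(`[<-`, c(list(x), idx, list(value = 0)))
    }
  }
  keep <- setdiff(seq_len(nd), axes)
  if (length(keep) == 0) return(sqrt(sum(x^2)))
  sqrt(apply(x^2, keep, sum))
}

#' Norm summary chain of an interaction field
#'
#' Convenience wrapper computing the full chain of norm summaries from a
#' `local_interaction_field`: per-sample pair strengths `beta_ijk`, global
#' pair strengths `beta_ij`, per-sample incoming influence `beta_ik`
#' (excluding self-interaction) and global incoming influence `beta_i`.
#'
#' @param field a `local_interaction_field`.
#' @return A list with `beta_ijk`, `beta_ij`, `beta_ik` and `beta_i`.
#' @export
norm_summary <- function(field) {
  stopifnot(inherits(field, "local_interaction_field"))
  b <- field$beta
  beta_ijk <- norm_collapse(b, 3)             # over parameters -> d x d x N
  beta_ij <- norm_collapse(beta_ijk, 3)       # over samples    -> d x d
  beta_ik <- norm_collapse(beta_ijk, 2, exclude_self = TRUE)  # -> d x N
  beta_i <- norm_collapse(beta_ik, 2)         # over samples    -> d
  list(beta_ijk = beta_ijk, beta_ij = beta_ij, beta_ik = beta_ik, beta_i = beta_i)
}

#' Standard summary statistics over selected tensor axes
#'
#' @param x numeric array (or `local_interaction_field`).
#' @param stat one of `"mean"`, `"median"`, `"max"`, `"min"`. Medians of an
#'   even count are the midpoint mean.
#' @param axes axes to collapse.
#' @return Array with the collapsed axes removed (or a scalar).
#' @export
basic_summary <- function(x, stat = c("mean", "median", "max", "min"), axes) {
  stat <- match.arg(stat)
  if (inherits(x, "local_interaction_field")) x <- x$beta
  if (is.null(dim(x))) x <- array(x, dim = length(x))
  nd <- length(dim(x))
  if (length(axes) == 0) stop("no axes selected to collapse")
  if (any(axes < 1 | axes > nd)) stop("axis out of range")
  f <- switch(stat, mean = mean, median = stats::median, max = max, min = min)
  keep <- setdiff(seq_len(nd), axes)
  if (length(keep) == 0) return(f(x))
  apply(x, keep, f)
}

#' Peak-median summary of interaction values across samples
#'
#' Implements the density-peak compromise to the interaction center: values
#' are first classified by sign; if at least `majority` of the non-zero values
#' share a sign, that sign is the direction, otherwise the entry is excluded.
#' For a directed entry, a Gaussian kernel density estimate (Silverman
#' bandwidth) is computed over the values, the global density mode located,
#' and the peak membership taken as the contiguous region where the density
#' stays at or above half the mode height; the summary `M` is the median of
#' the member values. Exact zeros do not count toward either sign.
#'
#' @param values numeric vector of interaction values across samples.
#' @param majority required sign-majority fraction (default 0.8).
#' @param min_values minimum number of non-zero values (default 5).
#' @param rel_height peak-membership cut as a fraction of the mode density.
#' @param bw kernel bandwidth rule, passed to [stats::density()].
#' @return A list with `M`, `direction` (`"positive"`, `"negative"` or
#'   `"excluded"`), `support` (majority-sign fraction) and `reason` for
#'   exclusion (`NA` otherwise).
#' @export
peak_median <- function(values, majority = 0.8, min_values = 5L,
                        rel_height = 0.5, bw = "nrd0") {
  values <- values[is.finite(values)]
  nz <- values[values != 0]
  if (length(nz) < min_values) {
    return(list(M = NA_real_, direction = "excluded", support = NA_real_,
                reason = "too_few_values"))
  }
  frac_pos <- mean(nz > 0)
  support <- max(frac_pos, 1 - frac_pos)
  direction <- if (frac_pos >= majority) "positive"
               else if (1 - frac_pos >= majority) "negative"
               else "excluded"
  if (direction == "excluded") {
    return(list(M = NA_real_, direction = "excluded", support = support,
                reason = "no_sign_majority"))
  }
  M <- density_peak_median(values, rel_height = rel_height, bw = bw)
  if (!is.na(M) && sign(M) != ifelse(direction == "positive", 1, -1)) {
    # guard: global mode on the minority side; restrict to the majority sign
    M <- density_peak_median(nz[sign(nz) == ifelse(direction == "positive", 1, -1)],
                             rel_height = rel_height, bw = bw)
  }
  list(M = M, direction = direction, support = support, reason = NA_character_)
}

density_peak_median <- function(x, rel_height = 0.5, bw = "nrd0") {
  if (max(x) - min(x) < 1e-12 * max(1, abs(x[1]))) return(stats::median(x))
  dens <- stats::density(x, bw = bw, n = 512)
  mode_idx <- which.max(dens$y)
  cut <- dens$y[mode_idx] * rel_height
  lo <- mode_idx
  while (lo > 1 && dens$y[lo - 1] >= cut) lo <- lo - 1
  hi <- mode_idx
  while (hi < length(dens$y) && dens$y[hi + 1] >= cut) hi <- hi + 1
  members <- x[x >= dens$x[lo] & x <= dens$x[hi]]
  if (length(members) == 0) members <- x
  stats::median(members)
}

#' Global directed interaction value from per-parameter peak summaries
#'
#' Combines the per-parameter peak medians `M_alpha` of one ordered taxon pair
#' into a single global value with a determinacy status. If at least
#' `majority` of the qualifying (non-excluded) `M_alpha` share a sign, the
#' global value is the median of that sign's `M_alpha`. Otherwise the medians
#' of the positive and negative groups are compared: if the magnitude ratio of
#' the larger to the smaller strictly exceeds `ratio_threshold`, the
#' larger-magnitude median wins; a ratio at or below the threshold is
#' indeterminate. With no qualifying parameter the status is
#' `"no_qualifying_parameter"`.
#'
#' @param M numeric vector of per-parameter peak medians.
#' @param direction character vector parallel to `M` (`"positive"`,
#'   `"negative"`, `"excluded"`).
#' @param majority majority fraction (default 0.8).
#' @param ratio_threshold magnitude-ratio threshold (default 2; strict).
#' @return A list with `value` and `status` (`"determinate"`,
#'   `"indeterminate"` or `"no_qualifying_parameter"`).
#' @export
global_beta <- function(M, direction, majority = 0.8, ratio_threshold = 2) {
  stopifnot(length(M) == length(direction))
  q <- direction %in% c("positive", "negative")
  if (!any(q)) {
    return(list(value = NA_real_, status = "no_qualifying_parameter"))
  }
  Mq <- M[q]
  dq <- direction[q]
  n_pos <- sum(dq == "positive")
  n_neg <- sum(dq == "negative")
  frac <- max(n_pos, n_neg) / length(Mq)
  if (frac >= majority && n_pos != n_neg) {
    winner <- if (n_pos > n_neg) "positive" else "negative"
    return(list(value = stats::median(Mq[dq == winner]), status = "determinate"))
  }
  M_pos <- if (n_pos > 0) stats::median(Mq[dq == "positive"]) else NA_real_
  M_neg <- if (n_neg > 0) stats::median(Mq[dq == "negative"]) else NA_real_
  if (is.na(M_pos)) return(list(value = M_neg, status = "determinate"))
  if (is.na(M_neg)) return(list(value = M_pos, status = "determinate"))
  ratio <- max(abs(M_pos), abs(M_neg)) / min(abs(M_pos), abs(M_neg))
  if (ratio > ratio_threshold) {
    value <- if (abs(M_pos) > abs(M_neg)) M_pos else M_neg
    return(list(value = value, status = "determinate"))
  }
  list(value = NA_real_, status = "indeterminate")
}

#' Summarize a local interaction field into a global interaction matrix
#'
#' Applies [peak_median()] per ordered taxon pair and parameter (across
#' samples), then [global_beta()] per ordered pair (across parameters). When
#' `weights` are supplied, the field is first combined across parameters with
#' [weight_combine()] and the peak summary applied to the combined values
#' (one pseudo-parameter).
#'
#' @param field a `local_interaction_field`.
#' @param majority sign-majority fraction used at both stages.
#' @param ratio_threshold magnitude-ratio threshold of the global stage.
#' @param weights optional nonnegative per-parameter weights.
#' @param min_values,rel_height,bw passed to [peak_median()].
#' @return A `global_interaction_matrix`: list with `beta` (d x d, `NA` where
#'   not determinate), `status` (d x d character), per-pair-parameter `peaks`
#'   (`M`, `direction`, `support` arrays) and the method settings.
#' @export
summarize_interactions <- function(field, majority = 0.8, ratio_threshold = 2,
                                   weights = NULL, min_values = 5L,
                                   rel_height = 0.5, bw = "nrd0") {
  stopifnot(inherits(field, "local_interaction_field"))
  b <- field$beta
  if (!is.null(weights)) {
    comb <- weight_combine(field, weights)
    d <- dim(comb)[1]
    b <- array(comb, dim = c(d, d, 1, dim(comb)[3]),
               dimnames = c(dimnames(comb)[1:2], list("combined"),
                            dimnames(comb)[3]))
  }
  d <- dim(b)[1]; m <- dim(b)[3]
  taxa <- dimnames(b)[[1]]
  M <- array(NA_real_, dim = c(d, d, m), dimnames = c(dimnames(b)[1:2], dimnames(b)[3]))
  dir <- array("excluded", dim = c(d, d, m), dimnames = dimnames(M))
  supp <- array(NA_real_, dim = c(d, d, m), dimnames = dimnames(M))
  gb <- matrix(NA_real_, d, d, dimnames = list(taxa, taxa))
  status <- matrix(NA_character_, d, d, dimnames = list(taxa, taxa))
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      for (al in seq_len(m)) {
        pk <- peak_median(b[i, j, al, ], majority = majority,
                          min_values = min_values, rel_height = rel_height, bw = bw)
        M[i, j, al] <- pk$M
        dir[i, j, al] <- pk$direction
        supp[i, j, al] <- pk$support
      }
      g <- global_beta(M[i, j, ], dir[i, j, ], majority = majority,
                       ratio_threshold = ratio_threshold)
      gb[i, j] <- g$value
      status[i, j] <- g$status
    }
  }
  structure(list(beta = gb, status = status,
                 peaks = list(M = M, direction = dir, support = supp),
                 method = list(majority = majority, ratio_threshold = ratio_threshold,
                               weighted = !is.null(weights))),
            class = "global_interaction_matrix")
}

#' @export
print.global_interaction_matrix <- function(x, ...) {
  d <- nrow(x$beta)
  tab <- table(factor(x$status, levels = c("determinate", "indeterminate",
                                           "no_qualifying_parameter")))
  cat(sprintf("global_interaction_matrix: %d x %d taxa\n", d, d))
  cat(sprintf("  determinate: %d, indeterminate: %d, no qualifying parameter: %d\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Write a global interaction matrix as TSV
#'
#' Long format with one row per ordered taxon pair: influenced taxon (row),
#' influencing taxon (column), global value and determinacy status.
#'
#' @param x a `global_interaction_matrix`.
#' @param path output TSV path.
#' @export
write_global_matrix <- function(x, path) {
  stopifnot(inherits(x, "global_interaction_matrix"))
  dn <- dimnames(x$beta)
  df <- expand.grid(taxon_i = dn[[1]], taxon_j = dn[[2]],
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$beta <- as.vector(x$beta)
  df$status <- as.vector(x$status)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
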