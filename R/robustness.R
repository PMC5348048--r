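#' Multiplicative uniform perturbation
#'
#' Each entry is independently multiplied by `(1 + u * e)` with
#' `u ~ Uniform(-1, 1)`, so the perturbed value stays within a relative error
#' band of width `e` around the original. Draws come from the current RNG
#' stream; seed control belongs to the caller.
#'
#' @param values numeric matrix or vector.
#' @param e error level (relative half-width, `e >= 0`).
#' @return Perturbed object of the same shape.
#' @export
perturb <- function(values, e) {
  stopifnot(is.numeric(e), length(e) == 1, e >= 0)
  if (e == 0) return(values)
  values * (1 + stats::runif(length(values), -1, 1) * e)
}

#' Specification of a perturbation assay
#'
#' @param target what to perturb: `"environment"`, `"abundance"`, `"both"`
#'   (multiplicative noise) or `"subsample"` (random sampling of sites
#'   without replacement).
#' @param error_level relative error level `e` (ignored for subsampling).
#' @param subsample_fraction fraction of samples retained (default 0.9).
#' @param n_iter number of iterations (default 1000).
#' @param seed integer seed.
#' @return A `perturbation_spec` list.
#' @export
perturbation_spec <- function(target = c("environment", "abundance", "both", "subsample"),
                              error_level = 0.05, subsample_fraction = 0.9,
                              n_iter = 1000L, seed = 1L) {
  target <- match.arg(target)
  stopifnot(error_level >= 0,
            subsample_fraction > 0, subsample_fraction <= 1,
            n_iter >= 1)
  structure(list(target = target, error_level = error_level,
                 subsample_fraction = subsample_fraction,
                 n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Joint random subsampling of sites
#'
#' Retains `floor(fraction * N)` samples, drawn without replacement from the
#' current RNG stream; the same samples are kept in both tables. Sampling with
#' replacement is deliberately not offered: duplicated samples make the
#' difference regressions degenerate.
#'
#' @param a an `abundance_table`.
#' @param e an aligned `environment_table`.
#' @param fraction fraction of samples to retain.
#' @param min_keep the retained count must strictly exceed this (defaults to
#'   the larger of the taxon and parameter counts, the regressor count of the
#'   reduced difference regressions).
#' @return A list with the subsampled `abundance` and `environment` tables.
#' @export
subsample <- function(a, e, fraction = 0.9, min_keep = NULL) {
  stopifnot(inherits(a, "abundance_table"), inherits(e, "environment_table"),
            fraction > 0, fraction <= 1)
  if (!identical(rownames(a$values), rownames(e$values))) {
    stop("tables are not aligned")
  }
  N <- nrow(a$values)
  n_keep <- floor(fraction * N)
  if (is.null(min_keep)) min_keep <- max(ncol(a$values), ncol(e$values))
  if (n_keep <= min_keep) {
    stop(sprintf("subsample would retain %d samples for %d regression variables",
                 n_keep, min_keep))
  }
  idx <- sort(sample.int(N, n_keep, replace = FALSE))
  a$values <- a$values[idx, , drop = FALSE]
  e$values <- e$values[idx, , drop = FALSE]
  list(abundance = a, environment = e)
}

perturb_tables <- function(a, e, spec) {
  if (spec$target == "subsample") {
    return(subsample(a, e, spec$subsample_fraction))
  }
  if (spec$target %in% c("abundance", "both")) {
    a$values <- perturb(a$values, spec$error_level)
  }
  if (spec$target %in% c("environment", "both")) {
    e$values <- perturb(e$values, spec$error_level)
  }
  list(abundance = a, environment = e)
}

#' Perturbation robustness of the global interaction estimates
#'
#' Reruns the full inference chain (preprocessing, slope field, interaction
#' field, global summarization) on perturbed or subsampled copies of the raw
#' input tables and summarizes, per ordered taxon pair, the spread of the
#' determinate global values: mean, t-based and percentile 95% confidence
#' intervals, and a two-sided one-sample t-test against zero. Iterations in
#' which a pair is not determinate are dropped for that pair and reflected in
#' `n_valid`. Perturbation applies to the raw (pre-scaling) values; scaling
#' and pruning are recomputed in every iteration. Deterministic given
#' `spec$seed`.
#'
#' @param a raw `abundance_table`.
#' @param e raw `environment_table`.
#' @param spec a [perturbation_spec()] (`n_iter >= 2`).
#' @param variant model variant for both estimation stages.
#' @param majority,ratio_threshold,weights,min_values summarization settings.
#' @param scale,prune preprocessing switches.
#' @param slope_field optional `local_slope_field` (e.g. ground truth from
#'   [truth_slope_field()]) used instead of slope estimation; under
#'   subsampling it is restricted to the retained samples.
#' @return A `robustness_report`: list with `pairs` (data frame of per-pair
#'   statistics), `iterations` (d x d x n_iter array of global values, `NA`
#'   where indeterminate), the base `global` matrix and the `spec`.
#' @export
robustness_run <- function(a, e, spec, variant = "reduced",
                           majority = 0.8, ratio_threshold = 2, weights = NULL,
                           min_values = 5L, scale = TRUE, prune = TRUE,
                           slope_field = NULL) {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (spec$n_iter < 2) stop("n_iter must be at least 2 to form confidence intervals")
  base <- infer_interactions(a, e, variant = variant, majority = majority,
                             ratio_threshold = ratio_threshold, weights = weights,
                             min_values = min_values, scale = scale, prune = prune,
                             seed = spec$seed, slope_field = slope_field)
  taxa <- rownames(base$global$beta)
  d <- length(taxa)
  iters <- array(NA_real_, dim = c(d, d, spec$n_iter),
                 dimnames = list(taxa, taxa, NULL))
  with_preserved_seed(spec$seed, {
    for (it in seq_len(spec$n_iter)) {
      tabs <- perturb_tables(a, e, spec)
      sf_it <- slope_field
      if (!is.null(sf_it)) {
        keep <- rownames(tabs$abundance$values)
        sf_it$p <- sf_it$p[, , keep, drop = FALSE]
      }
      res <- tryCatch(
        infer_interactions(tabs$abundance, tabs$environment, variant = variant,
                           majority = majority, ratio_threshold = ratio_threshold,
                           weights = weights, min_values = min_values,
                           scale = scale, prune = prune, seed = spec$seed + it,
                           slope_field = sf_it),
        error = function(err) NULL)
      if (is.null(res)) next
      g <- res$global
      common <- intersect(taxa, rownames(g$beta))
      vals <- g$beta[common, common, drop = FALSE]
      vals[g$status[common, common, drop = FALSE] != "determinate"] <- NA_real_
      iters[common, common, it] <- vals
    }
  })
  pairs <- do.call(rbind, lapply(seq_len(d), function(i) {
    do.call(rbind, lapply(seq_len(d), function(j) {
      v <- iters[i, j, ]
      v <- v[!is.na(v)]
      n <- length(v)
      if (n >= 2) {
        mu <- mean(v)
        s <- stats::sd(v)
        half <- stats::qt(0.975, n - 1) * s / sqrt(n)
        tstat <- if (s > 0) mu / (s / sqrt(n)) else if (mu == 0) 0 else Inf
        pval <- if (s > 0) 2 * stats::pt(-abs(tstat), n - 1) else if (mu == 0) 1 else 0
        qs <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
        data.frame(taxon_i = taxa[i], taxon_j = taxa[j],
                   base = base$global$beta[i, j], mean = mu, sd = s,
                   ci_low = mu - half, ci_high = mu + half,
                   pct_low = qs[1], pct_high = qs[2],
                   t = tstat, p_value = pval, n_valid = n,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(taxon_i = taxa[i], taxon_j = taxa[j],
                   base = base$global$beta[i, j], mean = NA_real_, sd = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   pct_low = NA_real_, pct_high = NA_real_,
                   t = NA_real_, p_value = NA_real_, n_valid = n,
                   stringsAsFactors = FALSE)
      }
    }))
  }))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, iterations = iters, global = base$global,
                 spec = spec),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("robustness_report: %s perturbation, e = %g, %d iterations\n",
              x$spec$target, x$spec$error_level, x$spec$n_iter))
  ok <- x$pairs$n_valid >= 2
  cat(sprintf("  pairs with >= 2 determinate iterations: %d of %d\n",
              sum(ok), nrow(x$pairs)))
  invisible(x)
}
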