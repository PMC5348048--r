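#' Remove taxa not observed in every sample
#'
#' The interaction estimator divides by each taxon's abundance, so taxa with a
#' zero abundance in any sample cannot enter the analysis and are removed.
#' Column order of the retained taxa is preserved.
#'
#' @param a an `abundance_table`.
#' @return A list with the filtered `abundance_table` and `dropped`, the
#'   identifiers of removed taxa.
#' @export
drop_zero_taxa <- function(a) {
  stopifnot(inherits(a, "abundance_table"))
  keep <- apply(a$values > 0, 2, all)
  if (!any(keep)) stop("no taxon observed in all samples")
  dropped <- colnames(a$values)[!keep]
  a$values <- a$values[, keep, drop = FALSE]
  a2 <- suppressWarnings(abundance_table(a$values, mode = a$mode))
  list(abundance = a2, dropped = dropped)
}

#' Scale columns to unit variance without centering
#'
#' Each column is divided by its sample standard deviation (n - 1 denominator);
#' no centering is applied, so signs and zero patterns are preserved.
#'
#' @param values numeric matrix (samples x variables).
#' @return A list with the scaled `values` and the `scale_factors` used
#'   (the per-column standard deviations).
#' @export
scale_unit_variance <- function(values) {
  values <- as.matrix(values)
  s <- apply(values, 2, stats::sd)
  zero <- !is.finite(s) | s <= 0
  if (any(zero)) {
    stop(sprintf("constant column(s) cannot be scaled to unit variance: %s",
                 paste(colnames(values)[zero], collapse = ", ")))
  }
  list(values = sweep(values, 2, s, "/"), scale_factors = s)
}

numeric_rank <- function(x) {
  if (ncol(x) == 0) return(0L)
  d <- svd(x, nu = 0, nv = 0)$d
  if (d[1] == 0) return(0L)
  sum(d > max(dim(x)) * .Machine$double.eps * d[1])
}

#' Remove collinear columns until the matrix has full column rank
#'
#' Numerical rank uses the standard convention: singular values below
#' `max(dim) * eps * sigma_max` count as zero. While the matrix is rank
#' deficient, the columns flagged as pivot-dependent by column-pivoted QR form
#' the candidate set and one candidate is removed uniformly at random
#' (deterministic given `seed`); the test is then repeated.
#'
#' @param values numeric matrix (samples x variables).
#' @param labels column labels; defaults to `colnames(values)`.
#' @param seed integer seed controlling the random removal.
#' @param center assess rank on the column-centered matrix (the returned
#'   values stay uncentered). The difference regressions cancel constant
#'   offsets between samples, so affine column relationships — including the
#'   unit-sum closure of complete compositions — degenerate their design;
#'   centering exposes exactly those.
#' @return A list with the pruned `values`, `removed` labels in removal order,
#'   and `rank_before` / `rank_after`.
#' @export
collinearity_prune <- function(values, labels = colnames(values), seed = 1L,
                               center = FALSE) {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- paste0("c", seq_len(ncol(values)))
  colnames(values) <- labels
  rank_of <- function(v) {
    if (center) v <- sweep(v, 2, colMeans(v))
    numeric_rank(v)
  }
  rank_before <- rank_of(values)
  removed <- character(0)
  with_preserved_seed(seed, {
    repeat {
      r <- rank_of(values)
      if (r == ncol(values)) break
      v <- if (center) sweep(values, 2, colMeans(values)) else values
      qrx <- qr(v, LAPACK = TRUE)
      cand <- colnames(values)[qrx$pivot[(r + 1):ncol(values)]]
      drop_one <- cand[sample.int(length(cand), 1)]
      removed <- c(removed, drop_one)
      values <- values[, setdiff(colnames(values), drop_one), drop = FALSE]
    }
  })
  list(values = values, removed = removed,
       rank_before = rank_before, rank_after = ncol(values))
}

# Runs expr with a locally seeded RNG, restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  eval.parent(substitute(expr))
}

#' Check that the sample count supports the regression design
#'
#' The difference regressions are underdetermined unless the number of samples
#' exceeds the number of regression variables; fewer than twice as many
#' samples as variables is flagged as a warning (overfitting risk).
#'
#' @param n_samples,n_variables positive integers.
#' @return `"ok"`, `"warning"` or an error.
#' @export
check_dimensions <- function(n_samples, n_variables) {
  stopifnot(n_samples >= 1, n_variables >= 1)
  if (n_samples <= n_variables) {
    stop(sprintf("sample number (%d) must exceed the number of variables (%d)",
                 n_samples, n_variables))
  }
  if (n_samples < 2 * n_variables) {
    warning(sprintf("fewer than twice as many samples (%d) as variables (%d)",
                    n_samples, n_variables), call. = FALSE)
    return("warning")
  }
  "ok"
}

#' Preprocess aligned abundance and environment tables for estimation
#'
#' Applies, in order: sample alignment, zero-taxon removal, unit-variance
#' scaling (uncentered), collinearity pruning of the abundance matrix, then of
#' the environment matrix, and a dimensional sanity check of the combined
#' regressor count.
#'
#' @param a an `abundance_table`.
#' @param e an `environment_table`.
#' @param seed integer seed for the random collinearity removal.
#' @param scale logical; divide columns by their standard deviation.
#' @param prune logical; remove collinear columns.
#' @return A list with the processed `abundance` and `environment` tables and
#'   a `report` (class `preprocess_report`) recording dropped taxa, removed
#'   collinear columns, matrix ranks and scale factors.
#' @export
preprocess <- function(a, e, seed = 1L, scale = TRUE, prune = TRUE) {
  al <- align_tables(a, e)
  zf <- drop_zero_taxa(al$abundance)
  av <- zf$abundance$values
  ev <- al$environment$values
  sf_a <- sf_e <- NULL
  if (scale) {
    sa <- scale_unit_variance(av)
    se <- scale_unit_variance(ev)
    av <- sa$values; sf_a <- sa$scale_factors
    ev <- se$values; sf_e <- se$scale_factors
  }
  removed <- data.frame(label = character(0), type = character(0),
                        stringsAsFactors = FALSE)
  ranks <- list()
  if (prune) {
    pa <- collinearity_prune(av, seed = seed, center = TRUE)
    pe <- collinearity_prune(ev, seed = seed + 1L, center = TRUE)
    av <- pa$values
    ev <- pe$values
    removed <- rbind(
      if (length(pa$removed)) data.frame(label = pa$removed, type = "taxon"),
      if (length(pe$removed)) data.frame(label = pe$removed, type = "parameter"))
    if (is.null(removed)) removed <- data.frame(label = character(0), type = character(0))
    ranks <- list(abundance = c(before = pa$rank_before, after = pa$rank_after),
                  environment = c(before = pe$rank_before, after = pe$rank_after))
  }
  status <- check_dimensions(nrow(av), ncol(av) + ncol(ev))
  a2 <- zf$abundance
  a2$values <- av
  e2 <- al$environment
  e2$values <- ev
  report <- structure(list(dropped_taxa = zf$dropped,
                           removed_collinear = removed,
                           ranks = ranks,
                           scale_factors = list(abundance = sf_a, environment = sf_e),
                           dimension_status = status),
                      class = "preprocess_report")
  list(abundance = a2, environment = e2, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("preprocess_report\n")
  cat("  dropped taxa:", if (length(x$dropped_taxa)) paste(x$dropped_taxa, collapse = ", ") else "none", "\n")
  cat("  removed collinear:",
      if (nrow(x$removed_collinear)) paste(x$removed_collinear$label, collapse = ", ") else "none", "\n")
  cat("  dimension check:", x$dimension_status, "\n")
  invisible(x)
}
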