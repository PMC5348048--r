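#' Spearman co-occurrence matrix
#'
#' Pairwise Spearman rank correlations (average ranks for ties) between taxon
#' abundance profiles — the symmetric co-occurrence baseline the directed
#' interaction matrix is contrasted with. Constant taxa yield `NA` entries
#' (flagged with a warning).
#'
#' @param a an `abundance_table` with at least 3 samples.
#' @return A `correlation_matrix`: list with `rho` (d x d symmetric matrix).
#' @export
spearman_matrix <- function(a) {
  stopifnot(inherits(a, "abundance_table"))
  if (nrow(a$values) < 3) stop("at least 3 samples required")
  consts <- apply(a$values, 2, function(x) max(x) - min(x) == 0)
  rho <- suppressWarnings(stats::cor(a$values, method = "spearman"))
  if (any(consts)) {
    warning(sprintf("constant taxa flagged as missing: %s",
                    paste(colnames(a$values)[consts], collapse = ", ")),
            call. = FALSE)
    rho[consts, ] <- NA_real_
    rho[, consts] <- NA_real_
    diag(rho)[consts] <- 1
  }
  structure(list(rho = rho), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix (Spearman): %d taxa\n", nrow(x$rho)))
  invisible(x)
}

strength_category <- function(w, threshold) {
  cut(abs(w), breaks = c(threshold, 2 * threshold, 4 * threshold, Inf),
      labels = c("weak", "moderate", "strong"), right = FALSE,
      include.lowest = TRUE)
}

#' Thresholded network edge list
#'
#' For a `global_interaction_matrix`, exports directed edges for determinate
#' entries with `|beta| >= threshold` (default 0.1). In the interaction matrix
#' the column taxon influences the row taxon, so edges run from the
#' influencing taxon (`from = j`) to the influenced taxon (`to = i`). For a
#' `correlation_matrix`, exports undirected edges (each unordered pair once)
#' with `|rho| >= threshold` (default 0.4).
#'
#' @param x a `global_interaction_matrix` or `correlation_matrix`.
#' @param threshold positive magnitude threshold.
#' @return A data frame with columns `from`, `to`, `weight`, `sign`,
#'   `strength` and `directed`.
#' @export
export_network <- function(x, threshold = if (inherits(x, "correlation_matrix")) 0.4 else 0.1) {
  stopifnot(threshold > 0)
  if (inherits(x, "global_interaction_matrix")) {
    keep <- which(x$status == "determinate" & !is.na(x$beta) &
                    abs(x$beta) >= threshold, arr.ind = TRUE)
    w <- x$beta[keep]
    df <- data.frame(from = colnames(x$beta)[keep[, 2]],
                     to = rownames(x$beta)[keep[, 1]],
                     weight = w,
                     sign = ifelse(w > 0, "positive", "negative"),
                     strength = as.character(strength_category(w, threshold)),
                     directed = rep(TRUE, length(w)), stringsAsFactors = FALSE)
  } else if (inherits(x, "correlation_matrix")) {
    rho <- x$rho
    keep <- which(upper.tri(rho) & !is.na(rho) & abs(rho) >= threshold,
                  arr.ind = TRUE)
    w <- rho[keep]
    df <- data.frame(from = rownames(rho)[keep[, 1]],
                     to = colnames(rho)[keep[, 2]],
                     weight = w,
                     sign = ifelse(w > 0, "positive", "negative"),
                     strength = as.character(strength_category(w, threshold)),
                     directed = rep(FALSE, length(w)), stringsAsFactors = FALSE)
  } else {
    stop("export_network expects a global_interaction_matrix or correlation_matrix")
  }
  rownames(df) <- NULL
  df[order(-abs(df$weight)), , drop = FALSE]
}

#' Write an edge list as GraphML
#'
#' @param edges an edge list from [export_network()].
#' @param path output `.graphml` path.
#' @param vertices optional vertex names to include even if isolated.
#' @export
write_network_graphml <- function(edges, path, vertices = NULL) {
  directed <- if (nrow(edges) > 0) edges$directed[1] else TRUE
  verts <- unique(c(vertices, edges$from, edges$to))
  g <- igraph::graph_from_data_frame(
    edges[, setdiff(names(edges), "directed"), drop = FALSE],
    directed = directed,
    vertices = if (length(verts)) data.frame(name = verts) else NULL)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write an edge list as TSV
#'
#' @param edges an edge list from [export_network()].
#' @param path output TSV path.
#' @export
write_network_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Interaction profile along an environmental gradient
#'
#' Extracts, for one ordered taxon pair and one parameter, the per-sample
#' interaction values paired with the parameter's value in each sample,
#' sorted along the gradient — the data behind gradient scatter plots.
#'
#' @param field a `local_interaction_field`.
#' @param e the `environment_table` the field was estimated on.
#' @param taxon_i influenced taxon (row).
#' @param taxon_j influencing taxon (column).
#' @param param environmental parameter id.
#' @return A data frame with `sample`, `theta` and `beta`, sorted by `theta`.
#' @export
export_gradient_profile <- function(field, e, taxon_i, taxon_j, param) {
  stopifnot(inherits(field, "local_interaction_field"),
            inherits(e, "environment_table"))
  dn <- dimnames(field$beta)
  if (!taxon_i %in% dn[[1]]) stop(sprintf("unknown taxon '%s'", taxon_i))
  if (!taxon_j %in% dn[[2]]) stop(sprintf("unknown taxon '%s'", taxon_j))
  if (!param %in% dn[[3]] || !param %in% colnames(e$values)) {
    stop(sprintf("unknown parameter '%s'", param))
  }
  samples <- dn[[4]]
  df <- data.frame(sample = samples,
                   theta = e$values[samples, param],
                   beta = field$beta[taxon_i, taxon_j, param, ],
                   stringsAsFactors = FALSE)
  df <- df[order(df$theta), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a numeric matrix (heatmap data) as TSV
#'
#' @param m numeric matrix with dimnames.
#' @param path output TSV path.
#' @export
write_matrix_tsv <- function(m, path) {
  if (inherits(m, "global_interaction_matrix")) m <- m$beta
  if (inherits(m, "correlation_matrix")) m <- m$rho
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
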