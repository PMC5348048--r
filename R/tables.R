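#' Construct an abundance table
#'
#' An abundance table holds a samples x taxa matrix of nonnegative abundances,
#' either relative fractions (mode `"relative"`) or absolute counts/densities
#' (mode `"absolute"`). Row names are sample identifiers, column names taxon
#' identifiers; both must be unique and all values finite and nonnegative.
#'
#' In relative mode each row sum is checked against 1: sums above `1 + 1e-6`
#' raise an error, while sums below 1 only produce a warning, because dropping
#' taxa (e.g. zero filtering) legitimately breaks the unit-sum closure.
#'
#' @param values numeric matrix, samples in rows, taxa in columns, with
#'   dimnames giving sample and taxon identifiers.
#' @param mode `"relative"` or `"absolute"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("abundance values must be numeric")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("t", seq_len(ncol(values)))
  }
  obj <- structure(list(values = values, mode = mode),
                   class = "abundance_table")
  validate_abundance_table(obj)
  obj
}

validate_abundance_table <- function(x) {
  v <- x$values
  bad <- which(!is.finite(v), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-finite abundance at sample '%s', taxon '%s'",
                 rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
  }
  neg <- which(v < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative abundance (%g) at sample '%s', taxon '%s'",
                 v[neg[1, , drop = FALSE]],
                 rownames(v)[neg[1, 1]], colnames(v)[neg[1, 2]]))
  }
  if (anyDuplicated(rownames(v))) stop("duplicate sample ids in abundance table")
  if (anyDuplicated(colnames(v))) stop("duplicate taxon ids in abundance table")
  if (x$mode == "relative") {
    rs <- rowSums(v)
    if (any(rs > 1 + 1e-6)) {
      stop(sprintf("relative abundance row sum %.6f > 1 for sample '%s'",
                   max(rs), rownames(v)[which.max(rs)]))
    }
    if (any(rs < 1 - 1e-6)) {
      warning("some relative-abundance rows sum to less than 1 ",
              "(expected after taxon filtering)", call. = FALSE)
    }
  }
  invisible(x)
}

#' Construct an environment table
#'
#' Samples x parameters matrix of environmental measurements (mixed units).
#' All values must be finite; sample and parameter identifiers unique.
#'
#' @param values numeric matrix with dimnames (samples x parameters).
#' @return An object of class `environment_table`.
#' @export
environment_table <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("environmental values must be numeric")
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("p", seq_len(ncol(values)))
  }
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("missing or non-finite value at sample '%s', parameter '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids in environment table")
  if (anyDuplicated(colnames(values))) stop("duplicate parameter ids in environment table")
  structure(list(values = values), class = "environment_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s mode)\n",
              nrow(x$values), ncol(x$values), x$mode))
  invisible(x)
}

#' @export
print.environment_table <- function(x, ...) {
  cat(sprintf("environment_table: %d samples x %d parameters\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

read_table_tsv <- function(path, what) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("non-numeric cell in %s at row '%s', column '%s'",
                   what, rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    }
    storage.mode(m) <- "numeric"
  }
  m
}

#' Read an abundance table from TSV
#'
#' The file must be tab-delimited with a header row of taxon identifiers and
#' a first column of sample identifiers. Row and column order are preserved.
#'
#' @param path file path.
#' @param mode `"relative"` or `"absolute"`.
#' @return An [abundance_table()].
#' @export
read_abundance <- function(path, mode = c("relative", "absolute")) {
  abundance_table(read_table_tsv(path, "abundance table"), mode = match.arg(mode))
}

#' Read an environment table from TSV
#'
#' @param path file path; header row = parameter ids, first column = sample ids.
#' @return An [environment_table()].
#' @export
read_environment <- function(path) {
  environment_table(read_table_tsv(path, "environment table"))
}

#' Write an abundance or environment table to TSV
#'
#' Values are written tab-delimited with sample identifiers in the first
#' column, so that [read_abundance()] / [read_environment()] round-trip the
#' values exactly.
#'
#' @param x an `abundance_table` or `environment_table`.
#' @param path output file path.
#' @export
write_table_tsv <- function(x, path) {
  stopifnot(inherits(x, "abundance_table") || inherits(x, "environment_table"))
  df <- data.frame(sample = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
write_abundance <- function(x, path) {
  stopifnot(inherits(x, "abundance_table"))
  write_table_tsv(x, path)
}

#' @rdname write_table_tsv
#' @export
write_environment <- function(x, path) {
  stopifnot(inherits(x, "environment_table"))
  write_table_tsv(x, path)
}

#' Import a samples x variables matrix from an R serialized data file
#'
#' Convenience import path for benchmark matrices distributed as `.Rdata` /
#' `.RData` files containing a single matrix or data frame (samples in rows).
#'
#' @param path path to the serialized file.
#' @param type `"abundance"` or `"environment"`.
#' @param mode abundance mode, used when `type = "abundance"`.
#' @return An [abundance_table()] or [environment_table()].
#' @export
import_rdata_table <- function(path, type = c("abundance", "environment"),
                               mode = c("relative", "absolute")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  env <- new.env(parent = emptyenv())
  nm <- load(path, envir = env)
  if (length(nm) < 1) stop("no object found in ", path)
  m <- as.matrix(get(nm[1], envir = env))
  storage.mode(m) <- "numeric"
  if (type == "abundance") abundance_table(m, mode = match.arg(mode))
  else environment_table(m)
}

#' Align an abundance table and an environment table by sample id
#'
#' Both tables are restricted to the intersection of their sample identifiers,
#' ordered as in the abundance table. Dropped samples are reported via a
#' message. Alignment is idempotent.
#'
#' @param a an `abundance_table`.
#' @param e an `environment_table`.
#' @return A list with elements `abundance` and `environment`.
#' @export
align_tables <- function(a, e) {
  stopifnot(inherits(a, "abundance_table"), inherits(e, "environment_table"))
  common <- intersect(rownames(a$values), rownames(e$values))
  if (length(common) == 0) {
    stop("abundance and environment tables share no sample ids")
  }
  dropped_a <- setdiff(rownames(a$values), common)
  dropped_e <- setdiff(rownames(e$values), common)
  if (length(dropped_a) + length(dropped_e) > 0) {
    message(sprintf("align_tables: dropped %d abundance and %d environment samples",
                    length(dropped_a), length(dropped_e)))
  }
  ord <- rownames(a$values)[rownames(a$values) %in% common]
  a2 <- a
  a2$values <- a$values[ord, , drop = FALSE]
  e2 <- e
  e2$values <- e$values[ord, , drop = FALSE]
  list(abundance = a2, environment = e2)
}
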