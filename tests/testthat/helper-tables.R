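# small fixture builders shared across tests

make_abund <- function(values, mode = "absolute", samples = NULL, taxa = NULL) {
  m <- as.matrix(values)
  rownames(m) <- samples %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- taxa %||% paste0("t", seq_len(ncol(m)))
  abundance_table(m, mode = mode)
}

make_env <- function(values, samples = NULL, params = NULL) {
  m <- as.matrix(values)
  rownames(m) <- samples %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- params %||% paste0("p", seq_len(ncol(m)))
  environment_table(m)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# writes a matrix as the package's TSV table layout
write_fixture_tsv <- function(m, path) {
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
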