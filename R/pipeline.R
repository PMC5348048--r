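#' Full interaction-inference chain
#'
#' Runs preprocessing ([preprocess()]), slope-field estimation
#' ([estimate_p()]), interaction-field estimation ([estimate_beta()]) and
#' global summarization ([summarize_interactions()]) on raw input tables.
#'
#' @param a raw `abundance_table`.
#' @param e raw `environment_table`.
#' @param variant `"reduced"` or `"full"` (both estimation stages).
#' @param majority,ratio_threshold,weights,min_values summarization settings.
#' @param scale,prune,seed preprocessing settings.
#' @param slope_field optional precomputed `local_slope_field` (e.g. from
#'   [truth_slope_field()]) used instead of estimating one; its dimensions
#'   must match the preprocessed tables.
#' @return A list with `global` (the `global_interaction_matrix`), `field`,
#'   `p`, `report` (preprocessing report) and the processed `tables`.
#' @export
infer_interactions <- function(a, e, variant = "reduced", majority = 0.8,
                               ratio_threshold = 2, weights = NULL,
                               min_values = 5L, scale = TRUE, prune = TRUE,
                               seed = 1L, slope_field = NULL) {
  pre <- preprocess(a, e, seed = seed, scale = scale, prune = prune)
  p <- if (is.null(slope_field)) {
    estimate_p(pre$abundance, pre$environment, variant = variant)
  } else {
    slope_field
  }
  field <- estimate_beta(p, pre$abundance, pre$environment, variant = variant)
  global <- summarize_interactions(field, majority = majority,
                                   ratio_threshold = ratio_threshold,
                                   weights = weights, min_values = min_values)
  list(global = global, field = field, p = p, report = pre$report,
       tables = pre[c("abundance", "environment")])
}

write_manifest <- function(path, config) {
  manifest <- c(list(package = "crossbeta",
                     version = as.character(utils::packageVersion("crossbeta")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

ensure_outdir <- function(out) {
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  out
}

read_config_tables <- function(config) {
  for (f in c("abundance", "environment")) {
    if (is.null(config[[f]])) stop(sprintf("config field '%s' is required", f))
    if (!file.exists(config[[f]])) stop(sprintf("input file not found: %s", config[[f]]))
  }
  list(abundance = read_abundance(config$abundance,
                                  mode = config$mode %||% "relative"),
       environment = read_environment(config$environment))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run the inference pipeline from a configuration list
#'
#' Backs the `infer` subcommand of the command-line interface. Reads the
#' abundance and environment TSV files, runs [infer_interactions()] and
#' writes `p_field.tsv`, `beta_field.tsv`, `global_beta.tsv`,
#' `preprocess_report.json` and `manifest.json` to the output directory.
#' Outputs are written only after the whole chain succeeds.
#'
#' @param config named list: `abundance`, `environment` (paths), `mode`,
#'   `variant`, `majority`, `ratio`, `min_values`, `seed`, `out`.
#' @return Invisibly, the result of [infer_interactions()].
#' @export
run_infer <- function(config) {
  tabs <- read_config_tables(config)
  seed <- as.integer(config$seed %||% 1L)
  res <- infer_interactions(tabs$abundance, tabs$environment,
                            variant = config$variant %||% "reduced",
                            majority = as.numeric(config$majority %||% 0.8),
                            ratio_threshold = as.numeric(config$ratio %||% 2),
                            min_values = as.integer(config$min_values %||% 5L),
                            seed = seed)
  out <- ensure_outdir(config$out %||% ".")
  write_field_tsv(res$p, file.path(out, "p_field.tsv"))
  write_field_tsv(res$field, file.path(out, "beta_field.tsv"))
  write_global_matrix(res$global, file.path(out, "global_beta.tsv"))
  rep <- res$report
  jsonlite::write_json(
    list(dropped_taxa = rep$dropped_taxa,
         removed_collinear = rep$removed_collinear,
         ranks = rep$ranks,
         dimension_status = rep$dimension_status),
    file.path(out, "preprocess_report.json"), auto_unbox = TRUE, pretty = TRUE)
  write_manifest(file.path(out, "manifest.json"),
                 list(command = "infer", seed = seed,
                      variant = config$variant %||% "reduced",
                      majority = as.numeric(config$majority %||% 0.8),
                      ratio = as.numeric(config$ratio %||% 2)))
  invisible(res)
}

#' Run a perturbation robustness assay from a configuration list
#'
#' Backs the `robustness` subcommand: runs [robustness_run()] and writes
#' `robustness_report.tsv` (per-pair statistics), `robustness_report.json`
#' and `manifest.json`.
#'
#' @param config named list: inputs as in [run_infer()] plus `perturb`
#'   (target), `error_level`, `fraction`, `iters`.
#' @return Invisibly, the `robustness_report`.
#' @export
run_robustness <- function(config) {
  tabs <- read_config_tables(config)
  seed <- as.integer(config$seed %||% 1L)
  spec <- perturbation_spec(target = config$perturb %||% "environment",
                            error_level = as.numeric(config$error_level %||% 0.05),
                            subsample_fraction = as.numeric(config$fraction %||% 0.9),
                            n_iter = as.integer(config$iters %||% 1000L),
                            seed = seed)
  rep <- robustness_run(tabs$abundance, tabs$environment, spec,
                        variant = config$variant %||% "reduced",
                        majority = as.numeric(config$majority %||% 0.8),
                        ratio_threshold = as.numeric(config$ratio %||% 2))
  out <- ensure_outdir(config$out %||% ".")
  utils::write.table(rep$pairs, file.path(out, "robustness_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(rep$pairs, file.path(out, "robustness_report.json"),
                       dataframe = "rows", na = "null", digits = NA)
  write_manifest(file.path(out, "manifest.json"),
                 list(command = "robustness", seed = seed,
                      target = spec$target, error_level = spec$error_level,
                      fraction = spec$subsample_fraction, n_iter = spec$n_iter))
  invisible(rep)
}

#' Generate a synthetic dataset from a configuration list
#'
#' Backs the `simulate` subcommand. Generators: `"predator_prey"`,
#' `"mutualism"`, `"analytic"`, `"squared_pair"`, `"study"`. Writes
#' `abundance.tsv`, `environment.tsv`, the ground truth (`true_beta_sign.tsv`
#' and/or `true_p.tsv`) and `manifest.json`.
#'
#' @param config named list: `generator`, `seed`, `noise`, `out`.
#' @return Invisibly, the `synthetic_truth`.
#' @export
run_simulate <- function(config) {
  seed <- as.integer(config$seed %||% 1L)
  noise <- as.numeric(config$noise %||% 0)
  gen <- config$generator %||% "predator_prey"
  truth <- switch(gen,
    predator_prey = simulate_predator_prey(seed = seed, noise = noise),
    mutualism = simulate_mutualism(seed = seed, noise = noise),
    analytic = make_analytic_dataset(coef = matrix(c(2, 0, 1, 3), 2, 2),
                                     intercept = c(5, 5), n_samples = 40,
                                     noise = noise, seed = seed),
    squared_pair = make_squared_pair_dataset(seed = seed),
    study = emulate_study(seed = seed),
    stop(sprintf("unknown generator '%s'", gen)))
  out <- ensure_outdir(config$out %||% ".")
  write_abundance(truth$abundance, file.path(out, "abundance.tsv"))
  write_environment(truth$environment, file.path(out, "environment.tsv"))
  if (!is.null(truth$true_beta_sign)) {
    utils::write.table(
      data.frame(taxon = rownames(truth$true_beta_sign), truth$true_beta_sign,
                 check.names = FALSE),
      file.path(out, "true_beta_sign.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  if (!is.null(truth$true_p)) {
    write_field_tsv(structure(list(p = truth$true_p, model_variant = "truth"),
                              class = "local_slope_field"),
                    file.path(out, "true_p.tsv"))
  }
  write_manifest(file.path(out, "manifest.json"),
                 list(command = "simulate", generator = gen, seed = seed,
                      noise = noise))
  invisible(truth)
}

#' Run the co-occurrence comparison from a configuration list
#'
#' Backs the `compare` subcommand: computes the Spearman co-occurrence matrix
#' and, when a `global_beta.tsv` produced by [run_infer()] is given via
#' `config$global`, exports both thresholded networks. Writes `spearman.tsv`,
#' `rho_network.graphml`/`.tsv`, and (with a global matrix)
#' `beta_network.graphml`/`.tsv`.
#'
#' @param config named list: `abundance`, `mode`, optional `global` (path to
#'   a `global_beta.tsv`), `beta_threshold` (0.1), `rho_threshold` (0.4),
#'   `out`.
#' @return Invisibly, a list with the correlation matrix and edge lists.
#' @export
run_compare <- function(config) {
  if (is.null(config$abundance) || !file.exists(config$abundance)) {
    stop("config field 'abundance' must name an existing file")
  }
  a <- read_abundance(config$abundance, mode = config$mode %||% "relative")
  out <- ensure_outdir(config$out %||% ".")
  rho <- spearman_matrix(a)
  write_matrix_tsv(rho, file.path(out, "spearman.tsv"))
  rho_edges <- export_network(rho, threshold = as.numeric(config$rho_threshold %||% 0.4))
  write_network_tsv(rho_edges, file.path(out, "rho_network.tsv"))
  write_network_graphml(rho_edges, file.path(out, "rho_network.graphml"),
                        vertices = colnames(a$values))
  beta_edges <- NULL
  if (!is.null(config$global)) {
    gdf <- utils::read.delim(config$global, stringsAsFactors = FALSE)
    taxa <- unique(gdf$taxon_i)
    gb <- matrix(NA_real_, length(taxa), length(taxa), dimnames = list(taxa, taxa))
    st <- matrix("no_qualifying_parameter", length(taxa), length(taxa),
                 dimnames = list(taxa, taxa))
    gb[cbind(gdf$taxon_i, gdf$taxon_j)] <- gdf$beta
    st[cbind(gdf$taxon_i, gdf$taxon_j)] <- gdf$status
    gm <- structure(list(beta = gb, status = st), class = "global_interaction_matrix")
    beta_edges <- export_network(gm, threshold = as.numeric(config$beta_threshold %||% 0.1))
    write_network_tsv(beta_edges, file.path(out, "beta_network.tsv"))
    write_network_graphml(beta_edges, file.path(out, "beta_network.graphml"),
                          vertices = taxa)
  }
  write_manifest(file.path(out, "manifest.json"),
                 list(command = "compare",
                      rho_threshold = as.numeric(config$rho_threshold %||% 0.4),
                      beta_threshold = as.numeric(config$beta_threshold %||% 0.1)))
  invisible(list(rho = rho, rho_edges = rho_edges, beta_edges = beta_edges))
}
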