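#' Run the full pipeline from files to artifacts
#'
#' Reads expression and metadata ([read_inputs()]), fits [phenoscore()],
#' and writes every artifact to the output directory: per-cell scores and
#' predictions (`scores.tsv`), the feature ranking (`feature_ranking.tsv`),
#' the collapsed attribution matrix (`attribution.csv`), the latent
#' embedding (`embedding.csv`), holdout metrics (`metrics.json`), the
#' per-cluster summary (`cluster_summary.tsv`, when a cluster column is
#' configured), and a manifest (`manifest.json`) with the package version,
#' seed, and full configuration, sufficient to reproduce the run.
#'
#' @param config Named list (or path to a JSON file) with entries
#'   `expression`, `metadata`, `out_dir`, `outcome`, `sample_col`, and
#'   optionally `cluster_col`, `covariates`, `interactions`,
#'   `harmonize_vars`, `normalize`, `graph_dims`, `k`, `steps`,
#'   `reduction`, `n_init`, `n_keep`, `nmf_k`, `collapse`,
#'   `score_columns`, `seed`, and a `model` sublist passed to
#'   [model_config()].
#' @return The output directory, invisibly; the fitted `phenoscore` object
#'   is attached as attribute `"fit"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  for (req in c("expression", "metadata", "out_dir", "outcome", "sample_col")) {
    if (is.null(config[[req]])) stop("config entry '", req, "' is required")
  }
  seed <- as.integer(config$seed %||% 1L)
  model_args <- config$model %||% list()
  model_args$seed <- model_args$seed %||% seed
  model <- do.call(model_config, model_args)

  inputs <- read_inputs(config$expression, config$metadata,
                        cells_as = config$cells_as %||% "rows")
  fit <- phenoscore(inputs$expression, inputs$meta,
                    outcome = config$outcome,
                    sample_col = config$sample_col,
                    cluster_col = config$cluster_col,
                    covariates = config$covariates,
                    interactions = config$interactions,
                    harmonize_vars = config$harmonize_vars,
                    normalize = config$normalize %||% "none",
                    graph_dims = config$graph_dims %||% 30L,
                    k = config$k %||% 30L,
                    steps = config$steps %||% 3L,
                    reduction = config$reduction %||% "pca",
                    n_init = config$n_init %||% 100L,
                    n_keep = config$n_keep %||% 20L,
                    nmf_k = config$nmf_k,
                    model = model,
                    collapse = config$collapse %||% "auto",
                    score_columns = config$score_columns %||% "all",
                    seed = seed)

  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  scores <- fit$scores
  scores$cluster <- if (!is.null(config$cluster_col))
    fit$meta[[config$cluster_col]] else NA
  prob <- fit$fit$oof_prob
  colnames(prob) <- paste0("prob_", colnames(prob))
  write.table(cbind(scores, prob), file.path(out, "scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fit$ranking, file.path(out, "feature_ranking.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(cell_id = rownames(fit$attribution),
                              fit$attribution, check.names = FALSE),
                   file.path(out, "attribution.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell_id = rownames(fit$embedding$scores),
                              fit$embedding$scores, check.names = FALSE),
                   file.path(out, "embedding.csv"), row.names = FALSE)
  jsonlite::write_json(fit$fit$metrics, file.path(out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(fit$cluster_summary)) {
    write.table(fit$cluster_summary$summary,
                file.path(out, "cluster_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "phenoscore",
    version = as.character(utils::packageVersion("phenoscore")),
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    n_cells = nrow(inputs$expression),
    n_features = ncol(inputs$expression),
    classes = fit$fit$class_names,
    embedding = list(method = fit$embedding$method, d = fit$embedding$d,
                     harmonized = fit$embedding$harmonized,
                     removed = fit$embedding$removed)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(invisible(out), fit = fit)
}
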