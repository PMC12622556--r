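#' Fit an interpretable per-cell phenotype score model
#'
#' The front door of the package: runs the full pipeline on a cells x
#' features matrix and per-cell metadata. Cells are embedded in a kNN graph
#' built on the top principal components of the (optionally log1p) scaled
#' expression matrix; an s-step random walk yields the samples x
#' neighborhoods abundance matrix, which is reduced (PCA by default, NMF
#' optionally), adjusted for technical covariates, and combined with
#' encoded covariates and latent-by-covariate interaction products into the
#' classifier design. A tree ensemble is fit under repeated nested
#' cross-validation with randomized hyperparameter search; exact TreeSHAP
#' attributions of the out-of-fold probability predictions are averaged
#' over repeats, collapsed to one value per cell and feature, and summed
#' into the per-cell Interpretable Score.
#'
#' @param expression Cells x features numeric matrix (rownames = cell ids).
#' @param meta Per-cell metadata with at least the outcome and sample
#'   columns; rows aligned to `expression`.
#' @param outcome Metadata column holding the sample-level phenotype.
#' @param sample_col Metadata column holding the sample (subject) id.
#' @param cluster_col Optional metadata column with cluster labels, used for
#'   the per-cluster score summary and plots.
#' @param covariates Metadata columns to include as encoded covariates.
#' @param interactions Covariate names interacted with every latent
#'   dimension.
#' @param harmonize_vars Metadata columns (e.g. batch) whose structure is
#'   removed from the latent embedding; `NULL` disables adjustment.
#' @param normalize `"none"` (default, for already-normalized input) or
#'   `"log1p"` for raw counts.
#' @param graph_dims Principal components of the expression matrix used for
#'   the kNN graph.
#' @param k Neighbours per cell for the graph.
#' @param steps Random-walk steps for the NAM.
#' @param reduction `"pca"` or `"nmf"`.
#' @param n_init,n_keep PCA components initialized/kept (see
#'   [reduce_pca()]).
#' @param nmf_k NMF rank; `NULL` selects it by silhouette
#'   ([select_nmf_rank()]).
#' @param model A [model_config()].
#' @param collapse,score_columns Passed to [collapse_multiclass()] and
#'   [interpretable_score()].
#' @param keep_nam Keep the NAM matrices in the returned object.
#' @param seed Seed for the expression PCA and reduction stages (the model
#'   seed lives in `model`).
#' @return An object of class `phenoscore`: `scores` (per-cell data frame),
#'   `ranking` (feature importance), `attribution` (collapsed cells x
#'   features matrix), `base` (per-class base values averaged over
#'   repeats), `fit` (the `pheno_fit`), `embedding`, `cluster_summary`
#'   (when `cluster_col` is given), `meta`, `call`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_subjects_per_group = 4,
#'                                    cells_per_cluster = 15,
#'                                    clusters = c("A", "B"),
#'                                    expanded = c(A = 3), n_features = 10))
#' fit <- phenoscore(sim$expression, sim$meta, outcome = "condition",
#'                   sample_col = "subject_id", cluster_col = "cluster",
#'                   k = 10, model = model_config(n_outer_folds = 2,
#'                     n_repeats = 1, search_budget = 2,
#'                     holdout_fraction = 0))
#' fit
phenoscore <- function(expression, meta, outcome, sample_col,
                       cluster_col = NULL, covariates = NULL,
                       interactions = NULL, harmonize_vars = NULL,
                       normalize = c("none", "log1p"),
                       graph_dims = 30L, k = 30L, steps = 3L,
                       reduction = c("pca", "nmf"),
                       n_init = 100L, n_keep = 20L, nmf_k = NULL,
                       model = model_config(),
                       collapse = c("auto", "literal", "positive"),
                       score_columns = c("all", "latent_only"),
                       keep_nam = FALSE, seed = 1L) {
  normalize <- match.arg(normalize)
  reduction <- match.arg(reduction)
  collapse <- match.arg(collapse)
  score_columns <- match.arg(score_columns)
  cl <- match.call()

  expression <- as.matrix(expression)
  meta <- as.data.frame(meta)
  if (nrow(meta) != nrow(expression)) stop("meta must align with expression rows")
  for (col in c(outcome, sample_col, cluster_col, covariates, harmonize_vars)) {
    if (!col %in% names(meta)) stop("metadata column not found: ", col)
  }
  if (is.null(rownames(expression))) {
    rownames(expression) <- meta$cell_id %||% sprintf("cell%06d", seq_len(nrow(meta)))
  }

  # representation for the graph: top PCs of the scaled expression
  x <- expression
  if (normalize == "log1p") x <- log1p(x)
  x <- scale(x)
  x[, !is.finite(colSums(x))] <- 0
  d_rep <- min(graph_dims, ncol(x), nrow(x) - 1L)
  set.seed(seed)
  sv <- svd(x, nu = 0, nv = d_rep)
  rep_mat <- x %*% sv$v
  rownames(rep_mat) <- rownames(expression)

  graph <- build_knn_graph(rep_mat, k = k,
                           feature_space = sprintf("expression PC1-%d", d_rep))
  nam <- build_nam(graph, meta[[sample_col]], s = steps)

  emb <- if (reduction == "pca") {
    reduce_pca(nam, n_init = n_init, n_keep = n_keep)
  } else {
    kk <- nmf_k %||% select_nmf_rank(nam, seed = seed)
    reduce_nmf(nam, k = kk, seed = seed)
  }
  if (!is.null(harmonize_vars)) {
    emb <- harmonize(emb, meta[, harmonize_vars, drop = FALSE],
                     protect = meta[[outcome]])
  }

  design <- build_design(emb,
                         covariates = if (!is.null(covariates))
                           meta[, covariates, drop = FALSE] else NULL,
                         interaction_vars = interactions %||% character(0),
                         y = meta[[outcome]],
                         sample_ids = meta[[sample_col]],
                         cell_ids = rownames(expression))
  fit <- nested_cv_fit(design, model)

  sh <- cv_tree_shap(fit)
  sbar <- average_over_repeats(sh$tensors)
  # per-cell base: each cell is explained by its own out-of-training model,
  # averaged over repeats like the attributions themselves
  base_per_cell <- Reduce(`+`, sh$base) / length(sh$base)
  base <- colMeans(base_per_cell)
  collapsed <- collapse_multiclass(sbar, fit$predicted_class, mode = collapse)
  sv_out <- interpretable_score(collapsed, fit$predicted_class,
                                roles = design$roles, columns = score_columns)

  cluster_summary <- NULL
  if (!is.null(cluster_col)) {
    cluster_summary <- cluster_score_summary(sv_out, meta[[cluster_col]])
  }

  structure(list(scores = sv_out$scores, ranking = sv_out$ranking,
                 attribution = collapsed, base = base,
                 base_per_cell = base_per_cell, fit = fit,
                 embedding = emb,
                 nam = if (keep_nam) nam else NULL,
                 cluster_summary = cluster_summary,
                 outcome = outcome, cluster_col = cluster_col,
                 meta = meta, seed = seed, call = cl),
            class = "phenoscore")
}

#' @exportS3Method base::print
print.phenoscore <- function(x, ...) {
  cat("phenoscore fit:", nrow(x$scores), "cells,",
      length(x$fit$class_names), "classes (",
      paste(x$fit$class_names, collapse = ", "), ")\n")
  for (cl in x$fit$class_names) {
    cat(sprintf("  %s: AUROC %.3f, AUPRC %.3f\n", cl,
                x$fit$metrics[[cl]]["auroc"], x$fit$metrics[[cl]]["auprc"]))
  }
  cat("top features by mean |SHAP|:\n")
  print(utils::head(x$ranking, 5), digits = 3)
  invisible(x)
}

#' @exportS3Method base::summary
summary.phenoscore <- function(object, ...) {
  print(object)
  cat("\nInterpretable Score: ",
      sprintf("min %.3f, median %.3f, max %.3f\n",
              min(object$scores$score), stats::median(object$scores$score),
              max(object$scores$score)))
  if (!is.null(object$cluster_summary)) {
    cat("per-cluster scores (top cluster:",
        object$cluster_summary$top_cluster, "):\n")
    print(object$cluster_summary$summary, digits = 3)
  }
  invisible(object)
}

#' Boxplot of the Interpretable Score by cluster
#'
#' @param x A `phenoscore` fit (needs `cluster_col`).
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.phenoscore <- function(x, ...) {
  if (is.null(x$cluster_col)) stop("fit has no cluster column to plot by")
  boxplot(x$scores$score ~ x$meta[[x$cluster_col]],
          xlab = x$cluster_col, ylab = "Interpretable Score", ...)
  abline(h = 0, lty = 2)
  invisible(x)
}

#' @export
predict.phenoscore <- function(object, newdata, ...) {
  predict(object$fit, newdata, ...)
}
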