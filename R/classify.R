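#' Assemble the classifier design matrix
#'
#' Binds the latent abundance dimensions to encoded covariates and
#' latent-by-covariate interaction products. Categorical covariates are
#' label-encoded (integer codes in level order); two-level covariates enter
#' interactions as 0/1 and continuous ones are z-scored before the product,
#' so an interaction column is the elementwise product of its latent column
#' and the encoded variable. The per-cell target is the clinical phenotype
#' of the cell's sample, broadcast to cells.
#'
#' @param embedding A `latent_embedding` (or a plain cells x d matrix).
#' @param covariates Optional data frame of per-cell covariates.
#' @param interaction_vars Covariate names to interact with every latent
#'   dimension.
#' @param y Per-cell outcome labels (>= 2 classes).
#' @param sample_ids Per-cell sample ids (required for sample-grouped
#'   cross-validation splits).
#' @param cell_ids Optional cell ids (defaults to score row names).
#' @return An object of class `design_matrix`: `values` (cells x p), `roles`
#'   (per-column role: latent / covariate / interaction with its parents),
#'   `y` (factor), `class_names`, `sample_ids`, `cell_ids`.
#' @export
build_design <- function(embedding, covariates = NULL,
                         interaction_vars = character(0), y,
                         sample_ids = NULL, cell_ids = NULL) {
  scores <- if (inherits(embedding, "latent_embedding")) embedding$scores else as.matrix(embedding)
  n <- nrow(scores)
  if (is.null(colnames(scores))) colnames(scores) <- paste0("LD", seq_len(ncol(scores)))
  if (length(y) != n) stop("y must have one entry per cell")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariate table must align with cells")
  }
  if (length(interaction_vars) &&
      !all(interaction_vars %in% names(covariates))) {
    stop("interaction variables must be covariate columns: missing ",
         paste(setdiff(interaction_vars, names(covariates)), collapse = ", "))
  }

  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("the outcome must have at least 2 classes")
  if (!is.null(sample_ids)) {
    stopifnot(length(sample_ids) == n)
    tab <- table(unique(data.frame(s = sample_ids, y = y))$y)
    if (any(tab < 2)) {
      stop("every class needs at least 2 samples; got ",
           paste(names(tab), tab, sep = "=", collapse = ", "))
    }
  }

  label_encode <- function(v, nm) {
    if (is.numeric(v)) return(as.numeric(v))
    f <- as.factor(v)
    if (nlevels(f) > 20) {
      stop("covariate '", nm, "' has ", nlevels(f),
           " levels; this looks like an id column")
    }
    as.numeric(f) - 1
  }

  cols <- list()
  roles <- data.frame(name = colnames(scores), role = "latent",
                      latent = colnames(scores), variable = NA_character_)
  cols[[1]] <- scores

  enc <- list()
  if (!is.null(covariates) && ncol(covariates)) {
    keep <- character(0)
    for (nm in names(covariates)) {
      v <- label_encode(covariates[[nm]], nm)
      if (stats::var(v) == 0) {
        warning("dropping constant covariate '", nm, "'")
        next
      }
      enc[[nm]] <- v
      keep <- c(keep, nm)
    }
    if (length(keep)) {
      cv <- do.call(cbind, enc[keep])
      colnames(cv) <- keep
      cols[[length(cols) + 1]] <- cv
      roles <- rbind(roles, data.frame(name = keep, role = "covariate",
                                       latent = NA, variable = keep))
    }
  }

  for (v in intersect(interaction_vars, names(enc))) {
    ev <- enc[[v]]
    if (length(unique(ev)) > 2) ev <- as.numeric(scale(ev))
    inter <- scores * ev
    colnames(inter) <- paste0(colnames(scores), ":", v)
    cols[[length(cols) + 1]] <- inter
    roles <- rbind(roles, data.frame(name = colnames(inter),
                                     role = "interaction",
                                     latent = colnames(scores), variable = v))
  }

  values <- do.call(cbind, cols)
  rownames(values) <- cell_ids %||% rownames(scores)
  structure(list(values = values, roles = roles, y = y,
                 class_names = levels(y),
                 sample_ids = sample_ids,
                 cell_ids = rownames(values)),
            class = "design_matrix")
}

#' @exportS3Method base::print
print.design_matrix <- function(x, ...) {
  cat("design_matrix:", nrow(x$values), "cells x", ncol(x$values),
      "columns (", sum(x$roles$role == "latent"), "latent,",
      sum(x$roles$role == "covariate"), "covariate,",
      sum(x$roles$role == "interaction"), "interaction );",
      nlevels(x$y), "classes\n")
  invisible(x)
}

#' Configure the classification model
#'
#' @param family `"random_forest"` (probability forest via ranger, the
#'   default) or `"gradient_boosting"` (xgboost, binary outcomes only).
#' @param n_outer_folds,n_inner_folds Outer/inner stratified folds.
#' @param n_repeats Number of repeats of the whole nested procedure.
#' @param search_budget Randomized-search draws per outer fold.
#' @param holdout_fraction Fraction of samples per repeat held out from the
#'   outer folds; the best configuration is refit on the remaining samples
#'   and evaluated (AUROC/AUPRC per class) on this validation set. Set to 0
#'   to score on the out-of-fold predictions instead.
#' @param split_mode `"stratified_sample_grouped"` keeps all cells of a
#'   sample in one fold while stratifying folds by class (blocks leakage
#'   between a sample's cells); `"stratified_cell"` stratifies cells
#'   directly.
#' @param num_trees_default Trees used when a draw does not override it.
#' @param depth_range Candidate maximum tree depths for the randomized
#'   search. The default range starts at 2: with grouped (per-sample) data,
#'   shallow forests generalize across samples where deep ones memorize
#'   them, and the inner folds — which hold out whole samples — pick the
#'   depth that transfers. Deep trees also make exact SHAP expensive
#'   (cost grows with leaves x depth^2), so the default caps depth at 12.
#' @param seed Master seed; every split, draw, and forest fit derives its
#'   seed from it.
#' @return An object of class `model_config`.
#' @export
model_config <- function(family = c("random_forest", "gradient_boosting"),
                         n_outer_folds = 5L, n_inner_folds = 3L,
                         n_repeats = 3L, search_budget = 20L,
                         holdout_fraction = 0.2,
                         split_mode = c("stratified_sample_grouped",
                                        "stratified_cell"),
                         num_trees_default = 100L,
                         depth_range = c(2L, 12L),
                         seed = 1L) {
  family <- match.arg(family)
  split_mode <- match.arg(split_mode)
  stopifnot(n_outer_folds >= 2, n_inner_folds >= 2, n_repeats >= 1,
            search_budget >= 1, holdout_fraction >= 0, holdout_fraction < 1)
  structure(list(family = family, n_outer_folds = as.integer(n_outer_folds),
                 n_inner_folds = as.integer(n_inner_folds),
                 n_repeats = as.integer(n_repeats),
                 search_budget = as.integer(search_budget),
                 holdout_fraction = holdout_fraction,
                 split_mode = split_mode,
                 num_trees_default = as.integer(num_trees_default),
                 depth_range = as.integer(depth_range),
                 seed = as.integer(seed)),
            class = "model_config")
}

# stratified fold assignment of units (samples or cells) to nfolds;
# round-robin within shuffled classes so class proportions are preserved
stratified_folds <- function(classes, nfolds) {
  classes <- as.factor(classes)
  if (any(table(classes) < nfolds)) {
    stop("a class has fewer units (samples) than folds; ",
         "use fewer folds or more samples")
  }
  fold <- integer(length(classes))
  for (cl in levels(classes)) {
    idx <- sample(which(classes == cl))
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fold
}

draw_param_grid <- function(budget, p, num_trees_default, depth_range) {
  data.frame(
    num.trees = sample(c(num_trees_default, seq(100L, 500L, by = 50L)),
                       budget, replace = TRUE),
    max.depth = sample(seq(depth_range[1], depth_range[2]), budget,
                       replace = TRUE),
    min.node.size = sample(1:10, budget, replace = TRUE),
    mtry = pmax(1L, ifelse(stats::runif(budget) < 0.3,
                           floor(sqrt(p)),
                           round(stats::runif(budget, 0.3, 1) * p)))
  )
}

fit_forest <- function(X, y, params, seed, family) {
  if (family == "random_forest") {
    rf <- ranger::ranger(x = X, y = y, probability = TRUE,
                         num.trees = params$num.trees,
                         mtry = min(params$mtry, ncol(X)),
                         min.node.size = params$min.node.size,
                         max.depth = params$max.depth,
                         seed = seed, num.threads = 1L,
                         respect.unordered.factors = FALSE)
    structure(list(engine = "ranger", fit = rf, train = X, y = y,
                   classes = levels(y), params = params),
              class = "pheno_model")
  } else {
    if (!requireNamespace("xgboost", quietly = TRUE)) {
      stop("family 'gradient_boosting' needs the xgboost package")
    }
    if (nlevels(y) != 2) stop("gradient boosting supports binary outcomes only")
    dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y) - 1)
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = 0.1,
                    max_depth = max(2L, min(params$max.depth, 8L)),
                    nthread = 1L, seed = seed),
      data = dtrain, nrounds = max(20L, params$num.trees %/% 5L))
    structure(list(engine = "xgboost", fit = bst, train = X, y = y,
                   classes = levels(y), params = params),
              class = "pheno_model")
  }
}

#' Predict from a fitted tree-ensemble
#'
#' @param object A `pheno_model` as stored inside a [nested_cv_fit()]
#'   result.
#' @param newdata Matrix with the training columns.
#' @param type `"prob"` for class probabilities, `"class"` for the argmax
#'   class (ties go to the lower-indexed class).
#' @param ... Unused.
#' @export
predict.pheno_model <- function(object, newdata, type = c("prob", "class"),
                                ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  missing <- setdiff(colnames(object$train), colnames(newdata))
  if (length(missing)) {
    stop("newdata is missing model columns: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  newdata <- newdata[, colnames(object$train), drop = FALSE]
  if (object$engine == "ranger") {
    prob <- predict(object$fit, data = newdata,
                    num.threads = 1L)$predictions
  } else {
    p1 <- predict(object$fit, newdata)
    prob <- cbind(1 - p1, p1)
  }
  colnames(prob) <- object$classes
  if (type == "prob") return(prob)
  factor(object$classes[max.col(prob, ties.method = "first")],
         levels = object$classes)
}

#' Nested, repeated cross-validated tree-ensemble fit
#'
#' For each repeat: optionally holds out a stratified validation set of
#' samples, splits the remaining samples into stratified outer folds, and,
#' within each outer-training set, selects hyperparameters by randomized
#' search scored with mean inner-fold (macro one-vs-rest) AUROC. The best
#' configuration is refit on the outer-training set and predicts the outer
#' test fold, so every cell receives an out-of-fold probability; the overall
#' best configuration is refit on all development samples to predict and
#' score the holdout validation set. All randomness derives from the config
#' seed.
#'
#' @param design A [build_design()] result.
#' @param config A [model_config()].
#' @return An object of class `pheno_fit`: per-repeat models, chosen
#'   hyperparameters, per-cell out-of-fold probabilities (`oof_prob`, a list
#'   of cells x classes matrices), fold assignments (`fold_id`, 0 = holdout),
#'   holdout metrics, and the design.
#' @export
nested_cv_fit <- function(design, config = model_config()) {
  stopifnot(inherits(design, "design_matrix"), inherits(config, "model_config"))
  X <- design$values
  y <- design$y
  n <- nrow(X)
  classes <- design$class_names

  grouped <- config$split_mode == "stratified_sample_grouped"
  if (grouped && is.null(design$sample_ids)) {
    stop("sample-grouped splitting needs sample_ids in the design")
  }
  if (grouped) {
    sid <- as.character(design$sample_ids)
    stab <- unique(data.frame(s = sid, y = y, stringsAsFactors = FALSE))
    if (anyDuplicated(stab$s)) stop("a sample maps to more than one class")
    units <- stab$s
    unit_class <- factor(stab$y, levels = classes)
    unit_of_cell <- match(sid, units)
  } else {
    units <- as.character(seq_len(n))
    unit_class <- y
    unit_of_cell <- seq_len(n)
  }

  repeats <- vector("list", config$n_repeats)
  for (b in seq_len(config$n_repeats)) {
    set.seed(config$seed + 7919L * b)

    n_units <- length(units)
    holdout_units <- integer(0)
    if (config$holdout_fraction > 0) {
      for (cl in levels(unit_class)) {
        idx <- which(unit_class == cl)
        n_h <- max(1L, round(config$holdout_fraction * length(idx)))
        if (n_h >= length(idx)) {
          stop("holdout fraction leaves no development samples for class ", cl)
        }
        holdout_units <- c(holdout_units, sample(idx, n_h))
      }
    }
    dev_units <- setdiff(seq_len(n_units), holdout_units)
    dev_fold <- stratified_folds(unit_class[dev_units], config$n_outer_folds)

    fold_of_unit <- integer(n_units)            # 0 = holdout
    fold_of_unit[dev_units] <- dev_fold
    fold_id <- fold_of_unit[unit_of_cell]

    oof <- matrix(NA_real_, n, length(classes),
                  dimnames = list(design$cell_ids, classes))
    models <- vector("list", config$n_outer_folds)
    chosen <- vector("list", config$n_outer_folds)
    best_score <- -Inf; best_params <- NULL

    for (k in seq_len(config$n_outer_folds)) {
      tr_cells <- which(fold_id != k & fold_id != 0L)
      te_cells <- which(fold_id == k)
      if (length(unique(y[tr_cells])) < length(classes) ||
          length(unique(y[te_cells])) < length(classes)) {
        stop("an outer fold is missing a class; use fewer folds")
      }
      grid <- draw_param_grid(config$search_budget, ncol(X),
                              config$num_trees_default, config$depth_range)
      tr_units <- which(fold_of_unit != k & fold_of_unit != 0L)
      inner_fold_u <- stratified_folds(unit_class[tr_units],
                                       config$n_inner_folds)
      inner_fold <- integer(n)                  # 0 = not in outer-train
      inner_fold[unit_of_cell %in% tr_units] <-
        inner_fold_u[match(unit_of_cell[unit_of_cell %in% tr_units], tr_units)]

      scores <- numeric(nrow(grid))
      for (g in seq_len(nrow(grid))) {
        aucs <- numeric(config$n_inner_folds)
        for (j in seq_len(config$n_inner_folds)) {
          itr <- which(inner_fold != 0L & inner_fold != j)
          iva <- which(inner_fold == j)
          m <- fit_forest(X[itr, , drop = FALSE], droplevels(y[itr]),
                          grid[g, ], seed = config$seed + 131L * b + 17L * k +
                            7L * g + j, family = config$family)
          prob <- predict(m, X[iva, , drop = FALSE])
          aucs[j] <- auroc_macro(prob, factor(y[iva], levels = m$classes))
        }
        scores[g] <- mean(aucs)
      }
      gbest <- which.max(scores)
      chosen[[k]] <- cbind(grid[gbest, ], inner_auroc = scores[gbest])
      if (scores[gbest] > best_score) {
        best_score <- scores[gbest]; best_params <- grid[gbest, ]
      }
      m <- fit_forest(X[tr_cells, , drop = FALSE], y[tr_cells],
                      chosen[[k]][, 1:4], seed = config$seed + 131L * b + 17L * k,
                      family = config$family)
      models[[k]] <- list(model = m, train_cells = tr_cells,
                          test_cells = te_cells)
      oof[te_cells, ] <- predict(m, X[te_cells, , drop = FALSE])
    }

    holdout <- NULL
    dev_cells <- which(fold_id != 0L)
    final <- fit_forest(X[dev_cells, , drop = FALSE], y[dev_cells],
                        best_params, seed = config$seed + 131L * b,
                        family = config$family)
    if (length(holdout_units)) {
      ho_cells <- which(fold_id == 0L)
      prob <- predict(final, X[ho_cells, , drop = FALSE])
      oof[ho_cells, ] <- prob
      metrics <- lapply(classes, function(cl) {
        pos <- y[ho_cells] == cl
        c(auroc = auc_binary(prob[, cl], pos),
          auprc = auprc_binary(prob[, cl], pos))
      })
      holdout <- list(cells = ho_cells,
                      metrics = setNames(metrics, classes))
    }

    repeats[[b]] <- list(models = models, final = final,
                         chosen = do.call(rbind, chosen),
                         best_params = best_params,
                         fold_id = fold_id, oof_prob = oof,
                         holdout = holdout)
  }

  oof_mean <- Reduce(`+`, lapply(repeats, `[[`, "oof_prob")) /
    config$n_repeats
  if (is.null(repeats[[1]]$holdout)) {
    metrics <- lapply(classes, function(cl) {
      pos <- y == cl
      c(auroc = auc_binary(oof_mean[, cl], pos),
        auprc = auprc_binary(oof_mean[, cl], pos))
    })
    metrics <- setNames(metrics, classes)
  } else {
    metrics <- lapply(classes, function(cl) {
      ms <- vapply(repeats, function(r) r$holdout$metrics[[cl]], numeric(2))
      rowMeans(ms)
    })
    metrics <- setNames(metrics, classes)
  }

  structure(list(repeats = repeats, oof_prob = oof_mean,
                 predicted_class = factor(
                   classes[max.col(oof_mean, ties.method = "first")],
                   levels = classes),
                 metrics = metrics, design = design, config = config,
                 class_names = classes),
            class = "pheno_fit")
}

#' @exportS3Method base::print
print.pheno_fit <- function(x, ...) {
  cat("pheno_fit:", nrow(x$design$values), "cells,", length(x$class_names),
      "classes,", x$config$n_repeats, "repeat(s) of",
      x$config$n_outer_folds, "x", x$config$n_inner_folds, "nested CV (",
      x$config$family, ")\n")
  for (cl in x$class_names) {
    cat(sprintf("  %s: AUROC %.3f, AUPRC %.3f\n", cl,
                x$metrics[[cl]]["auroc"], x$metrics[[cl]]["auprc"]))
  }
  invisible(x)
}

#' @export
predict.pheno_fit <- function(object, newdata, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  probs <- lapply(object$repeats, function(r) predict(r$final, newdata))
  prob <- Reduce(`+`, probs) / length(probs)
  if (type == "prob") return(prob)
  factor(object$class_names[max.col(prob, ties.method = "first")],
         levels = object$class_names)
}
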