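# Flatten a fitted ranger probability forest into the array form consumed by
# the C++ TreeSHAP kernel. Node covers (training rows through each node) are
# recomputed by routing the model's stored training matrix down every tree:
# they define the conditional expectations of the path-dependent convention.
extract_forest <- function(model) {
  stopifnot(inherits(model, "pheno_model"))
  if (model$engine != "ranger") {
    stop("exact TreeSHAP is implemented for the random-forest family; ",
         "gradient boosting exposes attributions via xgboost's predcontrib")
  }
  rf <- model$fit
  ntree <- rf$num.trees
  C <- length(model$classes)
  lefts <- rights <- feats <- vector("list", ntree)
  ths <- vals <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    ti <- ranger::treeInfo(rf, t)
    pred_cols <- grep("^pred\\.", names(ti))
    if (length(pred_cols) != C) stop("unexpected treeInfo layout")
    v <- as.matrix(ti[, pred_cols, drop = FALSE])
    v[is.na(v)] <- 0
    # align leaf value columns to the class order of the model
    cls <- sub("^pred\\.", "", names(ti)[pred_cols])
    v <- v[, match(model$classes, cls), drop = FALSE]
    lefts[[t]] <- ifelse(is.na(ti$leftChild), -1L, ti$leftChild)
    rights[[t]] <- ifelse(is.na(ti$rightChild), -1L, ti$rightChild)
    feats[[t]] <- ifelse(is.na(ti$splitvarID), -1L, ti$splitvarID)
    ths[[t]] <- ifelse(is.na(ti$splitval), 0, ti$splitval)
    vals[[t]] <- v
  }
  nn <- vapply(lefts, length, integer(1))
  forest <- list(tree_offset = as.integer(cumsum(c(0L, nn))),
                 left = as.integer(unlist(lefts)),
                 right = as.integer(unlist(rights)),
                 feature = as.integer(unlist(feats)),
                 threshold = as.numeric(unlist(ths)),
                 values = do.call(rbind, vals),
                 n_class = C)
  forest$cover <- rcpp_node_cover(forest$tree_offset, forest$left,
                                  forest$right, forest$feature,
                                  forest$threshold, model$train)
  forest
}

#' Exact TreeSHAP attributions for a fitted tree ensemble
#'
#' Computes, for every row, the exact Shapley value of each feature under
#' the path-dependent conditional-expectation convention (node expectations
#' weighted by the number of training rows through each child), on the
#' probability output of the forest. Attributions satisfy local accuracy:
#' for each row and class, `base + sum(phi) = predicted probability`.
#'
#' Gradient-boosting models delegate to xgboost's built-in TreeSHAP; those
#' attributions are exact as well but live on the margin (log-odds) scale,
#' flagged by `scale = "margin"` in the result.
#'
#' @param model A `pheno_model` (as stored in a [nested_cv_fit()] result,
#'   e.g. `fit$repeats[[1]]$models[[1]]$model`).
#' @param rows Matrix of rows to explain, with the training columns.
#' @return List with `values` (rows x features x classes array) and `base`
#'   (per-class base value, the cover-weighted mean leaf value).
#' @export
tree_shap <- function(model, rows) {
  stopifnot(inherits(model, "pheno_model"))
  rows <- as.matrix(rows)
  missing <- setdiff(colnames(model$train), colnames(rows))
  if (length(missing)) {
    stop("rows are missing model columns: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  rows <- rows[, colnames(model$train), drop = FALSE]
  if (model$engine == "xgboost") {
    # boosting attributions come from xgboost's own TreeSHAP and live on
    # the margin (log-odds) scale, not the probability scale
    contrib <- predict(model$fit, rows, predcontrib = TRUE)
    p <- ncol(rows)
    phi <- array(NA_real_, c(nrow(rows), p, 2),
                 dimnames = list(rownames(rows), colnames(rows),
                                 model$classes))
    phi[, , 2] <- contrib[, seq_len(p), drop = FALSE]
    phi[, , 1] <- -phi[, , 2]
    base <- c(-contrib[1, p + 1], contrib[1, p + 1])
    names(base) <- model$classes
    return(list(values = phi, base = base, scale = "margin"))
  }
  forest <- extract_forest(model)
  out <- rcpp_forest_shap(forest$tree_offset, forest$left, forest$right,
                          forest$feature, forest$threshold, forest$values,
                          forest$cover, rows, forest$n_class)
  dimnames(out$phi) <- list(rownames(rows), colnames(rows), model$classes)
  names(out$base) <- model$classes
  list(values = out$phi, base = out$base)
}

#' Per-repeat out-of-fold attributions for a nested CV fit
#'
#' For each repeat, explains every cell with the model for which that cell
#' was out of training: outer-test cells with their fold's refit model and
#' holdout cells with the repeat's final development model. Returns one
#' cells x features x classes array per repeat plus the per-repeat,
#' per-fold base values broadcast per cell.
#'
#' @param fit A [nested_cv_fit()] result (random-forest family).
#' @return List with `tensors` (list of per-repeat arrays) and `base`
#'   (list of per-repeat cells x classes base-value matrices).
#' @export
cv_tree_shap <- function(fit) {
  stopifnot(inherits(fit, "pheno_fit"))
  X <- fit$design$values
  classes <- fit$class_names
  tensors <- vector("list", length(fit$repeats))
  bases <- vector("list", length(fit$repeats))
  for (b in seq_along(fit$repeats)) {
    rep <- fit$repeats[[b]]
    arr <- array(NA_real_, c(nrow(X), ncol(X), length(classes)),
                 dimnames = list(fit$design$cell_ids, colnames(X), classes))
    bmat <- matrix(NA_real_, nrow(X), length(classes),
                   dimnames = list(fit$design$cell_ids, classes))
    for (mk in rep$models) {
      sh <- tree_shap(mk$model, X[mk$test_cells, , drop = FALSE])
      arr[mk$test_cells, , ] <- sh$values
      bmat[mk$test_cells, ] <- matrix(sh$base, length(mk$test_cells),
                                      length(classes), byrow = TRUE)
    }
    if (!is.null(rep$holdout)) {
      ho <- rep$holdout$cells
      sh <- tree_shap(rep$final, X[ho, , drop = FALSE])
      arr[ho, , ] <- sh$values
      bmat[ho, ] <- matrix(sh$base, length(ho), length(classes), byrow = TRUE)
    }
    tensors[[b]] <- arr
    bases[[b]] <- bmat
  }
  list(tensors = tensors, base = bases)
}

#' Average attributions over cross-validation repeats
#'
#' Elementwise mean over the per-repeat attribution arrays; the result keeps
#' the original cells x features x classes dimensions. Cells absent
#' (all-NA) from some repeats are averaged over the repeats where they are
#' present; a cell present in no repeat is an error.
#'
#' @param tensors List of cells x features x classes arrays (aligned cell
#'   order), or the result of [cv_tree_shap()].
#' @return A cells x features x classes array.
#' @export
average_over_repeats <- function(tensors) {
  if (is.list(tensors) && !is.null(tensors$tensors)) tensors <- tensors$tensors
  stopifnot(length(tensors) >= 1)
  d <- dim(tensors[[1]])
  for (t in tensors) if (!identical(dim(t), d)) stop("misaligned repeat arrays")
  present <- lapply(tensors, function(t) !is.na(t[, 1, 1]))
  n_present <- Reduce(`+`, present)
  if (any(n_present == 0)) {
    stop(sum(n_present == 0), " cell(s) have attributions in no repeat")
  }
  acc <- array(0, d)
  for (t in tensors) {
    t[is.na(t)] <- 0
    acc <- acc + t
  }
  out <- sweep(acc, 1, n_present, "/")
  dimnames(out) <- dimnames(tensors[[1]])
  out
}

#' Collapse multiclass attributions to one value per cell and feature
#'
#' Multiclass tasks keep, for each cell, the attribution slice of the cell's
#' predicted class. Binary tasks default to the positive-class (second
#' level) slice for every cell, which keeps score signs comparable across
#' cells; `mode = "literal"` applies the predicted-class rule even for
#' binary outcomes.
#'
#' @param sbar Cells x features x classes array (e.g. from
#'   [average_over_repeats()]).
#' @param predicted_class Per-cell predicted class (factor or character in
#'   the array's class dimnames).
#' @param mode `"auto"` (positive slice when binary, literal otherwise),
#'   `"literal"`, or `"positive"`.
#' @return Cells x features matrix.
#' @export
collapse_multiclass <- function(sbar, predicted_class,
                                mode = c("auto", "literal", "positive")) {
  mode <- match.arg(mode)
  classes <- dimnames(sbar)[[3]]
  C <- dim(sbar)[3]
  if (mode == "auto") mode <- if (C == 2) "positive" else "literal"
  if (mode == "positive") {
    return(sbar[, , C, drop = TRUE])
  }
  pc <- as.character(predicted_class)
  if (length(pc) != dim(sbar)[1] || anyNA(pc)) {
    stop("need one predicted class per cell")
  }
  if (!all(pc %in% classes)) stop("predicted class outside the model classes")
  out <- matrix(NA_real_, dim(sbar)[1], dim(sbar)[2],
                dimnames = dimnames(sbar)[1:2])
  ci <- match(pc, classes)
  for (c in seq_len(C)) {
    rows <- which(ci == c)
    if (length(rows)) out[rows, ] <- sbar[rows, , c]
  }
  out
}

#' Interpretable Score: per-cell sum of Shapley attributions
#'
#' Sums the collapsed attribution matrix across feature columns (all columns
#' by default — latent, covariate, and interaction — or latent columns
#' only) to obtain each cell's contribution toward the predicted phenotype,
#' and ranks features by their mean absolute attribution.
#'
#' @param collapsed Cells x features matrix from [collapse_multiclass()].
#' @param predicted_class Optional per-cell predicted class carried through
#'   to the output.
#' @param roles Optional `design_matrix` roles table; required for
#'   `columns = "latent_only"`.
#' @param columns `"all"` or `"latent_only"`.
#' @return An object of class `score_vector`: data frame `scores`
#'   (`cell_id`, `score`, `predicted_class`) and data frame `ranking`
#'   (`feature`, `role`, `mean_abs_shap`, sorted decreasing).
#' @export
interpretable_score <- function(collapsed, predicted_class = NULL,
                                roles = NULL,
                                columns = c("all", "latent_only")) {
  columns <- match.arg(columns)
  if (!all(is.finite(collapsed))) stop("non-finite attribution values")
  use <- colnames(collapsed)
  if (columns == "latent_only") {
    if (is.null(roles)) stop("latent_only scoring needs the design roles")
    use <- roles$name[roles$role == "latent"]
  }
  psi <- rowSums(collapsed[, use, drop = FALSE])
  ranking <- data.frame(feature = colnames(collapsed),
                        role = if (!is.null(roles)) {
                          roles$role[match(colnames(collapsed), roles$name)]
                        } else NA_character_,
                        mean_abs_shap = colMeans(abs(collapsed)))
  ranking <- ranking[order(-ranking$mean_abs_shap), ]
  rownames(ranking) <- NULL
  scores <- data.frame(cell_id = rownames(collapsed) %||%
                         as.character(seq_along(psi)),
                       score = unname(psi))
  if (!is.null(predicted_class)) scores$predicted_class <- predicted_class
  structure(list(scores = scores, ranking = ranking, columns = columns),
            class = "score_vector")
}

#' @exportS3Method base::print
print.score_vector <- function(x, ...) {
  cat("score_vector:", nrow(x$scores), "cells; top features:\n")
  print(utils::head(x$ranking, 5))
  invisible(x)
}
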