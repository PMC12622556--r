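#' Correlate marker expression with the Interpretable Score
#'
#' Per-feature correlation between expression and the per-cell score on an
#' optional cell subset, with two-sided p-values and Benjamini-Hochberg
#' adjustment across all tested features. Zero-variance features are
#' reported with missing statistics, flagged, and excluded from the
#' adjustment.
#'
#' @param expression Cells x features matrix.
#' @param scores A `score_vector` or numeric vector aligned to the rows of
#'   `expression`.
#' @param cell_subset Optional logical/integer subset of cells (e.g. cells
#'   of one clinical group).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `data.frame` with one row per feature: `feature`, `r`, `n`,
#'   `p`, `p_adj`, `direction`, `zero_variance`; sorted by adjusted p, then
#'   decreasing absolute correlation.
#' @export
marker_score_correlation <- function(expression, scores, cell_subset = NULL,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (inherits(scores, "score_vector")) scores <- scores$scores$score
  expression <- as.matrix(expression)
  if (length(scores) != nrow(expression)) {
    stop("scores must align with the rows of expression")
  }
  if (!is.null(cell_subset)) {
    expression <- expression[cell_subset, , drop = FALSE]
    scores <- scores[cell_subset]
  }
  if (nrow(expression) < 3) stop("need at least 3 cells")

  res <- lapply(seq_len(ncol(expression)), function(j) {
    x <- expression[, j]
    if (stats::sd(x) == 0) {
      return(data.frame(feature = colnames(expression)[j], r = NA_real_,
                        n = length(x), p = NA_real_, zero_variance = TRUE))
    }
    ct <- stats::cor.test(x, scores, method = method, exact = FALSE)
    data.frame(feature = colnames(expression)[j], r = unname(ct$estimate),
               n = length(x), p = ct$p.value, zero_variance = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$p_adj <- NA_real_
  ok <- !tab$zero_variance
  tab$p_adj[ok] <- stats::p.adjust(tab$p[ok], method = "BH")
  tab$direction <- ifelse(is.na(tab$r), NA_character_,
                          ifelse(tab$r >= 0, "positive", "negative"))
  tab <- tab[order(tab$p_adj, -abs(tab$r), na.last = TRUE),
             c("feature", "r", "n", "p", "p_adj", "direction",
               "zero_variance")]
  rownames(tab) <- NULL
  tab
}

#' Per-cluster summaries and tests of the Interpretable Score
#'
#' Mean, median and IQR of the score per cluster; a global Kruskal-Wallis
#' test (Wilcoxon rank-sum when exactly two clusters are testable) and
#' per-cluster one-vs-rest Wilcoxon tests with BH adjustment. Clusters with
#' fewer than 3 cells are flagged and excluded from the tests.
#'
#' @param scores A `score_vector` or numeric vector.
#' @param cluster_labels Per-cell cluster label.
#' @return List with `summary` (per-cluster data frame), `global_test`
#'   (`htest`), `top_cluster` (highest mean among testable clusters).
#' @export
cluster_score_summary <- function(scores, cluster_labels) {
  if (inherits(scores, "score_vector")) scores <- scores$scores$score
  if (length(scores) != length(cluster_labels)) {
    stop("scores and cluster labels must align")
  }
  f <- factor(cluster_labels)
  if (nlevels(f) < 2) stop("need at least 2 clusters")
  sizes <- table(f)
  testable <- names(sizes)[sizes >= 3]

  summ <- data.frame(
    cluster = levels(f),
    n = as.integer(sizes),
    mean = as.numeric(tapply(scores, f, mean)),
    median = as.numeric(tapply(scores, f, stats::median)),
    iqr = as.numeric(tapply(scores, f, stats::IQR)),
    excluded = !(levels(f) %in% testable)
  )
  summ$p_vs_rest <- NA_real_
  for (cl in testable) {
    summ$p_vs_rest[summ$cluster == cl] <-
      stats::wilcox.test(scores[f == cl], scores[f != cl])$p.value
  }
  summ$p_vs_rest_adj <- NA_real_
  ok <- !is.na(summ$p_vs_rest)
  summ$p_vs_rest_adj[ok] <- stats::p.adjust(summ$p_vs_rest[ok], "BH")

  keep <- f %in% testable
  g <- droplevels(f[keep])
  global_test <- if (nlevels(g) == 2) {
    stats::wilcox.test(scores[keep][g == levels(g)[1]],
                       scores[keep][g == levels(g)[2]])
  } else {
    stats::kruskal.test(scores[keep], g)
  }
  top <- summ$cluster[!summ$excluded][which.max(summ$mean[!summ$excluded])]
  list(summary = summ, global_test = global_test, top_cluster = top)
}

#' Score detection accuracy against simulated ground truth
#'
#' Calls each cell condition-associated when its score exceeds the rule's
#' threshold (default `score > 0`; `rule = "quantile"` uses a score
#' quantile), compares calls with the simulator truth flags, and reports the
#' per-cluster proportion of matching calls and its median across clusters.
#' Cells of depleted clusters (negative `truth_direction`) count as
#' correctly detected when their score is negative.
#'
#' @param scores A `score_vector` or numeric vector.
#' @param truth Per-cell logical ground-truth flag from the simulator.
#' @param cluster_labels Per-cell cluster label.
#' @param rule `"positive"` (score > 0) or `"quantile"`.
#' @param truth_direction Optional per-cell shift direction (+1 expanded,
#'   -1 depleted, 0 none).
#' @param q Quantile for `rule = "quantile"`.
#' @return List of class `detection_report`: `per_cluster` data frame
#'   (`cluster`, `n`, `proportion_correct`, `mean_score`), `median`
#'   (median of the per-cluster proportions), `rule`.
#' @export
evaluate_detection <- function(scores, truth, cluster_labels,
                               rule = c("positive", "quantile"),
                               truth_direction = NULL, q = 0.9) {
  rule <- match.arg(rule)
  if (inherits(scores, "score_vector")) scores <- scores$scores$score
  if (is.null(truth)) stop("missing ground-truth flags")
  truth <- as.logical(truth)
  if (anyNA(truth)) stop("missing ground-truth flags")
  stopifnot(length(scores) == length(truth),
            length(scores) == length(cluster_labels))
  thr_hi <- if (rule == "positive") 0 else stats::quantile(scores, q)
  thr_lo <- if (rule == "positive") 0 else stats::quantile(scores, 1 - q)

  dir <- if (is.null(truth_direction)) rep(1L, length(scores)) else truth_direction
  called_up <- scores > thr_hi
  called_down <- scores < thr_lo
  correct <- ifelse(truth,
                    ifelse(dir < 0, called_down, called_up),
                    !called_up)

  f <- factor(cluster_labels)
  per <- data.frame(
    cluster = levels(f),
    n = as.integer(table(f)),
    proportion_correct = as.numeric(tapply(correct, f, mean)),
    mean_score = as.numeric(tapply(scores, f, mean))
  )
  structure(list(per_cluster = per,
                 median = stats::median(per$proportion_correct),
                 rule = rule),
            class = "detection_report")
}

#' @exportS3Method base::print
print.detection_report <- function(x, ...) {
  cat("detection_report (rule:", x$rule, ") median proportion correct:",
      round(x$median, 3), "\n")
  print(x$per_cluster, digits = 3)
  invisible(x)
}

#' Compare how score and predicted probability separate target clusters
#'
#' AUROC of membership in the target clusters against (a) the Interpretable
#' Score and (b) the classifier's predicted probability, on the same cells.
#'
#' @param scores A `score_vector` or numeric vector.
#' @param probabilities Per-cell predicted probability (e.g. of the disease
#'   class).
#' @param cluster_labels Per-cell cluster label.
#' @param target_clusters Clusters forming the positive set.
#' @return Named numeric vector `c(auroc_score, auroc_probability)`.
#' @export
separation_comparison <- function(scores, probabilities, cluster_labels,
                                  target_clusters) {
  if (inherits(scores, "score_vector")) scores <- scores$scores$score
  member <- cluster_labels %in% target_clusters
  if (!any(member) || all(member)) {
    stop("target clusters must include some but not all cells")
  }
  c(auroc_score = auc_binary(scores, member),
    auroc_probability = auc_binary(probabilities, member))
}
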