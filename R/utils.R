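# rank-based (Mann-Whitney) AUROC of a score against a binary indicator;
# ties get average rank
auc_binary <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) {
    stop("AUROC undefined: need both positive and negative cells")
  }
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# average precision (area under the precision-recall curve by the
# step-interpolation used for average precision)
auprc_binary <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  if (n1 == 0) stop("AUPRC undefined: no positive cells")
  o <- order(score, decreasing = TRUE)
  y <- positive[o]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  sum(precision[y]) / n1
}

# macro one-vs-rest AUROC over the columns of a probability matrix
auroc_macro <- function(prob, y) {
  y <- as.factor(y)
  mean(vapply(seq_len(ncol(prob)), function(c) {
    auc_binary(prob[, c], y == colnames(prob)[c])
  }, numeric(1)))
}
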