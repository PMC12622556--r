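#' Build a k-nearest-neighbour cell graph
#'
#' Finds the `k` nearest neighbours of every cell in the given representation
#' (typically top principal components of the expression matrix), takes the
#' union of directed edges to obtain a symmetric adjacency `A` (self-loops
#' excluded), and row-normalizes it into the random-walk transition matrix.
#' Edge weights are binary by default; `weight = "gaussian"` weights each
#' edge by `exp(-(d / sigma)^2)` with `sigma` the median k-th neighbour
#' distance, symmetrized by averaging.
#'
#' @param x Cells x dims numeric matrix; row names are cell ids.
#' @param k Neighbours per cell, `1 <= k < nrow(x)`.
#' @param weight `"binary"` or `"gaussian"`.
#' @param feature_space Free-text tag recording what `x` is.
#' @return An object of class `neighbor_graph` with elements `A` (sparse
#'   symmetric adjacency), `transition` (row-stochastic), `k`, `M`,
#'   `feature_space`.
#' @export
#' @examples
#' g <- build_knn_graph(matrix(rnorm(100), 20, 5), k = 3)
#' range(Matrix::rowSums(g$transition))
build_knn_graph <- function(x, k = 30L, weight = c("binary", "gaussian"),
                            feature_space = "embedding") {
  weight <- match.arg(weight)
  x <- as.matrix(x)
  M <- nrow(x)
  if (!all(is.finite(x))) stop("cell representation contains non-finite values")
  if (k < 1) stop("k must be at least 1")
  if (k >= M) stop("k (", k, ") must be smaller than the number of cells (", M, ")")
  if (is.null(rownames(x))) rownames(x) <- sprintf("cell%06d", seq_len(M))
  if (anyDuplicated(rownames(x))) stop("duplicate cell ids in representation")

  nn <- BiocNeighbors::findKNN(x, k = k, get.distance = (weight == "gaussian"))
  i <- rep(seq_len(M), times = k)
  j <- as.vector(nn$index)
  if (weight == "binary") {
    A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(M, M))
    A <- A + Matrix::t(A)
    A@x <- rep(1, length(A@x))
  } else {
    sigma <- stats::median(nn$distance[, k])
    if (sigma == 0) sigma <- 1
    w <- exp(-(as.vector(nn$distance) / sigma)^2)
    A <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(M, M))
    A <- (A + Matrix::t(A)) / 2
  }
  diag(A) <- 0
  A <- Matrix::drop0(A)
  rs <- Matrix::rowSums(A)
  if (any(rs == 0)) stop("isolated cell in kNN graph")  # cannot happen for k >= 1
  transition <- Matrix::Diagonal(x = 1 / rs) %*% A
  dimnames(A) <- list(rownames(x), rownames(x))
  dimnames(transition) <- dimnames(A)
  structure(list(A = A, transition = transition, k = as.integer(k), M = M,
                 feature_space = feature_space),
            class = "neighbor_graph")
}

#' @exportS3Method base::print
print.neighbor_graph <- function(x, ...) {
  cat("neighbor_graph:", x$M, "cells, k =", x$k, ", on", x$feature_space, "\n")
  invisible(x)
}

#' s-step random-walk probabilities
#'
#' Returns the dense matrix of probabilities that a walk started at cell `m'`
#' (row) ends at cell `m` (column) after `s` steps, i.e. the s-th power of
#' the row-stochastic transition matrix. `s = 0` gives the identity. Intended
#' for inspection and testing on small graphs; [build_nam()] never
#' materializes this matrix.
#'
#' @param graph A [build_knn_graph()] result (or any list with a
#'   row-stochastic `transition`).
#' @param s Number of steps, non-negative integer.
#' @return Dense `M x M` matrix with rows summing to 1.
#' @export
random_walk_probability <- function(graph, s) {
  if (length(s) != 1 || s < 0 || s != round(s)) {
    stop("s must be a non-negative integer")
  }
  M <- nrow(graph$transition)
  if (M > 4000) {
    stop("refusing to materialize a dense ", M, " x ", M,
         " walk matrix; use build_nam()")
  }
  P <- Matrix::Diagonal(M)
  for (i in seq_len(s)) P <- P %*% graph$transition
  P <- as.matrix(P)
  dimnames(P) <- dimnames(graph$transition)
  P
}

#' Build the sample-by-neighborhood abundance matrix (NAM)
#'
#' Computes `R[n, m]`, the expected number of cells from sample `n` found in
#' the neighborhood anchored at cell `m` after an `s`-step random walk, by
#' propagating the per-sample cell indicator matrix through the transition
#' matrix (`R = B T^s`, computed as repeated sparse products, never as a
#' dense `T^s`). The NAM `Q` row-normalizes `R` so each sample row sums
#' to 1. Row sums of `R` equal the per-sample cell counts (random-walk mass
#' conservation).
#'
#' @param graph A [build_knn_graph()] result.
#' @param sample_labels Per-cell sample id, length `M`, no missing values.
#' @param s Number of walk steps (default 3).
#' @return An object of class `nam`: list with `Q` (samples x cells, rows sum
#'   to 1), `R` (pre-normalization), `samples`, `cells`, `s`, `k`.
#' @export
build_nam <- function(graph, sample_labels, s = 3L) {
  M <- graph$M
  if (length(sample_labels) != M) {
    stop("sample_labels must have one entry per cell (", M, ")")
  }
  if (anyNA(sample_labels)) stop("missing sample labels")
  if (length(s) != 1 || s < 0 || s != round(s)) stop("s must be a non-negative integer")
  f <- factor(sample_labels)
  counts <- table(f)
  if (any(counts == 0)) {
    stop("empty sample(s): ", paste(names(counts)[counts == 0], collapse = ", "))
  }
  N <- nlevels(f)
  B <- Matrix::sparseMatrix(i = as.integer(f), j = seq_len(M), x = 1,
                            dims = c(N, M))
  R <- B
  for (i in seq_len(s)) R <- R %*% graph$transition
  R <- as.matrix(R)
  Q <- R / rowSums(R)
  cells <- colnames(graph$transition)
  dimnames(R) <- list(levels(f), cells)
  dimnames(Q) <- dimnames(R)
  structure(list(Q = Q, R = R, samples = levels(f), cells = cells,
                 s = as.integer(s), k = graph$k),
            class = "nam")
}

#' @exportS3Method base::print
print.nam <- function(x, ...) {
  cat("nam:", nrow(x$Q), "samples x", ncol(x$Q), "neighborhoods, s =", x$s, "\n")
  invisible(x)
}

#' Write a NAM to disk
#'
#' Writes `Q` either as a MatrixMarket file (`nam.mtx`) or a dense
#' `nam.csv` (samples as rows), plus a JSON sidecar (`nam.json`) recording
#' the walk length, graph `k`, and dimensions.
#'
#' @param nam A [build_nam()] result.
#' @param dir Output directory (created if missing).
#' @param format `"mtx"` or `"csv"`.
#' @return `dir`, invisibly.
#' @export
write_nam <- function(nam, dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx") {
    Matrix::writeMM(as(Matrix::Matrix(nam$Q, sparse = TRUE), "CsparseMatrix"),
                    file.path(dir, "nam.mtx"))
    writeLines(nam$samples, file.path(dir, "nam_samples.tsv"))
    writeLines(nam$cells, file.path(dir, "nam_cells.tsv"))
  } else {
    utils::write.csv(data.frame(sample = nam$samples, nam$Q,
                                check.names = FALSE),
                     file.path(dir, "nam.csv"), row.names = FALSE)
  }
  jsonlite::write_json(list(s = nam$s, k = nam$k,
                            n_samples = nrow(nam$Q), n_cells = ncol(nam$Q)),
                       file.path(dir, "nam.json"), auto_unbox = TRUE)
  invisible(dir)
}
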