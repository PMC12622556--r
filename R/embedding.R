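#' Reduce the NAM by principal component analysis
#'
#' Column-centres `Q` and takes its singular value decomposition. The
#' per-cell (per-neighborhood) coordinates are the neighborhood-side singular
#' vectors scaled by the singular values, so cells and latent scores stay in
#' one-to-one correspondence with neighborhoods. Initialization starts from
#' up to `n_init` components (clipped to the available rank) and keeps the
#' top `n_keep` of them, further truncated to the dimensions needed to reach
#' a cumulative variance-explained threshold. The sign of each dimension is
#' fixed so its largest-magnitude cell score is positive.
#'
#' @param nam A [build_nam()] result.
#' @param n_init Components to start from (default 100).
#' @param n_keep Components to keep (default 20).
#' @param ve_threshold Optional cumulative variance-explained threshold used
#'   to truncate below `n_keep` (default 1, i.e. keep all `n_keep`
#'   dimensions; early truncation can drop weak abundance contrasts that sit
#'   in low-variance dimensions).
#' @param center Column-centre `Q` before the decomposition.
#' @return An object of class `latent_embedding`: `scores` (cells x d),
#'   `method = "pca"`, `d`, `variance_explained` (per kept dimension,
#'   non-increasing), `sample_loadings` (samples x d, for back-projection),
#'   `center`, `harmonized`, `removed`.
#' @export
reduce_pca <- function(nam, n_init = 100L, n_keep = 20L, ve_threshold = 1,
                       center = TRUE) {
  Q <- nam$Q
  N <- nrow(Q); M <- ncol(Q)
  stopifnot(n_keep >= 1, n_init >= n_keep, ve_threshold > 0, ve_threshold <= 1)
  r_max <- min(N - as.integer(center), M)
  n_init <- min(n_init, r_max)
  Qc <- scale(Q, center = center, scale = FALSE)
  sv <- svd(Qc)
  pos <- sv$d > max(sv$d) * 1e-12
  r <- min(n_init, sum(pos))
  ve_all <- sv$d^2 / sum(sv$d^2)
  d_keep <- min(n_keep, r)
  if (d_keep < n_keep) {
    warning("rank of the centered NAM supports only ", d_keep,
            " of the requested ", n_keep, " dimensions")
  }
  cum <- cumsum(ve_all)
  hit <- which(cum >= ve_threshold)
  if (length(hit)) d_keep <- min(d_keep, max(1L, hit[1]))

  idx <- seq_len(d_keep)
  scores <- sv$v[, idx, drop = FALSE] %*% diag(sv$d[idx], d_keep)
  loadings <- sv$u[, idx, drop = FALSE]
  for (j in idx) {
    if (scores[which.max(abs(scores[, j])), j] < 0) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  dimnames(scores) <- list(nam$cells, paste0("LD", idx))
  dimnames(loadings) <- list(nam$samples, paste0("LD", idx))
  structure(list(scores = scores, method = "pca", d = d_keep,
                 variance_explained = ve_all[idx],
                 sample_loadings = loadings,
                 center = if (center) attr(Qc, "scaled:center") else NULL,
                 harmonized = FALSE, removed = character(0)),
            class = "latent_embedding")
}

#' @exportS3Method base::print
print.latent_embedding <- function(x, ...) {
  cat("latent_embedding:", nrow(x$scores), "cells x", x$d, "dims (",
      x$method, ")")
  if (x$harmonized) cat(", harmonized over", paste(x$removed, collapse = "+"))
  cat("\n")
  invisible(x)
}

# non-negative double SVD initialization (zeros filled with the matrix mean,
# so multiplicative updates are not stuck at exact zeros)
nndsvd_init <- function(Q, k) {
  sv <- svd(Q, nu = k, nv = k)
  W <- matrix(0, nrow(Q), k)
  H <- matrix(0, k, ncol(Q))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  for (j in seq_len(k)[-1]) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npos >= nneg) {
      if (npos > 0) {
        W[, j] <- sqrt(sv$d[j] * npos) * up / sqrt(sum(up^2))
        H[j, ] <- sqrt(sv$d[j] * npos) * vp / sqrt(sum(vp^2))
      }
    } else {
      W[, j] <- sqrt(sv$d[j] * nneg) * un / sqrt(sum(un^2))
      H[j, ] <- sqrt(sv$d[j] * nneg) * vn / sqrt(sum(vn^2))
    }
  }
  m <- mean(Q)
  W[W == 0] <- m
  H[H == 0] <- m
  list(W = W, H = H)
}

#' Reduce the NAM by non-negative matrix factorization
#'
#' Factorizes the non-negative NAM as `Q ~ W H` (`W`: samples x k, `H`:
#' k x cells) with multiplicative updates from a non-negative double-SVD
#' initialization, stopping when the relative change of the Frobenius
#' reconstruction error drops below `tol` or after `max_iter` iterations.
#' The per-cell scores are `t(H)`; unlike PCA the dimensions are
#' non-negative and not orthogonal.
#'
#' @param nam A [build_nam()] result (entries must be non-negative).
#' @param k Rank, `2 <= k < min(samples, cells)` (rank 1 is allowed for
#'   degenerate checks).
#' @param seed Seed (the initialization is deterministic; the seed only
#'   guards against future stochastic solvers).
#' @param tol Relative-change convergence tolerance (default 1e-5).
#' @param max_iter Maximum iterations (default 500).
#' @return A `latent_embedding` with `method = "nmf"`, non-negative
#'   `scores`, `sample_loadings = W`, and the reconstruction-error
#'   trajectory in `recon_errors`.
#' @export
reduce_nmf <- function(nam, k, seed = 1L, tol = 1e-5, max_iter = 500L) {
  Q <- nam$Q
  if (any(Q < 0)) stop("NMF requires a non-negative matrix")
  if (k < 1 || k >= min(dim(Q))) {
    stop("k must satisfy 1 <= k < min(samples, cells)")
  }
  set.seed(seed)
  init <- nndsvd_init(Q, k)
  W <- init$W; H <- init$H
  eps <- 1e-10
  errs <- numeric(0)
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, Q)) / (crossprod(W) %*% H + eps)
    W <- W * (Q %*% t(H)) / (W %*% tcrossprod(H) + eps)
    err <- sqrt(sum((Q - W %*% H)^2))
    errs <- c(errs, err)
    if (is.finite(err_prev) && abs(err_prev - err) <= tol * max(err_prev, eps)) break
    err_prev <- err
  }
  scores <- t(H)
  dimnames(scores) <- list(nam$cells, paste0("LD", seq_len(k)))
  dimnames(W) <- list(nam$samples, paste0("LD", seq_len(k)))
  structure(list(scores = scores, method = "nmf", d = as.integer(k),
                 rank = as.integer(k), sample_loadings = W,
                 recon_errors = errs, harmonized = FALSE,
                 removed = character(0)),
            class = "latent_embedding")
}

#' Select the NMF rank by silhouette
#'
#' Fits an NMF at each candidate rank, assigns every cell to its
#' maximum-loading factor, and computes the mean silhouette width of that
#' labelling in factor-score space; the rank with the highest mean
#' silhouette wins (ties go to the smallest rank). Ranks whose labelling
#' collapses to a single factor score -1. For large cell numbers the
#' silhouette is evaluated on a seeded subsample.
#'
#' @param nam A [build_nam()] result.
#' @param candidate_ks Integer ranks to try, all `>= 2` and `<` the number
#'   of cells.
#' @param seed Seed for the subsample.
#' @param subsample Max cells used for the silhouette (default 2000).
#' @return The selected rank (integer), with the per-rank mean silhouettes
#'   in attribute `"silhouettes"`.
#' @export
select_nmf_rank <- function(nam, candidate_ks = 2:6, seed = 1L,
                            subsample = 2000L) {
  M <- ncol(nam$Q)
  if (any(candidate_ks < 2)) stop("candidate ranks must be >= 2")
  if (any(candidate_ks >= M)) stop("candidate ranks must be below the number of cells")
  sil <- vapply(candidate_ks, function(k) {
    emb <- reduce_nmf(nam, k, seed = seed)
    sc <- emb$scores
    lab <- max.col(sc, ties.method = "first")
    if (length(unique(lab)) < 2) return(-1)
    idx <- seq_len(nrow(sc))
    if (nrow(sc) > subsample) {
      set.seed(seed)
      idx <- sort(sample.int(nrow(sc), subsample))
      if (length(unique(lab[idx])) < 2) return(-1)
    }
    mean(cluster::silhouette(lab[idx], stats::dist(sc[idx, , drop = FALSE]))[, 3])
  }, numeric(1))
  best <- candidate_ks[which.max(sil)]  # which.max takes the first (smallest) tie
  structure(as.integer(best), silhouettes = setNames(sil, candidate_ks))
}

#' Remove technical covariate structure from an embedding
#'
#' Adjusts the latent scores for one or more technical grouping variables
#' (sample, batch, ...) through a narrow interface around a linear
#' batch-effect removal (`limma::removeBatchEffect`): group means are
#' removed from every latent dimension while the dimensionality and cell
#' count are untouched. Biological covariates such as age and sex should
#' never be passed here, so that their variation is retained for the
#' classifier. With `enabled = FALSE` the embedding is returned unchanged.
#'
#' When a grouping variable is partially confounded with the phenotype
#' (e.g. each sample is wholly diseased or wholly healthy), pass the
#' phenotype as `protect`: the adjustment is then estimated orthogonally to
#' it, so group means are removed without flattening the biological
#' contrast.
#'
#' @param embedding A `latent_embedding`.
#' @param batch A vector, or data frame of per-cell grouping variables to
#'   remove.
#' @param protect Optional per-cell labels of a biological contrast to
#'   preserve (used as the design of the adjustment model).
#' @param enabled Set to `FALSE` for a strict identity pass-through.
#' @return The adjusted `latent_embedding` (`harmonized = TRUE`, removed
#'   variable names recorded).
#' @export
harmonize <- function(embedding, batch, protect = NULL, enabled = TRUE) {
  if (!enabled) return(embedding)
  if (is.null(dim(batch))) batch <- data.frame(batch = batch)
  batch <- as.data.frame(batch)
  if (nrow(batch) != nrow(embedding$scores)) {
    stop("batch labels must align with cells")
  }
  usable <- vapply(batch, function(v) length(unique(v)) >= 2, logical(1))
  if (!any(usable)) {
    warning("all grouping variables have a single level; returning the ",
            "embedding unchanged")
    return(embedding)
  }
  if (!all(usable)) {
    warning("dropping single-level grouping variable(s): ",
            paste(names(batch)[!usable], collapse = ", "))
    batch <- batch[, usable, drop = FALSE]
  }
  b1 <- factor(batch[[1]])
  b2 <- if (ncol(batch) >= 2) factor(batch[[2]]) else NULL
  covs <- NULL
  if (ncol(batch) > 2) {
    extra <- lapply(names(batch)[-(1:2)], function(nm) {
      mm <- model.matrix(~ factor(batch[[nm]]))[, -1, drop = FALSE]
      colnames(mm) <- paste0(nm, seq_len(ncol(mm)))
      mm
    })
    covs <- do.call(cbind, extra)
  }
  design <- if (!is.null(protect)) {
    stats::model.matrix(~ factor(protect))
  } else {
    matrix(1, nrow(batch), 1)
  }
  adj <- t(limma::removeBatchEffect(t(embedding$scores), batch = b1,
                                    batch2 = b2, covariates = covs,
                                    design = design))
  dimnames(adj) <- dimnames(embedding$scores)
  embedding$scores <- adj
  embedding$harmonized <- TRUE
  embedding$removed <- union(embedding$removed, names(batch))
  embedding
}
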