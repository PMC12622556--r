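make_nam <- function(Q) {
  list(Q = Q, R = Q * 10, samples = rownames(Q),
       cells = colnames(Q) %||% paste0("c", seq_len(ncol(Q))), s = 3L, k = 5L)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("PCA scores match a dense eigendecomposition oracle", {
  set.seed(1)
  Q <- matrix(runif(5 * 8), 5, 8)
  Q <- Q / rowSums(Q)
  emb <- reduce_pca(make_nam(Q), n_init = 4, n_keep = 4, ve_threshold = 1)
  Qc <- scale(Q, scale = FALSE)
  eig <- eigen(crossprod(Qc))
  for (j in seq_len(emb$d)) {
    v <- eig$vectors[, j] * sqrt(eig$values[j])
    expect_equal(abs(unname(emb$scores[, j])), abs(v), tolerance = 1e-8)
  }
  # variance explained ordered and consistent with eigenvalues
  expect_true(all(diff(emb$variance_explained) <= 1e-12))
  expect_equal(emb$variance_explained[1],
               eig$values[1] / sum(pmax(eig$values, 0)), tolerance = 1e-8)
})

test_that("PCA back-projection reconstructs the centered NAM", {
  set.seed(2)
  Q <- matrix(runif(6 * 30), 6, 30)
  Q <- Q / rowSums(Q)
  emb <- reduce_pca(make_nam(Q), n_init = 5, n_keep = 5, ve_threshold = 1)
  recon <- emb$sample_loadings %*% t(emb$scores)
  expect_equal(max(abs(recon - scale(Q, scale = FALSE))), 0, tolerance = 1e-8)
})

test_that("rank-1 NAM puts all variance on one dimension and warns", {
  Q <- outer(c(1, 2, 3, 4), rep(0.25, 8))
  Q <- Q / rowSums(Q) + outer(c(0.1, 0.2, 0.3, 0.4), seq(0.01, 0.08, 0.01))
  Q <- Q / rowSums(Q)
  expect_warning(emb <- reduce_pca(make_nam(Q), n_init = 3, n_keep = 3,
                                   ve_threshold = 1), "rank")
  expect_gt(emb$variance_explained[1], 0.99)
})

test_that("PCA defaults start from 100 components and keep 20", {
  expect_equal(formals(reduce_pca)$n_init, 100L)
  expect_equal(formals(reduce_pca)$n_keep, 20L)
  set.seed(3)
  Q <- matrix(runif(30 * 200), 30, 200); Q <- Q / rowSums(Q)
  emb <- reduce_pca(make_nam(Q), ve_threshold = 1)
  expect_equal(emb$d, 20L)
  # deterministic sign: largest-|score| entry of each dimension is positive
  for (j in 1:emb$d) expect_gt(emb$scores[which.max(abs(emb$scores[, j])), j], 0)
})

test_that("NMF separates disjoint blocks and keeps everything non-negative", {
  Q <- rbind(c(5, 4, 6, 0, 0, 0), c(6, 5, 5, 0, 0, 0),
             c(0, 0, 0, 5, 6, 4), c(0, 0, 0, 4, 5, 6)) + 0.01
  Q <- Q / rowSums(Q)
  emb <- reduce_nmf(make_nam(Q), k = 2, seed = 1)
  expect_true(all(emb$scores >= 0))
  load_frac <- emb$scores / rowSums(emb$scores)
  lab <- max.col(load_frac)
  expect_equal(length(unique(lab[1:3])), 1)
  expect_equal(length(unique(lab[4:6])), 1)
  expect_true(all(apply(load_frac, 1, max) >= 0.9))
  # multiplicative updates never increase the reconstruction error
  expect_true(all(diff(emb$recon_errors) <= 1e-8))
})

test_that("rank-1 NMF on a rank-1 matrix recovers the column profile", {
  Q <- outer(c(1, 2, 3, 4), c(4, 1, 2, 3, 5))
  Q <- Q / rowSums(Q)
  emb <- reduce_nmf(make_nam(Q), k = 1, seed = 1)
  prof <- emb$scores[, 1] / sum(emb$scores[, 1])
  expected <- colMeans(Q) / sum(colMeans(Q))
  expect_equal(unname(prof), unname(expected), tolerance = 1e-6)
  expect_error(reduce_nmf(make_nam(Q - 1), k = 1), "non-negative")
})

test_that("silhouette-based rank selection finds planted structure", {
  set.seed(4)
  blockQ <- function(n_per, k, noise = 0.02) {
    Q <- matrix(noise * runif(4 * n_per * k), 4 * 1, n_per * k)
    Q <- do.call(rbind, lapply(1:4, function(i) {
      row <- rep(noise, n_per * k)
      g <- ((i - 1) %% k)
      row[(g * n_per + 1):((g + 1) * n_per)] <- 1
      row + noise * runif(n_per * k)
    }))
    Q / rowSums(Q)
  }
  Q <- rbind(blockQ(10, 2), blockQ(10, 2))
  sel <- select_nmf_rank(make_nam(Q), candidate_ks = 2:5, seed = 1)
  expect_equal(as.integer(sel), 2L)
  # reported silhouettes agree with the direct pairwise-distance formula
  emb <- reduce_nmf(make_nam(Q), k = 2, seed = 1)
  lab <- max.col(emb$scores, ties.method = "first")
  expect_equal(unname(attr(sel, "silhouettes")["2"]),
               mean(oracle_silhouette(lab, emb$scores)), tolerance = 1e-8)
  expect_error(select_nmf_rank(make_nam(Q), candidate_ks = c(2, 50)),
               "below the number of cells")
})

test_that("harmonization removes batch offsets but not the protected contrast", {
  set.seed(5)
  n <- 300
  scores <- cbind(rnorm(n), rnorm(n))
  colnames(scores) <- c("LD1", "LD2")
  batch <- rep(c("b1", "b2"), each = n / 2)
  scores[batch == "b2", 1] <- scores[batch == "b2", 1] + 2
  emb <- structure(list(scores = scores, method = "pca", d = 2L,
                        harmonized = FALSE, removed = character(0)),
                   class = "latent_embedding")
  adj <- harmonize(emb, batch)
  gap0 <- abs(diff(tapply(scores[, 1], batch, mean)))
  gap1 <- abs(diff(tapply(adj$scores[, 1], batch, mean)))
  expect_lt(gap1, 0.2 * gap0)
  expect_equal(dim(adj$scores), dim(scores))
  expect_true(adj$harmonized)

  # identity contracts
  expect_identical(harmonize(emb, batch, enabled = FALSE), emb)
  expect_warning(same <- harmonize(emb, rep("b1", n)), "single level")
  expect_identical(same$scores, emb$scores)

  # protected contrast survives confounded adjustment
  cond <- rep(c("ctl", "dis"), n / 2)
  scores2 <- scores
  scores2[cond == "dis", 2] <- scores2[cond == "dis", 2] + 1.5
  emb2 <- emb; emb2$scores <- scores2
  sample_id <- paste0(batch, "_", rep(1:25, each = 6), "_", cond)
  gap_before <- abs(diff(tapply(scores2[, 2], cond, mean)))
  adj2 <- suppressWarnings(harmonize(emb2, sample_id, protect = cond))
  adj2_unprot <- suppressWarnings(harmonize(emb2, sample_id))
  gap_prot <- abs(diff(tapply(adj2$scores[, 2], cond, mean)))
  gap_unprot <- abs(diff(tapply(adj2_unprot$scores[, 2], cond, mean)))
  expect_lt(gap_unprot, 0.1 * gap_before)  # unprotected removal flattens it
  expect_gt(gap_prot, 0.5 * gap_before)    # protection retains most of it
})
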