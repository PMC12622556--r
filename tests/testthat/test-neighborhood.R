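test_that("kNN graph is symmetric, row-stochastic, and matches brute force", {
  set.seed(1)
  x <- matrix(rnorm(200 * 5), 200, 5)
  g <- build_knn_graph(x, k = 10)
  expect_true(Matrix::isSymmetric(g$A))
  expect_equal(max(abs(Matrix::rowSums(g$transition) - 1)), 0,
               tolerance = 1e-9)
  expect_true(all(g$transition@x >= 0))
  expect_equal(sum(Matrix::diag(g$A)), 0)

  # brute-force all-pairs neighbour sets agree with the search
  D <- as.matrix(dist(x))
  diag(D) <- Inf
  hits <- vapply(seq_len(200), function(i) {
    expected <- order(D[i, ])[1:10]
    found <- which(g$A[i, ] > 0)
    mean(expected %in% found)
  }, numeric(1))
  expect_gte(mean(hits), 0.99)
})

test_that("three collinear points connect the middle to its nearest endpoint", {
  x <- matrix(c(0, 1, 5), ncol = 1)
  g <- build_knn_graph(x, k = 1)
  A <- as.matrix(g$A)
  expect_equal(A[2, 1], 1)  # middle -> nearest endpoint
  expect_equal(A, t(A))     # union symmetrization
  expect_equal(A[3, 2], 1)  # far endpoint's nearest is the middle
})

test_that("graph construction validates its inputs", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(build_knn_graph(x, k = 10), "smaller than")
  expect_error(build_knn_graph(x, k = 0), "at least 1")
  x[1, 1] <- NA
  expect_error(build_knn_graph(x, k = 2), "non-finite")
  x[1, 1] <- 0
  rownames(x) <- rep("dup", 10)
  expect_error(build_knn_graph(x, k = 2), "duplicate")
})

test_that("random walk powers behave like transition-matrix powers", {
  g <- list(transition = Matrix::Matrix(c(0, 1, 1, 0), 2, 2, sparse = TRUE))
  expect_equal(unname(random_walk_probability(g, 0)), diag(2))
  expect_equal(unname(random_walk_probability(g, 1)),
               matrix(c(0, 1, 1, 0), 2))
  expect_equal(unname(random_walk_probability(g, 2)), diag(2))
  u <- Matrix::Matrix(1 / 3, 3, 3, sparse = FALSE)
  expect_equal(unname(random_walk_probability(list(transition = u), 5)),
               matrix(1 / 3, 3, 3))
  expect_error(random_walk_probability(g, -1), "non-negative")
})

test_that("NAM rows are normalized and mass is conserved", {
  # hand-computable uniform transition on 4 cells, 2 samples
  u <- Matrix::Matrix(1 / 4, 4, 4, sparse = FALSE)
  g <- list(transition = u, M = 4L, k = 1L)
  nam <- build_nam(g, c("s1", "s1", "s2", "s2"), s = 1)
  expect_equal(unname(nam$R), matrix(0.5, 2, 4))
  expect_equal(unname(nam$Q), matrix(0.25, 2, 4))

  # random graph: rows of Q sum to 1, rows of R sum to sample sizes
  set.seed(2)
  x <- matrix(rnorm(120 * 4), 120, 4)
  g2 <- build_knn_graph(x, k = 6)
  labels <- sample(paste0("s", 1:5), 120, replace = TRUE)
  for (s in c(0, 1, 3)) {
    nam2 <- build_nam(g2, labels, s = s)
    expect_equal(max(abs(rowSums(nam2$Q) - 1)), 0, tolerance = 1e-9)
    expect_equal(as.numeric(rowSums(nam2$R)),
                 as.numeric(table(factor(labels))), tolerance = 1e-6)
    expect_true(all(nam2$Q >= 0))
  }

  # single sample: one row summing to 1
  nam1 <- build_nam(g2, rep("only", 120), s = 2)
  expect_equal(dim(nam1$Q), c(1L, 120L))
  expect_equal(sum(nam1$Q), 1, tolerance = 1e-9)

  expect_error(build_nam(g2, labels[-1]), "one entry per cell")
  expect_error(build_nam(g2, c(labels[-1], NA)), "missing")
})

test_that("indicator propagation equals the dense walk-matrix computation", {
  set.seed(3)
  x <- matrix(rnorm(80 * 3), 80, 3)
  g <- build_knn_graph(x, k = 5)
  labels <- rep(paste0("s", 1:4), each = 20)
  for (s in c(1, 2, 4)) {
    nam <- build_nam(g, labels, s = s)
    P <- random_walk_probability(g, s)
    B <- t(sapply(paste0("s", 1:4), function(l) as.numeric(labels == l)))
    expect_equal(max(abs(nam$R - B %*% P)), 0, tolerance = 1e-10)
  }
})

test_that("longer walks mix samples toward uniformity on a connected graph", {
  set.seed(4)
  x <- matrix(rnorm(100 * 2), 100, 2)
  g <- build_knn_graph(x, k = 8)
  labels <- rep(c("a", "b"), 50)
  v <- sapply(c(1, 2, 4, 16), function(s) {
    mean(apply(build_nam(g, labels, s = s)$Q, 1, var))
  })
  expect_true(all(diff(v) <= 1e-12))
})

test_that("the NAM round-trips to disk with its sidecar", {
  set.seed(5)
  g <- build_knn_graph(matrix(rnorm(60 * 3), 60, 3), k = 4)
  nam <- build_nam(g, rep(c("s1", "s2", "s3"), 20), s = 2)
  dir <- withr::local_tempdir()
  write_nam(nam, dir, format = "mtx")
  Q2 <- as.matrix(Matrix::readMM(file.path(dir, "nam.mtx")))
  expect_equal(unname(nam$Q), unname(Q2), tolerance = 1e-12)
  side <- jsonlite::read_json(file.path(dir, "nam.json"))
  expect_equal(side$s, 2)
  expect_equal(side$k, 4)
})
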