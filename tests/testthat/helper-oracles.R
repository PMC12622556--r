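# Independent oracles used across test files. These are deliberately naive
# (enumeration / direct formulas) and never share code with the package
# implementation they check.

# --- brute-force Shapley values on an extracted tree structure -------------
# path-dependent conditional expectation: unseen splits are averaged with
# cover weights, seen splits follow x
oracle_expvalue <- function(tr, node, x, S) {
  f <- tr$feature[node]
  if (f < 0) return(tr$values[node, ])
  if ((f + 1) %in% S) {
    nxt <- if (x[f + 1] <= tr$threshold[node]) tr$left[node] else tr$right[node]
    return(oracle_expvalue(tr, nxt + 1, x, S))
  }
  wl <- tr$cover[tr$left[node] + 1] / tr$cover[node]
  wr <- tr$cover[tr$right[node] + 1] / tr$cover[node]
  wl * oracle_expvalue(tr, tr$left[node] + 1, x, S) +
    wr * oracle_expvalue(tr, tr$right[node] + 1, x, S)
}

# exhaustive Shapley sum over all feature subsets
oracle_shap <- function(tr, x, p) {
  n_out <- ncol(tr$values)
  phi <- matrix(0, p, n_out)
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    for (k in 0:length(others)) {
      subs <- if (k == 0) list(integer(0)) else utils::combn(others, k, simplify = FALSE)
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      for (S in subs) {
        phi[i, ] <- phi[i, ] +
          w * (oracle_expvalue(tr, 1, x, c(S, i)) - oracle_expvalue(tr, 1, x, S))
      }
    }
  }
  phi
}

# slice one tree out of an extract_forest() result
forest_tree <- function(fo, t) {
  idx <- (fo$tree_offset[t] + 1):(fo$tree_offset[t + 1])
  list(left = fo$left[idx], right = fo$right[idx], feature = fo$feature[idx],
       threshold = fo$threshold[idx], values = fo$values[idx, , drop = FALSE],
       cover = fo$cover[idx])
}

# fit a small ranger probability forest wrapped as a pheno_model
toy_forest <- function(X, y, num.trees = 3, max.depth = 3, seed = 1) {
  rf <- ranger::ranger(x = X, y = y, probability = TRUE,
                       num.trees = num.trees, max.depth = max.depth,
                       seed = seed, num.threads = 1)
  structure(list(engine = "ranger", fit = rf, train = X, y = y,
                 classes = levels(y),
                 params = list(num.trees = num.trees)),
            class = "pheno_model")
}

# --- step-up Benjamini-Hochberg from the definition ------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# --- silhouette width from the definition ----------------------------------
oracle_silhouette <- function(labels, X) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- if (sum(own) == 1) 0 else (b - a) / max(a, b)
  }
  s
}

# --- small simulated cohorts ------------------------------------------------
tiny_config <- function(seed = 1, ...) {
  defaults <- list(n_subjects_per_group = 4L, cells_per_cluster = 15L,
                   clusters = c("A", "B", "C"), expanded = c(A = 2),
                   n_features = 8L, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

tiny_model_config <- function(seed = 1, ...) {
  defaults <- list(n_outer_folds = 2L, n_inner_folds = 2L, n_repeats = 1L,
                   search_budget = 2L, holdout_fraction = 0,
                   depth_range = c(3L, 5L), seed = seed)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}
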