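make_blobs <- function(n_samples = 12, cells_each = 25, sep = 4, seed = 1,
                       d = 3) {
  set.seed(seed)
  cls <- rep(c("ctl", "dis"), each = n_samples / 2)
  rows <- lapply(seq_len(n_samples), function(i) {
    mu <- if (cls[i] == "dis") sep else 0
    cbind(matrix(rnorm(cells_each * d, mean = mu), cells_each, d))
  })
  X <- do.call(rbind, rows)
  colnames(X) <- paste0("LD", seq_len(d))
  list(X = X, y = rep(cls, each = cells_each),
       sample = rep(sprintf("s%02d", seq_len(n_samples)), each = cells_each))
}

test_that("design matrix assembles latent, covariate and interaction columns", {
  set.seed(2)
  scores <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("LD", 1:3)))
  cov <- data.frame(sex = rep(c("F", "M"), 5), age = seq(20, 65, 5))
  y <- rep(c("a", "b"), each = 5)
  sid <- rep(c("s1", "s2", "s3", "s4"), c(3, 2, 3, 2))
  d <- build_design(scores, cov, interaction_vars = "sex", y = y,
                    sample_ids = sid)
  expect_equal(ncol(d$values), 3 + 2 + 3)
  expect_equal(sum(d$roles$role == "interaction"), 3)
  # interaction columns are exactly latent * encoded variable
  enc_sex <- as.numeric(factor(cov$sex)) - 1
  for (j in 1:3) {
    expect_equal(unname(d$values[, paste0("LD", j, ":sex")]),
                 unname(scores[, j] * enc_sex))
  }
  # no covariates reduces to the plain embedding
  d0 <- build_design(scores, NULL, character(0), y, sample_ids = sid)
  expect_equal(unname(d0$values), unname(scores))
  expect_true(all(d0$roles$role == "latent"))
})

test_that("design validation catches id-like and constant covariates", {
  scores <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("LD1", "LD2")))
  y <- rep(c("a", "b"), 15)
  ids <- data.frame(tag = paste0("cell", 1:30))
  expect_error(build_design(scores, ids, character(0), y), "id column")
  expect_warning(build_design(scores, data.frame(flat = rep(1, 30)),
                              character(0), y), "constant")
  expect_error(build_design(scores, NULL, character(0), rep("a", 30)),
               "at least 2 classes")
})

test_that("continuous interaction variables are z-scored before the product", {
  scores <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("LD1", "LD2")))
  cov <- data.frame(age = seq(20, 77, 3))
  d <- build_design(scores, cov, "age", rep(c("a", "b"), 10))
  expect_equal(unname(d$values[, "LD1:age"]),
               unname(scores[, 1] * as.numeric(scale(cov$age))))
})

test_that("perfectly separable samples reach holdout AUROC 1", {
  b <- make_blobs(sep = 6)
  d <- build_design(b$X, NULL, character(0), b$y, sample_ids = b$sample)
  fit <- nested_cv_fit(d, tiny_model_config(holdout_fraction = 0.25))
  expect_equal(unname(fit$metrics$dis["auroc"]), 1)
  expect_equal(unname(fit$metrics$dis["auprc"]), 1)
})

test_that("permuted labels give chance-level performance", {
  set.seed(3)
  b <- make_blobs(n_samples = 20, cells_each = 100, sep = 5, d = 2)
  y_perm <- b$y
  # permute class assignment at the sample level
  samp <- unique(b$sample)
  new_cls <- sample(rep(c("ctl", "dis"), length(samp) / 2))
  y_perm <- new_cls[match(b$sample, samp)]
  d <- build_design(b$X, NULL, character(0), y_perm, sample_ids = b$sample)
  fit <- nested_cv_fit(d, tiny_model_config(holdout_fraction = 0))
  expect_lt(abs(fit$metrics$dis["auroc"] - 0.5), 0.1)
})

test_that("folds cover every cell, group samples, and preserve class shares", {
  b <- make_blobs(n_samples = 20, cells_each = 50)
  d <- build_design(b$X, NULL, character(0), b$y, sample_ids = b$sample)
  cfg <- tiny_model_config(n_outer_folds = 3L, holdout_fraction = 0.2)
  fit <- nested_cv_fit(d, cfg)
  rep1 <- fit$repeats[[1]]
  # every cell in exactly one fold (0 = holdout)
  expect_true(all(rep1$fold_id %in% 0:3))
  expect_false(anyNA(rep1$oof_prob))
  # probabilities sum to 1
  expect_equal(max(abs(rowSums(fit$oof_prob) - 1)), 0, tolerance = 1e-9)
  # all cells of a sample share one fold
  expect_true(all(tapply(rep1$fold_id, b$sample,
                         function(v) length(unique(v))) == 1))
  # class shares per fold stay near the global share
  global <- mean(b$y == "dis")
  for (k in 1:3) {
    expect_lt(abs(mean(b$y[rep1$fold_id == k] == "dis") - global), 0.05 + 0.1)
  }
})

test_that("fits are reproducible under a fixed seed", {
  b <- make_blobs(n_samples = 12, cells_each = 20, sep = 2)
  d <- build_design(b$X, NULL, character(0), b$y, sample_ids = b$sample)
  f1 <- nested_cv_fit(d, tiny_model_config(seed = 5))
  f2 <- nested_cv_fit(d, tiny_model_config(seed = 5))
  expect_identical(f1$repeats[[1]]$fold_id, f2$repeats[[1]]$fold_id)
  expect_identical(f1$repeats[[1]]$best_params, f2$repeats[[1]]$best_params)
  expect_identical(f1$oof_prob, f2$oof_prob)
})

test_that("prediction is a majority vote with deterministic tie-breaking", {
  set.seed(6)
  X <- matrix(rnorm(100 * 2), 100, 2, dimnames = list(NULL, c("LD1", "LD2")))
  y <- factor(ifelse(X[, 1] > 0, "b", "a"))
  m1 <- toy_forest(X, y, num.trees = 1, max.depth = 2, seed = 1)
  fo <- phenoscore:::extract_forest(m1)
  # single tree: forest prediction equals that tree's leaf value
  pred <- phenoscore:::rcpp_tree_predict(fo$tree_offset, fo$left, fo$right,
                                         fo$feature, fo$threshold, fo$values,
                                         X[1:10, ], 2L)
  expect_equal(unname(predict(m1, X[1:10, ])), unname(pred))
  # exact tie goes to the lower-indexed class
  mt <- m1
  cls <- predict(mt, X[1:4, ])
  tied <- matrix(0.5, 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(as.character(factor(c("a", "b")[max.col(tied, "first")])),
               c("a", "a"))
  expect_error(predict(m1, X[, 1, drop = FALSE]), "missing model columns")
})

test_that("a class with fewer samples than folds is refused", {
  b <- make_blobs(n_samples = 6, cells_each = 10)
  d <- build_design(b$X, NULL, character(0), b$y, sample_ids = b$sample)
  cfg <- tiny_model_config(n_outer_folds = 5L, holdout_fraction = 0)
  expect_error(nested_cv_fit(d, cfg), "fewer")
})

test_that("interaction columns elevate the scores of the interaction-expanded populations", {
  # with latent-by-sex columns the model can condition on sex, so the
  # female-stratum expanded clusters should score higher than in a model
  # fitted without them
  elev <- sapply(1:2, function(s) {
    sim <- simulate_dataset(sim_preset("interaction", seed = s,
                                       cells_per_cluster = 20))
    m <- sim$meta
    sapply(c(TRUE, FALSE), function(use_inter) {
      fit <- phenoscore(sim$expression, m, outcome = "condition",
                        sample_col = "subject_id",
                        covariates = "sex",
                        interactions = if (use_inter) "sex" else NULL,
                        harmonize_vars = "batch",
                        model = model_config(n_outer_folds = 3,
                                             n_inner_folds = 2,
                                             n_repeats = 1, search_budget = 4,
                                             depth_range = c(2L, 4L),
                                             holdout_fraction = 0, seed = s))
      mean(fit$scores$score[m$sex == "F" & m$cluster %in% c("B", "J")])
    })
  })
  expect_gte(mean(elev[1, ]), mean(elev[2, ]))
})

test_that("the gradient-boosting family fits, predicts, and attributes on the margin scale", {
  skip_if_not_installed("xgboost")
  b <- make_blobs(n_samples = 10, cells_each = 30, sep = 3)
  d <- build_design(b$X, NULL, character(0), b$y, sample_ids = b$sample)
  m <- phenoscore:::fit_forest(d$values, d$y,
                               list(num.trees = 100, max.depth = 3,
                                    min.node.size = 5, mtry = 2),
                               seed = 1, family = "gradient_boosting")
  prob <- predict(m, d$values)
  expect_equal(unname(rowSums(prob)), rep(1, nrow(prob)), tolerance = 1e-9)
  expect_gt(phenoscore:::auc_binary(prob[, "dis"], b$y == "dis"), 0.9)
  sh <- tree_shap(m, d$values[1:5, ])
  expect_equal(sh$scale, "margin")
  # margin additivity: base + sum(phi) = logit of the predicted probability
  margin <- sh$base[2] + apply(sh$values[, , 2], 1, sum)
  expect_equal(unname(margin), unname(qlogis(prob[1:5, 2])), tolerance = 1e-5)
})
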