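test_that("weight normalization keeps squared amplitudes summing to 1", {
  cfg <- sim_config(variance_explained = c(cluster = 0.4, condition = 0.2,
                                           subject = 0.1, batch = 0.1))
  expect_equal(sum(cfg$factor_weights^2) + cfg$noise_weight^2, 1,
               tolerance = 1e-12)
  cfg2 <- sim_config(variance_explained = c(cluster = 0.5),
                     interaction_ve = c("condition:sex" = 0.2))
  expect_equal(sum(cfg2$factor_weights^2) + sum(cfg2$interaction_weights^2) +
                 cfg2$noise_weight^2, 1, tolerance = 1e-12)
})

test_that("config validation rejects bad inputs", {
  expect_error(sim_config(expanded = c(A = 0)), "positive")
  expect_error(sim_config(expanded = c(Z = 2)), "subset")
  expect_error(sim_config(cluster_props = c(0.5, 0.4),
                          clusters = c("A", "B")), "sum to 1")
  expect_error(sim_config(clusters = c("A", "B"),
                          cluster_props = c(1, 0), expanded = c(B = 2)),
               "baseline proportion")
  expect_error(sim_config(variance_explained = c(cluster = 0.9,
                                                 condition = 0.2)),
               "more than 1")
  expect_error(sim_preset("nope"), "dataset1")
})

test_that("abundance plan realizes fold changes with fixed subject totals", {
  # unit fold change: disease counts identical to control counts
  cfg0 <- tiny_config(expanded = c(A = 1), poisson_jitter = FALSE)
  plan0 <- plan_abundance(cfg0)
  counts <- tapply(plan0$n_cells, list(plan0$condition, plan0$cluster), mean)
  expect_equal(counts["disease", ], counts["control", ])

  # single cluster at p = 0.1 and fold 3: 100 -> 300, shift of 200 cells
  cfg <- sim_config(n_subjects_per_group = 2, cells_per_cluster = 100,
                    clusters = LETTERS[1:10], expanded = c(A = 3),
                    poisson_jitter = FALSE)
  plan <- plan_abundance(cfg)
  a <- plan[plan$cluster == "A", ]
  expect_equal(unique(a$n_cells[a$condition == "control"]), 100L)
  expect_equal(unique(a$n_cells[a$condition == "disease"]), 300L)
  expect_equal(300L - 100L, 200L)
  # subject totals stay constant
  totals <- tapply(plan$n_cells, plan$subject, sum)
  expect_true(all(abs(totals - 1000) <= 5))
})

test_that("dataset1 preset realizes a proportion fold change of about 3", {
  ratios <- sapply(1:10, function(s) {
    plan <- plan_abundance(sim_preset("dataset1", seed = s,
                                      cells_per_cluster = 50))
    tot <- tapply(plan$n_cells, plan$subject, sum)
    prop <- plan$n_cells / tot[plan$subject]
    sapply(c("A", "J"), function(cl) {
      x <- plan$cluster == cl
      mean(prop[x & plan$condition == "disease"]) /
        mean(prop[x & plan$condition == "control"])
    })
  })
  expect_true(all(abs(rowMeans(ratios) - 3) < 0.3))
})

test_that("interaction preset puts rare clusters at exactly 5% of control cells", {
  cfg_i <- sim_preset("interaction")
  cfg_i$poisson_jitter <- FALSE
  plan <- plan_abundance(cfg_i)
  ctrl <- plan[plan$condition == "control", ]
  tot <- tapply(ctrl$n_cells, ctrl$subject, sum)
  for (cl in c("I", "J")) {
    prop <- as.numeric(ctrl$n_cells[ctrl$cluster == cl] / tot)
    expect_equal(prop, rep(0.05, length(prop)))
  }
  # shifts confined to female disease subjects
  sim <- simulate_dataset(sim_preset("interaction", cells_per_cluster = 20))
  expect_true(all(sim$meta$sex[sim$meta$truth] == "F"))
  expect_true(all(sim$meta$condition[sim$meta$truth] == "disease"))
  expect_setequal(unique(sim$meta$cluster[sim$meta$truth]),
                  c("A", "B", "I", "J"))
  expect_true(all(sim$meta$truth_direction[sim$meta$truth &
                                             sim$meta$cluster %in% c("B", "J")] == 1))
  expect_true(all(sim$meta$truth_direction[sim$meta$truth &
                                             sim$meta$cluster %in% c("A", "I")] == -1))
})

test_that("preset parameters match the study design", {
  expect_equal(sim_preset("dataset1")$n_subjects_per_group, 15L)
  expect_equal(sim_preset("dataset1")$cells_per_cluster, 100L)
  expect_equal(unname(sim_preset("dataset1")$expanded), c(3, 3))
  expect_equal(unname(sim_preset("dataset2")$expanded), c(0.1, 0.1))
  expect_true(sim_preset("dataset2")$fold_is_increment)
  expect_equal(unname(sim_preset("interaction")$cluster_props[c("I", "J")]),
               c(0.05, 0.05))
})

test_that("factor signals are standardized with level-dependent means", {
  # balanced two-point mixture with means (0, 10), small noise: after
  # standardization the group means sit near -1 and +1
  labels <- rep(c("lo", "hi"), each = 500)
  s <- sample_factor_signal(labels, c(lo = 0, hi = 10), sd = 0.1, seed = 7)
  expect_equal(mean(s), 0, tolerance = 1e-12)
  expect_equal(sd(s), 1, tolerance = 1e-12)
  expect_equal(mean(s[labels == "lo"]), -1, tolerance = 0.05)
  expect_equal(mean(s[labels == "hi"]), 1, tolerance = 0.05)

  # degenerate single-level factor: standardized pure noise
  s1 <- sample_factor_signal(rep("only", 200), c(only = 5), sd = 1, seed = 1)
  expect_equal(c(mean(s1), sd(s1)), c(0, 1), tolerance = 1e-12)

  # determinism under a fixed seed
  expect_identical(sample_factor_signal(labels, c(lo = 0, hi = 1), 1, seed = 3),
                   sample_factor_signal(labels, c(lo = 0, hi = 1), 1, seed = 3))

  expect_error(sample_factor_signal("x", c(x = 1)), "fewer than 2")
  expect_error(sample_factor_signal(rep("a", 10), c(a = 2), sd = 0,
                                    name = "flat"), "flat")
})

test_that("composed features recover the designed variance fractions", {
  set.seed(11)
  n <- 10000
  sig <- list(disease = as.numeric(scale(rnorm(n))),
              noise = as.numeric(scale(rnorm(n))))
  x <- compose_feature(sig, c(disease = 0.6, noise = 0.8))
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(var(x), 1, tolerance = 1e-9)
  r2 <- summary(lm(x ~ sig$disease))$r.squared
  expect_lt(abs(r2 - 0.36), 0.03)

  # single-factor identity up to rescaling
  x1 <- compose_feature(sig, c(disease = 1))
  expect_equal(x1, sig$disease, tolerance = 1e-12)

  expect_error(compose_feature(sig, c(disease = -1)), "non-negative")
  expect_error(compose_feature(list(a = 1:3, b = 1:4), c(a = 1, b = 1)),
               "equal length")
})

test_that("pure interaction terms are uncorrelated with their main effects", {
  set.seed(5)
  n <- 10000
  sx <- as.numeric(scale(sample(c(-1, 1), n, replace = TRUE)))
  sd_ <- as.numeric(scale(sample(c(0, 1), n, replace = TRUE)))
  sig <- list(disease = sd_, sex = sx, noise = as.numeric(scale(rnorm(n))))
  x <- compose_feature(sig, c("disease:sex" = 0.8, noise = 0.6))
  expect_gt(abs(cor(x, sd_ * sx)), 0.7)
  expect_lt(abs(cor(x, sd_)), 0.05)
  expect_lt(abs(cor(x, sx)), 0.05)
})

test_that("simulated datasets have standardized features and consistent metadata", {
  cfg <- sim_config(n_subjects_per_group = 3, cells_per_cluster = 60,
                    clusters = c("A", "B", "C"), expanded = c(A = 2),
                    n_features = 6, seed = 2)
  sim <- simulate_dataset(cfg)
  expect_false(anyDuplicated(sim$meta$cell_id) > 0)
  # every subject belongs to exactly one condition group
  expect_true(all(rowSums(table(sim$meta$subject_id,
                                sim$meta$condition) > 0) == 1))
  expect_true(all(abs(colMeans(sim$expression)) < 0.05))
  expect_true(all(abs(apply(sim$expression, 2, var) - 1) < 0.05))
  # truth flags: expanded cluster in disease subjects only
  expect_true(all(sim$meta$cluster[sim$meta$truth] == "A"))
  expect_true(all(sim$meta$condition[sim$meta$truth] == "disease"))
})

test_that("simulation is reproducible and stable under added features", {
  cfg <- tiny_config(seed = 9)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$meta, b$meta)
  # adding features does not perturb earlier columns
  cfg_more <- tiny_config(seed = 9, n_features = 12L)
  c <- simulate_dataset(cfg_more)
  expect_identical(a$expression, c$expression[, 1:8])
})

test_that("pure-noise features carry no cluster structure", {
  cfg <- tiny_config(variance_explained = c(cluster = 0),
                     cells_per_cluster = 40L, n_features = 6L)
  sim <- simulate_dataset(cfg)
  sil <- oracle_silhouette(sim$meta$cluster, sim$expression)
  expect_lt(abs(mean(sil)), 0.05)
})
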