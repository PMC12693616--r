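# Hold-one-stressor-out splitting, SMOTE, model fitting/evaluation, feature
# curves and the importance-intersection core set. Sized for speed: signal
# structure, not scale, is what these check.

rf_meta <- function(stressors = c("heat", "salt", "cold"), n_bp = 2, k = 3) {
  do.call(rbind, lapply(seq_along(stressors), function(i) {
    do.call(rbind, lapply(seq_len(n_bp), function(b) {
      bp <- sprintf("BP_%s_%d", stressors[i], b)
      data.frame(sample_id = sprintf("%s_s%d", bp, seq_len(2 * k)),
                 bioproject = bp,
                 treatment = c(rep("control", k), rep(stressors[i], k)),
                 stringsAsFactors = FALSE)
    }))
  }))
}

separable_data <- function(meta, n_genes = 60, n_signal = 8, shift = 3,
                           seed = 21) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * nrow(meta), 5), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              meta$sample_id))
  stressed <- meta$treatment != "control"
  m[seq_len(n_signal), stressed] <- m[seq_len(n_signal), stressed] + shift
  m
}

test_that("hold-one-stressor-out split isolates all of a stressor's BioProjects", {
  meta <- rf_meta()
  sp <- split_hold_one_stressor(meta, "salt")
  test_bp <- unique(meta$bioproject[meta$sample_id %in% sp$test])
  expect_true(all(grepl("salt", test_bp)))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), meta$sample_id)
  # across all stressors each sample is held out exactly once
  held <- unlist(lapply(c("heat", "salt", "cold"),
                        function(s) split_hold_one_stressor(meta, s)$test))
  expect_identical(sort(held), sort(meta$sample_id))
  expect_error(split_hold_one_stressor(meta, "flooding"), "not present")
})

test_that("SMOTE balances classes, keeps originals and interpolates within the minority", {
  set.seed(1)
  x <- matrix(rnorm(120 * 2), ncol = 2,
              dimnames = list(sprintf("s%03d", 1:120), c("f1", "f2")))
  y <- factor(rep(c("control", "stress"), c(30, 90)),
              levels = c("control", "stress"))
  x[y == "control", ] <- x[y == "control", ] + 10
  bal <- corestress:::with_seed(5, smote_balance(x, y))
  expect_equal(as.numeric(table(bal$y)), c(90, 90))
  expect_identical(bal$x[1:120, ], x)
  synth <- bal$x[-(1:120), ]
  rng <- apply(x[y == "control", ], 2, range)
  expect_true(all(synth[, 1] >= rng[1, 1] & synth[, 1] <= rng[2, 1]))
  expect_true(all(synth[, 2] >= rng[1, 2] & synth[, 2] <= rng[2, 2]))
  # minority synthetic points stay near the minority cloud, far from majority
  expect_true(all(rowMeans(synth) > 5))

  balanced <- smote_balance(x, factor(rep(c("control", "stress"), 60)))
  expect_equal(nrow(balanced$x), 120)
  expect_error(smote_balance(x, factor(rep("stress", 120))), "both classes")
  expect_warning(
    smote_balance(x[1:20, ], factor(rep(c("control", "stress"), c(3, 17)))),
    "reducing k")
})

test_that("a separable planted signal gives AUC 1 and normalized importances", {
  meta <- rf_meta()
  m <- separable_data(meta)
  labels <- stress_labels(meta)
  sp <- split_hold_one_stressor(meta, "cold")
  x <- t(m)
  res <- tune_fit_evaluate(x[sp$train, ], labels[sp$train],
                           x[sp$test, ], labels[sp$test],
                           rf_config(n_candidates = 2,
                                     importance_num_trees = 300),
                           seed = 4)
  expect_equal(res$metrics[["auc"]], 1)
  expect_true(all(res$metrics >= 0 & res$metrics <= 1))
  expect_true(all(res$importance >= 0))
  expect_equal(sum(res$importance), 1, tolerance = 1e-8)
})

test_that("permuted labels give chance-level AUC", {
  set.seed(8)
  n <- 200
  x <- matrix(rnorm(n * 30), n,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("g%02d", 1:30)))
  y <- factor(rep(c("control", "stress"), each = n / 2),
              levels = c("control", "stress"))
  y <- sample(y)  # break any association
  res <- tune_fit_evaluate(x[1:100, ], y[1:100], x[101:200, ], y[101:200],
                           rf_config(n_candidates = 2,
                                     importance_num_trees = 200),
                           seed = 6)
  expect_gt(res$metrics[["auc"]], 0.35)
  expect_lt(res$metrics[["auc"]], 0.65)
})

test_that("feature curve has one row per valid size and finds a small optimum on concentrated signal", {
  meta <- rf_meta(n_bp = 2, k = 4)
  m <- separable_data(meta, n_genes = 120, n_signal = 10, seed = 31)
  labels <- stress_labels(meta)
  sp <- split_hold_one_stressor(meta, "heat")
  x <- t(m)
  res <- tune_fit_evaluate(x[sp$train, ], labels[sp$train],
                           x[sp$test, ], labels[sp$test],
                           rf_config(n_candidates = 2,
                                     importance_num_trees = 500),
                           seed = 9)
  expect_warning(
    curve <- iterative_feature_selection(
      x[sp$train, ], labels[sp$train], x[sp$test, ], labels[sp$test],
      res$importance, res$hyperparameters,
      subset_sizes = c(10, 25, 50, 120, 500), seed = 10),
    "skipping")
  expect_identical(curve$size, c(10, 25, 50, 120))
  expect_gte(curve$auc[curve$size == 10],
             curve$auc[curve$size == 120] - 0.02)
  best <- max(curve$auc)
  expect_equal(attr(curve, "optimum_size"),
               min(curve$size[curve$auc >= best - 0.01]))
})

test_that("core intersection honours top_k, tie-breaking and partial inputs", {
  imp1 <- c(a = 0.5, b = 0.3, c = 0.15, d = 0.05)
  res <- list(heat = list(importance = imp1),
              cold = list(importance = imp1),
              salt = list(importance = imp1))
  expect_identical(rf_core_genes(res, top_k = 2), c("a", "b"))
  res$salt$importance <- c(a = 0.05, b = 0.15, c = 0.3, d = 0.5)
  expect_identical(rf_core_genes(res, top_k = 2), character(0))
  # ties at the boundary break by gene id
  tied <- list(x = list(importance = c(b = 0.4, a = 0.4, c = 0.2)),
               y = list(importance = c(b = 0.4, a = 0.4, c = 0.2)))
  expect_identical(rf_core_genes(tied, top_k = 1), "a")
  expect_error(rf_core_genes(res[1:2], stressors = c("heat", "cold", "salt")),
               "missing models")
  expect_identical(
    rf_core_genes(res[1:2], top_k = 2,
                  stressors = c("heat", "cold", "salt"), allow_partial = TRUE),
    c("a", "b"))
})

test_that("direction annotation counts up-and-down genes in both directions", {
  calls <- data.frame(
    gene = c("g1", "g1", "g2", "g3"),
    bioproject = c("BP1", "BP2", "BP1", "BP1"),
    stressor = c("drought", "cold", "heat", "heat"),
    tn_ratio = 1,
    call = c("up", "down", "up", "none"),
    stringsAsFactors = FALSE)
  ann <- annotate_direction(c("g1", "g2", "g3"), calls)
  expect_equal(unname(ann$counts), c(2, 1, 1))
  expect_identical(ann$up, c("g1", "g2"))
  expect_identical(ann$down, "g1")
  expect_identical(ann$none, "g3")
  expect_gte(sum(ann$counts), 3)
})

test_that("test samples never influence fitting (leakage check)", {
  meta <- rf_meta(stressors = c("heat", "salt"), n_bp = 2, k = 3)
  m <- separable_data(meta, n_genes = 40, n_signal = 5, seed = 41)
  labels <- stress_labels(meta)
  sp <- split_hold_one_stressor(meta, "salt")
  x <- t(m)
  cfg <- rf_config(n_candidates = 2, importance_num_trees = 200)
  r1 <- tune_fit_evaluate(x[sp$train, ], labels[sp$train],
                          x[sp$test, ], labels[sp$test], cfg, seed = 3)
  # garbage test data: fitted model and importances must be unchanged
  x_garbage <- x[sp$test, ]
  x_garbage[] <- 0
  r2 <- tune_fit_evaluate(x[sp$train, ], labels[sp$train],
                          x_garbage, labels[sp$test], cfg, seed = 3)
  expect_identical(r1$importance, r2$importance)
  expect_identical(r1$hyperparameters, r2$hyperparameters)
})
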