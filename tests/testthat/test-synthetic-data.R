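# Generator: determinism, bookkeeping, planted-effect magnitudes, degenerate
# configurations and recovery scoring.

test_that("generator is bit-reproducible and respects configured counts", {
  cfg <- sim_config(n_genes = 400, n_core_up = 50, n_core_down = 20,
                    n_specific_per_stressor = 5, samples_per_group = 3,
                    n_tfs = 5, targets_per_tf = 4, n_coexpr_blocks = 2,
                    block_size = 10, seed = 1)
  sim1 <- generate_compendium(cfg)
  sim2 <- generate_compendium(cfg)
  expect_identical(sim1$expr, sim2$expr)
  expect_identical(sim1$meta, sim2$meta)
  expect_identical(sim1$truth, sim2$truth)

  expect_length(sim1$truth$core_up, 50)
  expect_length(sim1$truth$core_down, 20)
  expect_length(unlist(sim1$truth$specific), 6 * 5)
  expect_true(all(sim1$expr >= 0))
  expect_identical(sort(colnames(sim1$expr)), sort(sim1$meta$sample_id))
})

test_that("planted gene classes are pairwise disjoint and inside the universe", {
  sim <- generate_compendium(sim_config(n_genes = 500, seed = 7,
                                        n_specific_per_stressor = 10,
                                        n_tfs = 10, targets_per_tf = 5,
                                        n_coexpr_blocks = 2, block_size = 15,
                                        samples_per_group = 3))
  tr <- sim$truth
  expect_length(intersect(tr$core_up, tr$core_down), 0)
  all_specific <- unlist(tr$specific)
  expect_false(anyDuplicated(all_specific) > 0)
  expect_length(intersect(all_specific, union(tr$core_up, tr$core_down)), 0)
  expect_length(intersect(tr$tf_catalog$gene_id,
                          c(tr$core_up, tr$core_down, all_specific)), 0)
  expect_true(all(unlist(tr$regulator_targets) %in% rownames(sim$expr)))
})

test_that("every BioProject carries both control and stressed samples", {
  sim <- generate_compendium(sim_config(n_genes = 300, samples_per_group = 2,
                                        n_specific_per_stressor = 5,
                                        n_tfs = 5, targets_per_tf = 4,
                                        n_coexpr_blocks = 2, block_size = 10,
                                        seed = 3))
  by_bp <- split(sim$meta$treatment, sim$meta$bioproject)
  expect_true(all(vapply(by_bp, function(x) "control" %in% x, logical(1))))
  expect_true(all(vapply(by_bp, function(x) any(x != "control"), logical(1))))
})

test_that("realized per-experiment TN-ratio of core-up genes matches the planted fold change", {
  sim <- generate_compendium(sim_config(core_fold_change = 4, noise_cv = 0.1,
                                        samples_per_group = 6, seed = 11))
  bps <- unique(sim$meta$bioproject)
  ratios <- unlist(lapply(bps, function(bp) {
    compute_tn_ratio(sim$expr, sim$meta, bp)[sim$truth$core_up]
  }))
  expect_gt(median(ratios), 3)
  expect_lt(median(ratios), 5)
})

test_that("all randomness off collapses every gene to identical samples", {
  cfg <- sim_config(n_genes = 150, batch_shift_sd = 0, batch_scale_sd = 0,
                    noise_cv = 0, core_fold_change = 1,
                    specific_fold_change = 1, tf_activity_sd = 0,
                    block_factor_sd = 0, samples_per_group = 2,
                    n_core_up = 10, n_core_down = 5,
                    n_specific_per_stressor = 2, n_tfs = 4,
                    targets_per_tf = 3, n_coexpr_blocks = 1, block_size = 5,
                    seed = 5)
  sim <- generate_compendium(cfg)
  ranges <- apply(sim$expr, 1, function(x) diff(range(x)))
  expect_true(all(ranges < 1e-12))
})

test_that("realized group-mean fold change converges to the configured value", {
  sim <- generate_compendium(sim_config(n_genes = 400, samples_per_group = 50,
                                        n_bioprojects_per_stressor = 3,
                                        n_specific_per_stressor = 5,
                                        n_tfs = 5, targets_per_tf = 4,
                                        n_coexpr_blocks = 2, block_size = 10,
                                        core_fold_change = 4, seed = 13))
  meta <- sim$meta
  bp <- meta$bioproject[1]
  ctrl <- meta$sample_id[meta$bioproject == bp & meta$treatment == "control"]
  str <- meta$sample_id[meta$bioproject == bp & meta$treatment != "control"]
  fc <- rowMeans(sim$expr[sim$truth$core_up, str]) /
    rowMeans(sim$expr[sim$truth$core_up, ctrl])
  expect_lt(abs(median(fc) - 4), 0.4)
})

test_that("score_recovery implements precision/recall/F1 with the empty-set conventions", {
  u <- letters[1:10]
  perfect <- score_recovery(c("a", "b"), c("a", "b"), u)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  empty <- score_recovery(character(0), c("a", "b"), u)
  expect_equal(empty$precision, 0)
  expect_equal(empty$recall, 0)

  half <- score_recovery(c("a", "b", "c", "d"), c("a", "b", "e", "f"), u)
  expect_equal(half$precision, 0.5)
  expect_equal(half$recall, 0.5)
  expect_equal(half$f1, 0.5)

  expect_error(score_recovery("z", "a", u), "universe")
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_genes = 100, n_core_up = 80, n_core_down = 40),
               "configuration error")
  expect_error(sim_config(core_fold_change = 0.5), "fold changes")
  expect_error(sim_config(n_core_up = 0), "positive")
  expect_error(sim_config(tf_regulation_strength = 1.5), "tf_regulation_strength")
})

test_that("compendium writers round-trip through TSV", {
  sim <- generate_compendium(sim_config(n_genes = 150, samples_per_group = 2,
                                        n_core_up = 10, n_core_down = 5,
                                        n_specific_per_stressor = 2,
                                        n_tfs = 4, targets_per_tf = 3,
                                        n_coexpr_blocks = 1, block_size = 5,
                                        seed = 2))
  dir <- withr::local_tempdir()
  write_compendium(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "expression.tsv", "metadata.tsv", "tf_catalog.tsv", "ground_truth.json")))))
  m <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(m, sim$expr, tolerance = 1e-12)
  meta <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_identical(meta$sample_id, sim$meta$sample_id)
})
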