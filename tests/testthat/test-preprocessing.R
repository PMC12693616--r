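# Preprocessing: log transform, variance filter, batch adjustment, PCA,
# z-scoring and the treatment dendrogram.

test_that("log transform is log2(x + 1) and rejects negatives", {
  m <- toy_tpm(c(0, 1, 7, 3), 2, 2)
  lt <- log_transform(m)
  expect_equal(as.numeric(lt), c(0, 1, 3, 2))
  m[1, 1] <- -1
  expect_error(log_transform(m), "non-negative")
})

test_that("zero-variance filter keeps order and flags the degenerate case", {
  m <- toy_tpm(c(3.2, 1, 3.2, 1, 3.2, 2), 2, 3)
  f <- filter_zero_variance(m)
  expect_identical(rownames(f), "g02")
  expect_warning(filter_zero_variance(toy_tpm(rep(1, 6), 2, 3)),
                 "zero variance")
})

test_that("batch adjustment is the identity for a single batch", {
  set.seed(1)
  m <- toy_tpm(rnorm(60, 5), 10, 6)
  out <- combat_adjust(m, rep("A", 6))
  expect_equal(out, m, tolerance = 1e-8)
})

test_that("batch adjustment removes a planted pure location shift", {
  set.seed(2)
  n_g <- 100; n_s <- 30
  m <- matrix(rnorm(n_g * 2 * n_s, mean = 6, sd = 0.5), n_g,
              dimnames = list(sprintf("g%03d", 1:n_g),
                              sprintf("s%02d", 1:(2 * n_s))))
  batch <- rep(c("A", "B"), each = n_s)
  m[, batch == "B"] <- m[, batch == "B"] + 5
  before <- mean(abs(rowMeans(m[, batch == "B"]) - rowMeans(m[, batch == "A"])))
  out <- combat_adjust(m, batch)
  after <- mean(abs(rowMeans(out[, batch == "B"]) - rowMeans(out[, batch == "A"])))
  expect_gt(before, 4.9)
  expect_lt(after, 0.1)
})

test_that("batch adjustment equalizes a planted 3x variance ratio", {
  set.seed(3)
  n_g <- 200; n_s <- 50
  sds <- exp(rnorm(n_g, 0, 0.5))  # heterogeneous per-gene noise scales
  base <- matrix(rnorm(n_g * 2 * n_s), n_g) * sds
  batch <- rep(c("A", "B"), each = n_s)
  base[, batch == "B"] <- base[, batch == "B"] * sqrt(3)
  m <- base + 6
  dimnames(m) <- list(sprintf("g%03d", 1:n_g), sprintf("s%03d", 1:(2 * n_s)))
  out <- combat_adjust(m, batch)
  before <- apply(m[, batch == "B"], 1, var) / apply(m[, batch == "A"], 1, var)
  ratio <- apply(out[, batch == "B"], 1, var) / apply(out[, batch == "A"], 1, var)
  expect_gt(median(before), 2.5)
  # empirical-Bayes shrinkage leaves a sampling-noise residual on the scale
  # estimates, so the post-adjustment ratios centre tightly on 1 without
  # collapsing exactly
  expect_gt(median(ratio), 0.9)
  expect_lt(median(ratio), 1.1)
  expect_gte(mean(ratio >= 2 / 3 & ratio <= 1.5), 0.95)
})

test_that("batches with a single sample are rejected by name", {
  m <- toy_tpm(rnorm(30), 10, 3)
  expect_error(combat_adjust(m, c("A", "A", "B")), "B")
})

test_that("PCA variance fractions are invariant to sample duplication and sum to <= 1", {
  set.seed(4)
  m <- toy_tpm(rnorm(80, 5), 20, 4)
  p1 <- pca_expression(m, 2)
  m2 <- cbind(m, m); colnames(m2) <- sprintf("s%02d", 1:8)
  p2 <- pca_expression(m2, 2)
  expect_equal(p1$variance_explained, p2$variance_explained, tolerance = 1e-8)
  expect_lte(sum(p1$variance_explained), 1 + 1e-12)
  expect_error(pca_expression(m, 10), "n_components")
})

test_that("a near rank-1 matrix concentrates variance on PC1", {
  set.seed(5)
  load <- rnorm(30)
  sig <- rnorm(8)
  m <- outer(load, sig) + matrix(rnorm(240, sd = 1e-6), 30)
  dimnames(m) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:8))
  p <- pca_expression(m, 2)
  expect_gt(p$variance_explained[1], 0.99)
  # sign convention: largest-magnitude loading positive
  expect_gt(p$loadings[which.max(abs(p$loadings[, 1])), 1], 0)
})

test_that("z-scoring uses the population-sd convention and is idempotent", {
  m <- matrix(c(1, 2, 3, 4, 0, 8), nrow = 2, byrow = TRUE,
              dimnames = list(c("g01", "g02"), c("s01", "s02", "s03")))
  z <- zscore_genes(m)
  expect_equal(unname(z[1, ]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_true(all(abs(rowMeans(z)) < 1e-10))
  expect_equal(zscore_genes(z), z, tolerance = 1e-10)
  expect_error(zscore_genes(toy_tpm(rep(2, 6), 2, 3)), "zero-variance")
})

test_that("treatment dendrogram merges identical profiles first and has n-1 merges", {
  meta <- data.frame(sample_id = sprintf("s%d", 1:6),
                     bioproject = "BP01",
                     treatment = rep(c("a", "b", "c"), each = 2),
                     stringsAsFactors = FALSE)
  prof <- c(1, -1, 0.5)
  m <- rbind(g1 = c(1, 1, 1, 1, -2, -2),
             g2 = c(-1, -1, -1, -1, 2, 2))
  colnames(m) <- meta$sample_id
  # treatments a and b share the same mean profile; c is different
  tree <- treatment_dendrogram(zscore_genes(m), meta)
  expect_equal(length(tree$height), 2)  # n_treatments - 1 merges
  first <- sort(tree$labels[-tree$merge[1, ]])
  expect_identical(first, c("a", "b"))
  expect_equal(tree$height[1], 0, tolerance = 1e-12)
  expect_true(!is.unsorted(tree$height))
})

test_that("batch-driven variance on PC1 drops after adjustment", {
  sim <- generate_compendium(sim_config(n_genes = 300, batch_shift_sd = 2,
                                        core_fold_change = 1,
                                        specific_fold_change = 1,
                                        n_specific_per_stressor = 5,
                                        n_tfs = 5, targets_per_tf = 4,
                                        n_coexpr_blocks = 2, block_size = 10,
                                        samples_per_group = 3, seed = 9))
  lg <- filter_zero_variance(log_transform(sim$expr))
  corr <- combat_adjust(lg, sim$meta)
  r2 <- function(m) {
    pc1 <- pca_expression(m, 1)$scores[, 1]
    summary(lm(pc1 ~ factor(sim$meta$bioproject)))$r.squared
  }
  expect_lt(r2(corr), r2(lg))
})
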