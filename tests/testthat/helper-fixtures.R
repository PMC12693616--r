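# Deterministic fixtures and independent oracles shared across test files.
# Oracles re-derive expected results by a different route (explicit per-gene
# loops, direct enumeration) than the vectorized implementation they check.

# Small TPM matrix with named dims.
toy_tpm <- function(values, n_genes, n_samples,
                    genes = sprintf("g%02d", seq_len(n_genes)),
                    samples = sprintf("s%02d", seq_len(n_samples))) {
  matrix(values, nrow = n_genes, ncol = n_samples,
         dimnames = list(genes, samples))
}

# Random toy compendium (<= 50 genes, <= 4 BioProjects per stressor) for the
# brute-force set-operations equivalence checks.
random_toy_compendium <- function(seed) {
  set.seed(seed)
  n_genes <- sample(5:50, 1)
  stressors <- sort(sample(c("heat", "cold", "salt", "drought"),
                           sample(2:3, 1)))
  meta <- NULL
  bp_i <- 0
  for (s in stressors) {
    for (b in seq_len(sample(1:4, 1))) {
      bp_i <- bp_i + 1
      bp <- sprintf("BP%02d", bp_i)
      nc <- sample(1:3, 1)
      ns <- sample(1:3, 1)
      meta <- rbind(meta, data.frame(
        sample_id = c(sprintf("%s_c%d", bp, seq_len(nc)),
                      sprintf("%s_t%d", bp, seq_len(ns))),
        bioproject = bp,
        treatment = c(rep("control", nc), rep(s, ns)),
        stringsAsFactors = FALSE))
    }
  }
  m <- matrix(round(stats::rexp(n_genes * nrow(meta)) * 50, 2),
              nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              meta$sample_id))
  list(expr = m, meta = meta)
}

# Brute-force re-derivation of every TN-ratio call and of the per-stressor,
# core and specific sets, via explicit loops over genes and experiments.
oracle_gene_sets <- function(m, meta, up = 2, down = 0.5) {
  genes <- rownames(m)
  stressors <- sort(unique(meta$treatment[meta$treatment != "control"]))
  calls <- list()
  per_str <- list()
  for (s in stressors) {
    up_set <- character(0)
    down_set <- character(0)
    for (bp in sort(unique(meta$bioproject[meta$treatment == s]))) {
      cs <- meta$sample_id[meta$bioproject == bp & meta$treatment == "control"]
      ts <- meta$sample_id[meta$bioproject == bp & meta$treatment == s]
      for (g in genes) {
        r <- (mean(m[g, ts]) + 1) / (mean(m[g, cs]) + 1)
        call <- if (r > up) "up" else if (r < down) "down" else "none"
        calls[[paste(g, bp, s, sep = "|")]] <- call
        if (call == "up") up_set <- union(up_set, g)
        if (call == "down") down_set <- union(down_set, g)
      }
    }
    per_str[[s]] <- list(up = sort(up_set), down = sort(down_set))
  }
  core_up <- genes[vapply(genes, function(g) {
    all(vapply(stressors, function(s) g %in% per_str[[s]]$up, logical(1)))
  }, logical(1))]
  core_down <- genes[vapply(genes, function(g) {
    all(vapply(stressors, function(s) g %in% per_str[[s]]$down, logical(1)))
  }, logical(1))]
  specific <- lapply(stressors, function(s) {
    de_here <- union(per_str[[s]]$up, per_str[[s]]$down)
    only <- de_here[vapply(de_here, function(g) {
      !any(vapply(setdiff(stressors, s), function(o) {
        g %in% union(per_str[[o]]$up, per_str[[o]]$down)
      }, logical(1)))
    }, logical(1))]
    list(up = sort(intersect(only, per_str[[s]]$up)),
         down = sort(intersect(only, per_str[[s]]$down)))
  })
  names(specific) <- stressors
  list(calls = calls, sets = per_str,
       core_up = sort(core_up), core_down = sort(core_down),
       specific = specific)
}

# Direct hypergeometric tail enumeration via binomial-coefficient ratios
# (independent of phyper).
oracle_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  ks <- a:min(a + b, a + c)
  if (length(ks) == 0 || a > min(a + b, a + c)) return(if (a == 0) 1 else 0)
  sum(choose(a + c, ks) * choose(b + d, a + b - ks)) / choose(n, a + b)
}

# Plain Rand index of two labelings.
rand_index <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(same_a == same_b)
}

# Two planted co-expression blocks driven by independent latent factors.
two_block_matrix <- function(n_per_block = 30, n_samples = 40,
                             noise_sd = 0.25, seed = 10) {
  set.seed(seed)
  f1 <- stats::rnorm(n_samples)
  f2 <- stats::rnorm(n_samples)
  mk <- function(f, n) {
    t(vapply(seq_len(n), function(i) f + stats::rnorm(n_samples, sd = noise_sd),
             numeric(n_samples)))
  }
  m <- rbind(mk(f1, n_per_block), mk(f2, n_per_block))
  dimnames(m) <- list(sprintf("g%03d", seq_len(2 * n_per_block)),
                      sprintf("s%02d", seq_len(n_samples)))
  m
}

# Exact rejection probability of the one-sided hypergeometric test at level
# alpha, for given universe/set/annotation sizes (computed from the exact
# null distribution, independently of any simulation).
exact_attained_level <- function(alpha, n_univ, n_set, n_ann) {
  x <- 0:min(n_set, n_ann)
  p <- stats::phyper(x - 1, n_ann, n_univ - n_ann, n_set, lower.tail = FALSE)
  reject <- x[p < alpha]
  if (length(reject) == 0) return(0)
  stats::phyper(min(reject) - 1, n_ann, n_univ - n_ann, n_set,
                lower.tail = FALSE)
}

# Binomial 95% CI check for an observed rate around a nominal level.
within_binomial_ci <- function(rate, nominal, n) {
  half <- 1.96 * sqrt(nominal * (1 - nominal) / n)
  rate >= nominal - half && rate <= nominal + half
}
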