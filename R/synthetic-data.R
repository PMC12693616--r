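# Synthetic multi-BioProject stress compendium generator with planted ground
# truth: core genes responsive under every stressor, stress-specific genes
# responsive under exactly one, TF->target regulatory structure, co-expressed
# gene blocks, and per-BioProject batch distortions on the log scale.

#' Default stressor labels
#' @export
default_stressors <- function() {
  c("cold", "drought", "flooding", "heat", "low_nitrogen", "salt")
}

#' Simulation configuration for [generate_compendium()]
#'
#' The expression model works on the log2 scale. Each gene g has a baseline
#' log2 abundance b_g ~ Normal(5, 2), giving the heavy-tailed TPM dynamic
#' range typical of bulk RNA-seq. Planted effects are multiplicative on the
#' TPM scale (additive in log2): core genes gain +/- log2(core_fold_change)
#' in every stressed sample, stress-specific genes only in stressed samples
#' of their own stressor. Every BioProject b contributes an additive log2
#' shift gamma_b ~ Normal(0, batch_shift_sd) to all its samples and a
#' multiplicative factor delta_b = exp(Normal(0, batch_scale_sd)) that scales
#' the stochastic deviation of its samples -- exactly the location/scale
#' batch model that parametric empirical-Bayes adjustment assumes.
#' Biological noise is log-normal with coefficient of variation `noise_cv`.
#' TF regulators additionally carry a per-sample activity component with sd
#' `tf_activity_sd` (log2 units); each of their targets receives
#' `tf_regulation_strength` times the regulator's centred noise-free profile.
#' Genes in a co-expression block share a latent factor with sd
#' `block_factor_sd`.
#'
#' @param n_genes Total number of genes.
#' @param n_bioprojects_per_stressor Independent experiments per stressor
#'   (>= 3 mirrors a meta-analysis inclusion rule of at least three
#'   independent BioProjects per stressor).
#' @param stressors Character vector of stressor labels.
#' @param samples_per_group Samples in each of the control and stressed
#'   groups of every BioProject.
#' @param n_core_up,n_core_down Number of planted core up-/downregulated genes.
#' @param n_specific_per_stressor Planted specific genes per stressor (first
#'   half up-, second half downregulated).
#' @param core_fold_change,specific_fold_change Multiplicative effect on the
#'   stressed-group mean TPM (>= 1; 1 disables the effect).
#' @param batch_shift_sd Sd of the per-BioProject additive log2 shift.
#' @param batch_scale_sd Sd (log scale) of the per-BioProject noise scaling.
#' @param noise_cv Biological coefficient of variation of the log-normal noise.
#' @param n_tfs Number of transcription factors.
#' @param targets_per_tf Regulated targets per TF (disjoint across TFs).
#' @param tf_regulation_strength Weight in [0, 1] of the regulator profile
#'   copied into each target.
#' @param tf_activity_sd Sd (log2) of per-sample TF activity.
#' @param n_coexpr_blocks,block_size Number and size of co-expressed blocks.
#' @param block_factor_sd Sd (log2) of the shared block latent factor.
#' @param specific_n_bioprojects In how many of its stressor's BioProjects a
#'   specific gene is planted (default: all of them).
#' @param n_tissues 1 or 2; with 2, alternate BioProjects are assigned a
#'   second tissue whose samples get a global additive log2 separation of
#'   `tissue_shift`, letting ordination reproduce tissue-first grouping.
#' @param tissue_shift Log2 separation between the two tissues.
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_bioprojects_per_stressor = 3,
                       stressors = default_stressors(),
                       samples_per_group = 6,
                       n_core_up = 50,
                       n_core_down = 20,
                       n_specific_per_stressor = 25,
                       core_fold_change = 4,
                       specific_fold_change = 4,
                       batch_shift_sd = 1,
                       batch_scale_sd = 0.2,
                       noise_cv = 0.2,
                       n_tfs = 20,
                       targets_per_tf = 10,
                       tf_regulation_strength = 0.8,
                       tf_activity_sd = 1,
                       n_coexpr_blocks = 5,
                       block_size = 30,
                       block_factor_sd = 1,
                       specific_n_bioprojects = n_bioprojects_per_stressor,
                       n_tissues = 1,
                       tissue_shift = 3,
                       seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_genes = n_genes,
              n_bioprojects_per_stressor = n_bioprojects_per_stressor,
              samples_per_group = samples_per_group,
              n_core_up = n_core_up, n_core_down = n_core_down,
              n_specific_per_stressor = n_specific_per_stressor,
              n_tfs = n_tfs, targets_per_tf = targets_per_tf,
              n_coexpr_blocks = n_coexpr_blocks, block_size = block_size)
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("configuration error: all counts must be positive integers",
         call. = FALSE)
  }
  if (length(stressors) < 1 || anyDuplicated(stressors) > 0) {
    stop("configuration error: stressors must be unique labels", call. = FALSE)
  }
  if (core_fold_change < 1 || specific_fold_change < 1) {
    stop("configuration error: fold changes must be >= 1", call. = FALSE)
  }
  if (tf_regulation_strength < 0 || tf_regulation_strength > 1) {
    stop("configuration error: tf_regulation_strength must be in [0, 1]",
         call. = FALSE)
  }
  if (any(c(batch_shift_sd, batch_scale_sd, noise_cv, tf_activity_sd,
            block_factor_sd) < 0)) {
    stop("configuration error: sds and noise_cv must be >= 0", call. = FALSE)
  }
  if (!n_tissues %in% c(1, 2)) {
    stop("configuration error: n_tissues must be 1 or 2", call. = FALSE)
  }
  if (specific_n_bioprojects < 1 ||
      specific_n_bioprojects > n_bioprojects_per_stressor) {
    stop("configuration error: specific_n_bioprojects out of range",
         call. = FALSE)
  }
  planted <- n_core_up + n_core_down +
    length(stressors) * n_specific_per_stressor + n_tfs
  if (planted > n_genes) {
    stop("configuration error: planted genes (", planted,
         ") exceed n_genes (", n_genes, ")", call. = FALSE)
  }
  if (planted + n_tfs * targets_per_tf + n_coexpr_blocks * block_size > n_genes) {
    stop("configuration error: planted genes + TF targets + co-expression ",
         "blocks exceed n_genes", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic stress expression compendium
#'
#' See [sim_config()] for the generative model. Output TPM values are the
#' back-transformed (2^x) log2 expression values and therefore non-negative.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `expr` (genes x samples TPM matrix), `meta`
#'   (sample metadata data.frame), `truth` (planted ground truth: core_up,
#'   core_down, specific, specific_direction, tf_catalog, regulator_targets,
#'   coexpr_block) and `config`.
#' @export
generate_compendium <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  with_seed(cfg$seed, {
    gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))

    # --- role assignment -------------------------------------------------
    pool <- sample(gene_ids)
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      sort(out)
    }
    core_up <- take(cfg$n_core_up)
    core_down <- take(cfg$n_core_down)
    specific <- lapply(cfg$stressors, function(s) take(cfg$n_specific_per_stressor))
    names(specific) <- cfg$stressors
    tfs <- take(cfg$n_tfs)
    regulator_targets <- lapply(seq_len(cfg$n_tfs),
                                function(i) take(cfg$targets_per_tf))
    names(regulator_targets) <- tfs
    blocks <- lapply(seq_len(cfg$n_coexpr_blocks), function(i) take(cfg$block_size))
    coexpr_block <- stats::setNames(
      rep(sprintf("block%02d", seq_len(cfg$n_coexpr_blocks)),
          each = cfg$block_size),
      unlist(blocks))

    specific_direction <- stats::setNames(
      unlist(lapply(specific, function(g) {
        n_up <- ceiling(length(g) / 2)
        c(rep("up", n_up), rep("down", length(g) - n_up))
      })),
      unlist(specific))

    families <- c("AP2/ERF-ERF", "NAC", "bZIP", "HSF", "C2C2-CO-like",
                  "MYB", "WRKY", "Orphans")
    tf_catalog <- data.frame(
      gene_id = tfs,
      family = sample(families, cfg$n_tfs, replace = TRUE),
      stringsAsFactors = FALSE)

    # --- design ----------------------------------------------------------
    n_bp <- length(cfg$stressors) * cfg$n_bioprojects_per_stressor
    bp_ids <- sprintf("BP%02d", seq_len(n_bp))
    bp_stressor <- rep(cfg$stressors, each = cfg$n_bioprojects_per_stressor)
    bp_tissue <- if (cfg$n_tissues == 2) {
      c("leaf", "root")[(seq_len(n_bp) %% 2) + 1]
    } else rep("leaf", n_bp)

    k <- cfg$samples_per_group
    meta <- do.call(rbind, lapply(seq_len(n_bp), function(i) {
      data.frame(
        sample_id = c(sprintf("%s_c%02d", bp_ids[i], seq_len(k)),
                      sprintf("%s_t%02d", bp_ids[i], seq_len(k))),
        bioproject = bp_ids[i],
        treatment = c(rep("control", k), rep(bp_stressor[i], k)),
        tissue = bp_tissue[i],
        genotype = "B73",
        stringsAsFactors = FALSE)
    }))
    rownames(meta) <- NULL
    n_samples <- nrow(meta)
    stressed <- meta$treatment != "control"

    # which BioProjects carry each stressor's specific genes
    specific_bps <- lapply(cfg$stressors, function(s) {
      own <- bp_ids[bp_stressor == s]
      if (cfg$specific_n_bioprojects >= length(own)) own
      else sort(sample(own, cfg$specific_n_bioprojects))
    })
    names(specific_bps) <- cfg$stressors

    # --- noise-free log2 profiles ---------------------------------------
    baseline <- stats::rnorm(cfg$n_genes, mean = 5, sd = 2)
    names(baseline) <- gene_ids
    L <- matrix(baseline, nrow = cfg$n_genes, ncol = n_samples,
                dimnames = list(gene_ids, meta$sample_id))

    lfc_core <- log2(cfg$core_fold_change)
    L[core_up, stressed] <- L[core_up, stressed] + lfc_core
    L[core_down, stressed] <- L[core_down, stressed] - lfc_core

    lfc_spec <- log2(cfg$specific_fold_change)
    for (s in cfg$stressors) {
      cols <- stressed & meta$bioproject %in% specific_bps[[s]] &
        meta$treatment == s
      g <- specific[[s]]
      dir_up <- g[specific_direction[g] == "up"]
      dir_dn <- g[specific_direction[g] == "down"]
      if (length(dir_up)) L[dir_up, cols] <- L[dir_up, cols] + lfc_spec
      if (length(dir_dn)) L[dir_dn, cols] <- L[dir_dn, cols] - lfc_spec
    }

    if (cfg$n_tissues == 2) {
      root_cols <- meta$tissue == "root"
      L[, root_cols] <- L[, root_cols] + cfg$tissue_shift
    }

    act <- matrix(stats::rnorm(cfg$n_tfs * n_samples, sd = cfg$tf_activity_sd),
                  nrow = cfg$n_tfs,
                  dimnames = list(tfs, meta$sample_id))
    L[tfs, ] <- L[tfs, ] + act

    fac <- matrix(stats::rnorm(cfg$n_coexpr_blocks * n_samples,
                               sd = cfg$block_factor_sd),
                  nrow = cfg$n_coexpr_blocks)
    for (b in seq_len(cfg$n_coexpr_blocks)) {
      L[blocks[[b]], ] <- sweep(L[blocks[[b]], , drop = FALSE], 2,
                                fac[b, ], "+")
    }

    for (tf in tfs) {
      tgt <- regulator_targets[[tf]]
      centred <- L[tf, ] - mean(L[tf, ])
      L[tgt, ] <- sweep(L[tgt, , drop = FALSE], 2,
                        cfg$tf_regulation_strength * centred, "+")
    }

    # --- batch distortion + noise ---------------------------------------
    gamma <- stats::rnorm(n_bp, sd = cfg$batch_shift_sd)
    delta <- exp(stats::rnorm(n_bp, sd = cfg$batch_scale_sd))
    bp_of_sample <- match(meta$bioproject, bp_ids)

    sigma_log2 <- sqrt(log1p(cfg$noise_cv^2)) / log(2)
    eps <- matrix(stats::rnorm(cfg$n_genes * n_samples), nrow = cfg$n_genes)

    L <- sweep(L, 2, gamma[bp_of_sample], "+") +
      sweep(eps * sigma_log2, 2, delta[bp_of_sample], "*")

    expr <- 2^L

    truth <- list(core_up = core_up,
                  core_down = core_down,
                  specific = specific,
                  specific_direction = specific_direction,
                  tf_catalog = tf_catalog,
                  regulator_targets = regulator_targets,
                  coexpr_block = coexpr_block)
    list(expr = expr, meta = meta, truth = truth, config = cfg)
  })
}

#' Precision / recall / F1 of a predicted gene set against planted truth
#'
#' @param predicted,truth Character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe Character vector of all candidate gene ids.
#' @return List with precision, recall, f1, tp, fp, fn. An empty prediction
#'   has precision 0 when the truth set is non-empty.
#' @export
score_recovery <- function(predicted, truth, universe) {
  predicted <- unique(as.character(predicted))
  truth <- unique(as.character(truth))
  if (!all(predicted %in% universe) || !all(truth %in% universe)) {
    stop("predicted and truth sets must be subsets of the universe",
         call. = FALSE)
  }
  tp <- length(intersect(predicted, truth))
  fp <- length(predicted) - tp
  fn <- length(truth) - tp
  precision <- if (length(predicted) == 0) {
    if (length(truth) == 0) 1 else 0
  } else tp / length(predicted)
  recall <- if (length(truth) == 0) 1 else tp / length(truth)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}

#' Write a simulated compendium to a directory
#'
#' Writes expression.tsv, metadata.tsv, tf_catalog.tsv and ground_truth.json.
#'
#' @param sim Output of [generate_compendium()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_compendium <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expr, file.path(dir, "expression.tsv"))
  write_metadata(sim$meta, file.path(dir, "metadata.tsv"))
  utils::write.table(sim$truth$tf_catalog, file.path(dir, "tf_catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$specific_direction <- as.list(truth$specific_direction)
  truth$coexpr_block <- as.list(truth$coexpr_block)
  truth$tf_catalog <- NULL
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}
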