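# End-to-end orchestration: preprocess -> set-operations DE -> random forest
# -> co-expression -> enrichment -> GRN, from one config, with provenance
# records next to every stage's outputs.

#' Pipeline configuration
#'
#' @param expr Path to the TPM expression TSV.
#' @param meta Path to the sample metadata TSV.
#' @param tf_catalog Optional path to the TF catalog TSV (needed by the
#'   enrich and grn stages).
#' @param gmt Optional path to a GMT annotation file for term enrichment.
#' @param out_dir Output directory.
#' @param seed Global seed; stages derive their own via [derive_seed()].
#' @param stages Stages to run, subset of preprocess, de, rf, coexpress,
#'   enrich, grn. Upstream results a stage needs are computed in memory even
#'   when their stage is toggled off; only toggled stages write outputs.
#' @param up_threshold,down_threshold TN-ratio call thresholds.
#' @param min_experiments Experiments required for per-stressor membership.
#' @param soft_power Co-expression soft-thresholding power.
#' @param min_module_size Minimum module size.
#' @param hub_percentile Hub kME percentile.
#' @param rf [rf_config()] for the random-forest stage.
#' @param grn_n_trees Trees per GRN target forest.
#' @param grn_n_reps Dunnett repetitions.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expr, meta, tf_catalog = NULL, gmt = NULL,
                            out_dir = "corestress_out", seed = 1,
                            stages = c("preprocess", "de", "rf", "coexpress",
                                       "enrich", "grn"),
                            up_threshold = 2, down_threshold = 0.5,
                            min_experiments = 1,
                            soft_power = 9, min_module_size = 20,
                            hub_percentile = 0.95,
                            rf = rf_config(),
                            grn_n_trees = 100, grn_n_reps = 5000) {
  known <- c("preprocess", "de", "rf", "coexpress", "enrich", "grn")
  if (!all(stages %in% known)) {
    stop("unknown stages: ", paste(setdiff(stages, known), collapse = ", "),
         call. = FALSE)
  }
  for (p in c(expr, meta, tf_catalog, gmt)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  structure(as.list(environment())[names(formals(pipeline_config))],
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level YAML keys map to [pipeline_config()] arguments; an `rf` mapping
#' is passed to [rf_config()].
#'
#' @param path YAML file path.
#' @return `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$rf)) y$rf <- do.call(rf_config, y$rf)
  do.call(pipeline_config, y)
}

#' @keywords internal
write_provenance <- function(out_dir, stage, params, seed, inputs) {
  rec <- list(stage = stage, params = params, seed = seed,
              input_md5 = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(rec, file.path(out_dir,
                                      paste0("provenance_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order and writes all
#' artifacts (corrected matrix, TN-ratio calls and gene-set files,
#' per-stressor model summaries, module/kME/hub tables, enrichment tables,
#' GRN edge list and Dunnett comparisons) under `config$out_dir`, each stage
#' with a JSON provenance record. A stage failure aborts with a stage-named
#' error; outputs of completed stages are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(cfg$expr, cfg$meta, cfg$tf_catalog, cfg$gmt)
  log_path <- file.path(cfg$out_dir, "run.log")
  note <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  stage_guard <- function(stage, code) {
    tryCatch(force(code),
             error = function(e) {
               stop("stage '", stage, "' failed: ", conditionMessage(e),
                    call. = FALSE)
             })
  }
  on <- function(stage) stage %in% cfg$stages
  results <- list()

  expr <- read_expression(cfg$expr)
  meta <- read_metadata(cfg$meta)

  # preprocess (always computed; corrected matrix feeds rf/coexpress/grn)
  corrected <- stage_guard("preprocess", {
    logm <- filter_zero_variance(log_transform(expr))
    out <- if (length(unique(meta$bioproject)) > 1) {
      combat_adjust(logm, meta)
    } else logm
    if (on("preprocess")) {
      write_expression(out, file.path(cfg$out_dir, "corrected.tsv"))
      pca <- pca_expression(out, n_components = min(2, min(dim(out))))
      utils::write.table(
        data.frame(sample_id = rownames(pca$scores), pca$scores,
                   check.names = FALSE),
        file.path(cfg$out_dir, "pca_scores.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_provenance(cfg$out_dir, "preprocess", list(), cfg$seed, inputs)
      note("preprocess: ", nrow(out), " genes x ", ncol(out), " samples")
    }
    out
  })
  results$corrected <- corrected

  # set-operations DE (cheap; rf/grn reuse its gene sets)
  de <- stage_guard("de", {
    res <- derive_stress_gene_sets(expr, meta, cfg$up_threshold,
                                   cfg$down_threshold, cfg$min_experiments)
    if (on("de")) {
      utils::write.table(res$calls, file.path(cfg$out_dir, "tn_ratio_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_gene_set(res$core_up, file.path(cfg$out_dir, "core_up.txt"))
      write_gene_set(res$core_down, file.path(cfg$out_dir, "core_down.txt"))
      for (s in names(res$specific)) {
        for (d in c("up", "down")) {
          write_gene_set(res$specific[[s]][[d]],
                         file.path(cfg$out_dir,
                                   sprintf("specific_%s_%s.txt", s, d)))
        }
      }
      write_provenance(cfg$out_dir, "de",
                       list(up_threshold = cfg$up_threshold,
                            down_threshold = cfg$down_threshold,
                            min_experiments = cfg$min_experiments),
                       cfg$seed, inputs)
      note("de: ", length(res$core_up), " core up, ",
           length(res$core_down), " core down")
    }
    res
  })
  results$de <- de
  setops_core <- union(de$core_up, de$core_down)

  rf_core <- character(0)
  if (on("rf")) {
    results$rf <- stage_guard("rf", {
      models <- run_rf_models(corrected, meta, cfg$rf,
                              seed = derive_seed(cfg$seed, "rf"))
      rf_core <- rf_core_genes(models, top_k = cfg$rf$top_k)
      write_gene_set(rf_core, file.path(cfg$out_dir, "rf_core.txt"))
      for (s in names(models)) {
        r <- models[[s]]
        jsonlite::write_json(
          list(held_out_stressor = s,
               hyperparameters = r$hyperparameters,
               metrics = as.list(r$metrics),
               cv_auc = r$cv_auc),
          file.path(cfg$out_dir, sprintf("rf_%s.json", s)),
          auto_unbox = TRUE, pretty = TRUE, digits = NA)
      }
      imp <- do.call(cbind, lapply(models, `[[`, "importance"))
      utils::write.table(
        data.frame(gene_id = rownames(imp), imp, check.names = FALSE),
        file.path(cfg$out_dir, "rf_importance.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      combined <- sort(union(setops_core, rf_core))
      utils::write.table(
        data.frame(gene_id = combined,
                   set_operations = combined %in% setops_core,
                   random_forest = combined %in% rf_core),
        file.path(cfg$out_dir, "combined_core.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_provenance(cfg$out_dir, "rf", list(top_k = cfg$rf$top_k),
                       derive_seed(cfg$seed, "rf"), inputs)
      note("rf: core intersection of ", length(models), " models = ",
           length(rf_core), " genes; combined core = ", length(combined))
      models
    })
  }
  combined_core <- sort(union(setops_core, rf_core))

  if (on("coexpress")) {
    results$coexpression <- stage_guard("coexpress", {
      adj <- build_adjacency(corrected, power = cfg$soft_power)
      modules <- detect_modules(adj, min_module_size = cfg$min_module_size)
      em <- module_eigengenes(corrected, modules)
      kme <- compute_kme(corrected, em)
      hubs <- hub_genes(kme, modules, percentile = cfg$hub_percentile)
      utils::write.table(
        data.frame(gene_id = names(modules), module = as.character(modules)),
        file.path(cfg$out_dir, "modules.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(gene_id = rownames(kme), kme, check.names = FALSE),
        file.path(cfg$out_dir, "kme.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_gene_set(hubs$hubs, file.path(cfg$out_dir, "hubs.txt"))
      universe <- rownames(corrected)
      menr <- module_set_enrichment(modules,
                                    intersect(combined_core, universe),
                                    universe)
      utils::write.table(menr, file.path(cfg$out_dir, "module_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      hub_fisher <- fisher_enrichment(hubs$hubs,
                                      intersect(combined_core, universe),
                                      universe)
      jsonlite::write_json(hub_fisher,
                           file.path(cfg$out_dir, "hub_core_fisher.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      write_provenance(cfg$out_dir, "coexpress",
                       list(soft_power = cfg$soft_power,
                            min_module_size = cfg$min_module_size,
                            hub_percentile = cfg$hub_percentile),
                       cfg$seed, inputs)
      note("coexpress: ", length(setdiff(unique(modules), "M0")),
           " modules, ", length(hubs$hubs), " hubs (threshold ",
           signif(hubs$threshold, 3), ")")
      list(modules = modules, eigengenes = em, kme = kme, hubs = hubs,
           module_enrichment = menr)
    })
  }

  tf_cat <- if (!is.null(cfg$tf_catalog)) read_tf_catalog(cfg$tf_catalog)
  enriched_families <- character(0)
  if (on("enrich")) {
    results$enrichment <- stage_guard("enrich", {
      universe <- rownames(corrected)
      out <- list()
      if (!is.null(tf_cat)) {
        sets <- c(list(core_up = de$core_up, core_down = de$core_down),
                  stats::setNames(
                    unlist(lapply(names(de$specific), function(s) {
                      list(de$specific[[s]]$up, de$specific[[s]]$down)
                    }), recursive = FALSE),
                    unlist(lapply(names(de$specific), function(s) {
                      paste0("specific_", s, c("_up", "_down"))
                    }))))
        sets <- lapply(sets, intersect, y = universe)
        tfe <- tf_family_enrichment(sets, tf_cat, universe)
        utils::write.table(tfe, file.path(cfg$out_dir, "tf_enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        core_rows <- tfe$set %in% c("core_up", "core_down") &
          tfe$family != "all_TFs" & tfe$class %in% c("enriched", "near")
        enriched_families <- sort(unique(tfe$family[core_rows]))
        out$tf <- tfe
      }
      if (!is.null(cfg$gmt)) {
        ann <- read_gmt(cfg$gmt)
        for (set_name in c("core_up", "core_down")) {
          te <- term_enrichment(intersect(de[[set_name]], universe),
                                ann, universe)
          utils::write.table(
            te, file.path(cfg$out_dir,
                          sprintf("term_enrichment_%s.tsv", set_name)),
            sep = "\t", quote = FALSE, row.names = FALSE)
          out[[paste0("terms_", set_name)]] <- te
        }
      }
      write_provenance(cfg$out_dir, "enrich", list(), cfg$seed, inputs)
      note("enrich: ", length(enriched_families),
           " enriched/near TF families in core sets")
      out
    })
  }

  if (on("grn")) {
    results$grn <- stage_guard("grn", {
      if (is.null(tf_cat)) stop("grn stage needs a TF catalog")
      edges <- infer_grn(corrected, tf_cat$gene_id,
                         seed = derive_seed(cfg$seed, "grn"),
                         n_trees = cfg$grn_n_trees)
      utils::write.table(edges, file.path(cfg$out_dir, "grn_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      # focal TFs: core TFs from enriched/near families when available,
      # otherwise all core TFs, otherwise all TFs
      tfs_present <- intersect(tf_cat$gene_id, rownames(corrected))
      focal <- intersect(combined_core, tfs_present)
      if (length(enriched_families) > 0) {
        fam_tfs <- tf_cat$gene_id[tf_cat$family %in% enriched_families]
        focal2 <- intersect(focal, fam_tfs)
        if (length(focal2) > 0) focal <- focal2
      }
      if (length(focal) == 0) focal <- tfs_present
      group_sets <- c(list(core = combined_core),
                      stats::setNames(
                        lapply(de$specific, function(s) union(s$up, s$down)),
                        paste0("specific_", names(de$specific))))
      dn <- grn_group_comparison(edges, focal, group_sets,
                                 n_reps = cfg$grn_n_reps,
                                 seed = derive_seed(cfg$seed, "dunnett"))
      jsonlite::write_json(dn, file.path(cfg$out_dir, "dunnett.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           dataframe = "rows")
      write_provenance(cfg$out_dir, "grn",
                       list(n_trees = cfg$grn_n_trees,
                            n_reps = cfg$grn_n_reps,
                            focal_tfs = focal),
                       derive_seed(cfg$seed, "grn"), inputs)
      note("grn: ", nrow(edges), " edges; ",
           sum(dn$significant), " significant group comparisons")
      list(edges = edges, dunnett = dn, focal_tfs = focal)
    })
  }

  invisible(results)
}
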