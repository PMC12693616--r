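# Per-experiment TN-ratio differential expression and the set operations
# deriving core and stress-specific gene sets.
#
# The TN-ratio for one experiment (BioProject) is
#   (mean stressed TPM + 1) / (mean control TPM + 1),
# computed on raw TPM (the ratio is within-experiment, so batch effects
# cancel). A gene with ratio > 2 is called up, < 0.5 down (strict
# inequalities), otherwise none.

#' Per-gene TN-ratio for one BioProject
#'
#' @param m Raw (untransformed) TPM matrix, genes x samples.
#' @param meta Sample metadata (sample_id, bioproject, treatment).
#' @param bioproject BioProject label to evaluate.
#' @param stressor Optional stressor label; when given, only that stressor's
#'   samples form the stressed group (relevant if one BioProject assayed
#'   several stressors). Default pools all non-control samples.
#' @return Named numeric vector of TN-ratios (always > 0 thanks to the
#'   pseudocount).
#' @export
compute_tn_ratio <- function(m, meta, bioproject, stressor = NULL) {
  assert_expression_matrix(m, non_negative = TRUE)
  meta <- align_metadata(meta, m)
  in_bp <- meta$bioproject == bioproject
  if (!any(in_bp)) stop("unknown BioProject: ", bioproject, call. = FALSE)
  ctrl <- in_bp & meta$treatment == "control"
  str <- if (is.null(stressor)) {
    in_bp & meta$treatment != "control"
  } else {
    in_bp & meta$treatment == stressor
  }
  if (!any(ctrl)) {
    stop("BioProject ", bioproject, " has no control samples", call. = FALSE)
  }
  if (!any(str)) {
    stop("BioProject ", bioproject, " has no stressed samples",
         if (!is.null(stressor)) paste0(" for stressor ", stressor),
         call. = FALSE)
  }
  (rowMeans(m[, str, drop = FALSE]) + 1) /
    (rowMeans(m[, ctrl, drop = FALSE]) + 1)
}

#' Classify TN-ratios into up / down / none calls
#'
#' @param ratios Positive numeric vector of TN-ratios.
#' @param up_threshold Ratio above which a gene is called up (strict).
#' @param down_threshold Ratio below which a gene is called down (strict).
#' @return Character vector of calls in {"up", "down", "none"}, named like
#'   `ratios`.
#' @export
classify_de <- function(ratios, up_threshold = 2, down_threshold = 0.5) {
  if (down_threshold >= up_threshold) {
    stop("configuration error: down_threshold must be < up_threshold",
         call. = FALSE)
  }
  if (any(ratios <= 0)) stop("TN-ratios must be > 0", call. = FALSE)
  out <- rep("none", length(ratios))
  out[ratios > up_threshold] <- "up"
  out[ratios < down_threshold] <- "down"
  names(out) <- names(ratios)
  out
}

#' TN-ratio calls for every (gene, experiment) pair
#'
#' One experiment is one (BioProject, stressor) combination; for the common
#' case of single-stressor BioProjects this is one row block per BioProject.
#'
#' @inheritParams compute_tn_ratio
#' @inheritParams classify_de
#' @return data.frame with columns gene, bioproject, stressor, tn_ratio, call.
#' @export
de_call_table <- function(m, meta, up_threshold = 2, down_threshold = 0.5) {
  assert_expression_matrix(m, non_negative = TRUE)
  meta <- align_metadata(meta, m)
  design <- unique(meta[meta$treatment != "control",
                        c("bioproject", "treatment")])
  if (nrow(design) == 0) stop("no stressed samples in metadata", call. = FALSE)
  out <- lapply(seq_len(nrow(design)), function(i) {
    bp <- design$bioproject[i]
    s <- design$treatment[i]
    r <- compute_tn_ratio(m, meta, bp, stressor = s)
    data.frame(gene = names(r), bioproject = bp, stressor = s,
               tn_ratio = unname(r),
               call = classify_de(r, up_threshold, down_threshold),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "up_threshold") <- up_threshold
  attr(res, "down_threshold") <- down_threshold
  res
}

#' Per-stressor union of DE calls across experiments
#'
#' A gene enters a stressor's up set if it is called up in at least one of
#' that stressor's experiments (analogously for down); a gene may appear in
#' both directions via different experiments.
#'
#' @param calls Output of [de_call_table()].
#' @param min_experiments Minimum number of supporting experiments for set
#'   membership (default 1).
#' @return Named list: per stressor a list with `up` and `down` character
#'   vectors (sorted).
#' @export
stressor_union <- function(calls, min_experiments = 1) {
  stopifnot(all(c("gene", "stressor", "call") %in% names(calls)))
  stressors <- sort(unique(calls$stressor))
  out <- lapply(stressors, function(s) {
    sub <- calls[calls$stressor == s, , drop = FALSE]
    pick <- function(direction) {
      hits <- sub[sub$call == direction, "gene"]
      counts <- table(hits)
      sort(as.character(names(counts)[counts >= min_experiments]))
    }
    list(up = pick("up"), down = pick("down"))
  })
  names(out) <- stressors
  out
}

#' Core gene sets by intersection across all stressors
#'
#' @param sets Output of [stressor_union()].
#' @return List with `core_up` and `core_down`: genes in every stressor's
#'   up (respectively down) set.
#' @export
core_genes_set_ops <- function(sets) {
  if (length(sets) == 0) stop("no stressor sets", call. = FALSE)
  list(core_up = sort(Reduce(intersect, lapply(sets, `[[`, "up"))),
       core_down = sort(Reduce(intersect, lapply(sets, `[[`, "down"))))
}

#' Stress-specific gene sets
#'
#' A gene is specific to stressor s iff it is differentially expressed
#' (up or down, in >= 1 experiment) under s and under no other stressor.
#'
#' @param sets Output of [stressor_union()].
#' @return Named list: per stressor a list with `up` and `down` character
#'   vectors. Sets are pairwise disjoint across stressors by construction.
#' @export
stress_specific_genes <- function(sets) {
  any_de <- lapply(sets, function(s) union(s$up, s$down))
  counts <- table(unlist(any_de))
  once <- names(counts)[counts == 1]
  out <- lapply(sets, function(s) {
    de <- union(s$up, s$down)
    mine <- intersect(de, once)
    list(up = sort(intersect(mine, s$up)),
         down = sort(intersect(mine, s$down)))
  })
  names(out) <- names(sets)
  out
}

#' Full set-operations workflow from raw TPM
#'
#' Convenience wrapper: calls, per-stressor unions, core intersections and
#' stress-specific sets in one pass.
#'
#' @inheritParams de_call_table
#' @inheritParams stressor_union
#' @return List with `calls`, `sets`, `core_up`, `core_down`, `specific`.
#' @export
derive_stress_gene_sets <- function(m, meta, up_threshold = 2,
                                    down_threshold = 0.5,
                                    min_experiments = 1) {
  calls <- de_call_table(m, meta, up_threshold, down_threshold)
  sets <- stressor_union(calls, min_experiments)
  core <- core_genes_set_ops(sets)
  list(calls = calls, sets = sets,
       core_up = core$core_up, core_down = core$core_down,
       specific = stress_specific_genes(sets))
}
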