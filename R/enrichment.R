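# One-sided Fisher's exact overlap tests with Benjamini-Hochberg FDR,
# applied to TFs overall, TF families, arbitrary gene->term annotations
# ("classic" per-term testing, no ontology decorrelation) and co-expression
# modules.

#' One-sided Fisher's exact test from 2x2 counts
#'
#' The p-value is the upper hypergeometric tail P(X >= a) for the observed
#' overlap count a. The odds ratio is the sample odds ratio (a d)/(b c)
#' (Inf when b or c is 0 and the numerator is positive; NaN for 0/0).
#'
#' @param a Overlap count (in both sets).
#' @param b In set A only.
#' @param c In set B only.
#' @param d In neither.
#' @return List with a, b, c, d, odds_ratio and p.
#' @export
fisher_enrichment_counts <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  p <- stats::phyper(a - 1, m = a + c, n = b + d, k = a + b,
                     lower.tail = FALSE)
  num <- a * d
  den <- b * c
  odds <- if (den > 0) num / den else if (num > 0) Inf else NaN
  list(a = a, b = b, c = c, d = d, odds_ratio = odds, p = p)
}

#' One-sided Fisher's exact overlap test for two gene sets
#'
#' Tests whether `set_a` contains more of `set_b` than expected by chance
#' over `universe` (alternative: greater).
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all genes (non-empty).
#' @return As [fisher_enrichment_counts()].
#' @export
fisher_enrichment <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("gene sets must be subsets of the universe", call. = FALSE)
  }
  a <- length(intersect(set_a, set_b))
  fisher_enrichment_counts(a,
                           length(set_a) - a,
                           length(set_b) - a,
                           length(universe) - length(set_a) - length(set_b) + a)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; q equals p for a single
#' test and when all p are tied.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Numeric vector of q-values, same order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' @keywords internal
enrichment_class <- function(q) {
  ifelse(q < 0.05, "enriched", ifelse(q < 0.1, "near", "ns"))
}

#' TF and TF-family enrichment of gene sets
#'
#' For each gene set, a pooled test of all TFs (row `family = "all_TFs"`,
#' FDR-corrected separately, i.e. q = p) plus one one-sided Fisher test per
#' TF family, FDR-corrected within the gene set across families. Families
#' with no members in the universe are retained with a = 0. Upregulated and
#' downregulated sets should be supplied as separate entries of
#' `gene_sets`.
#'
#' @param gene_sets Named list of character vectors (e.g. core_up,
#'   core_down, specific sets).
#' @param tf_catalog data.frame with columns gene_id and family.
#' @param universe All genes under consideration.
#' @return data.frame with columns set, family, a, b, c, d, odds_ratio, p,
#'   q, class (enriched: q < 0.05; near: 0.05 <= q < 0.1; ns otherwise).
#' @export
tf_family_enrichment <- function(gene_sets, tf_catalog, universe) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  universe <- unique(universe)
  cat_in <- tf_catalog[tf_catalog$gene_id %in% universe, , drop = FALSE]
  families <- sort(unique(tf_catalog$family))
  out <- lapply(names(gene_sets), function(set_name) {
    gs <- intersect(unique(gene_sets[[set_name]]), universe)
    pooled <- fisher_enrichment(gs, unique(cat_in$gene_id), universe)
    pooled_row <- data.frame(set = set_name, family = "all_TFs",
                             a = pooled$a, b = pooled$b, c = pooled$c,
                             d = pooled$d, odds_ratio = pooled$odds_ratio,
                             p = pooled$p, q = pooled$p,
                             stringsAsFactors = FALSE)
    fam_rows <- do.call(rbind, lapply(families, function(fam) {
      members <- unique(cat_in$gene_id[cat_in$family == fam])
      fr <- fisher_enrichment(gs, members, universe)
      data.frame(set = set_name, family = fam, a = fr$a, b = fr$b,
                 c = fr$c, d = fr$d, odds_ratio = fr$odds_ratio, p = fr$p,
                 q = NA_real_, stringsAsFactors = FALSE)
    }))
    fam_rows$q <- fdr_adjust(fam_rows$p)
    rbind(pooled_row, fam_rows)
  })
  res <- do.call(rbind, out)
  res$class <- enrichment_class(res$q)
  rownames(res) <- NULL
  res
}

#' Per-term gene-set enrichment ("classic" algorithm)
#'
#' Independent one-sided Fisher test per term against a pre-propagated
#' gene -> term annotation map, FDR across terms. Terms with no annotated
#' genes in the universe are skipped with a warning.
#'
#' @param gene_set Character vector, subset of `universe`.
#' @param annotations Named list term -> character vector of annotated genes
#'   (e.g. from [read_gmt()]).
#' @param universe All genes under consideration.
#' @return data.frame with columns term, a, b, c, d, odds_ratio, p, q,
#'   class, sorted by p.
#' @export
term_enrichment <- function(gene_set, annotations, universe) {
  stopifnot(is.list(annotations), !is.null(names(annotations)))
  universe <- unique(universe)
  gs <- intersect(unique(gene_set), universe)
  ann <- lapply(annotations, function(g) intersect(unique(g), universe))
  empty <- vapply(ann, length, integer(1)) == 0
  if (any(empty)) {
    warning("skipping terms with no annotated genes in the universe: ",
            paste(utils::head(names(ann)[empty], 5), collapse = ", "),
            if (sum(empty) > 5) " ...")
    ann <- ann[!empty]
  }
  if (length(ann) == 0) stop("no usable terms", call. = FALSE)
  rows <- lapply(names(ann), function(term) {
    fr <- fisher_enrichment(gs, ann[[term]], universe)
    data.frame(term = term, a = fr$a, b = fr$b, c = fr$c, d = fr$d,
               odds_ratio = fr$odds_ratio, p = fr$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p)
  out$class <- enrichment_class(out$q)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
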