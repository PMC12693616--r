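# Weighted co-expression network: soft-thresholded correlation adjacency,
# topological overlap, average-linkage tree with a static height cut for
# module detection, module eigengenes, kME module membership and
# percentile-based hub genes. Modules are labelled M1.. by decreasing size;
# M0 collects unassigned background genes.

#' Soft-thresholded co-expression adjacency
#'
#' Unsigned: |cor|^power. Signed: ((1 + cor)/2)^power. Diagonal is 1.
#'
#' @param m Batch-corrected log2 expression, genes x samples (>= 3 samples),
#'   no zero-variance genes.
#' @param power Soft-thresholding exponent (default 9).
#' @param type "unsigned" (default) or "signed".
#' @return Symmetric gene x gene adjacency matrix with entries in [0, 1].
#' @export
build_adjacency <- function(m, power = 9, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  assert_expression_matrix(m)
  if (ncol(m) < 3) stop("need >= 3 samples", call. = FALSE)
  if (any(row_vars(m) == 0)) {
    stop("zero-variance genes present; filter before network construction",
         call. = FALSE)
  }
  cc <- stats::cor(t(m))
  a <- if (type == "unsigned") abs(cc)^power else ((1 + cc) / 2)^power
  a[a > 1] <- 1
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' Standard unsigned TOM: shared-neighbour weight relative to the sparser
#' node's connectivity.
#'
#' @param adjacency Output of [build_adjacency()].
#' @return Gene x gene TOM matrix, diagonal 1.
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  shared <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage clustering of TOM dissimilarity, cut at a fixed fraction
#' of the tree height; branches smaller than `min_module_size` fall into the
#' unassigned background module M0.
#'
#' @param adjacency Adjacency matrix.
#' @param min_module_size Minimum genes per module (default 20).
#' @param cut_height Cut at `cut_height * max(merge height)` (default 0.99).
#' @return Named character vector gene -> module label (M0, M1, ...), with
#'   the dendrogram in attribute `tree`.
#' @export
detect_modules <- function(adjacency, min_module_size = 20, cut_height = 0.99) {
  genes <- rownames(adjacency)
  if (nrow(adjacency) < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned (M0)")
    return(stats::setNames(rep("M0", nrow(adjacency)), genes))
  }
  diss <- 1 - tom_similarity(adjacency)
  tree <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- if (max(tree$height) <= 0) {
    rep(1L, length(genes))  # all genes identical
  } else {
    stats::cutree(tree, h = cut_height * max(tree$height))
  }
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  # label kept clusters M1.. by decreasing size, ties by first occurrence
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  labels <- stats::setNames(rep("M0", length(genes)), genes)
  for (i in seq_along(keep)) {
    labels[cl == as.integer(keep[i])] <- paste0("M", i)
  }
  attr(labels, "tree") <- tree
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' gene-standardized expression, oriented to correlate positively with the
#' module's mean standardized profile. Singleton modules use the gene's own
#' standardized profile. M0 (background) gets no eigengene.
#'
#' @param m Expression matrix (genes x samples).
#' @param modules Named module assignment from [detect_modules()].
#' @return Samples x modules matrix of eigengene values (unit norm).
#' @export
module_eigengenes <- function(m, modules) {
  mods <- setdiff(sort(unique(modules)), "M0")
  if (length(mods) == 0) stop("no assigned modules (all M0)", call. = FALSE)
  em <- vapply(mods, function(mod) {
    genes <- names(modules)[modules == mod]
    x <- m[genes, , drop = FALSE]
    xs <- t(scale(t(x)))  # standardize each gene
    if (nrow(xs) == 1) {
      e <- as.numeric(xs)
      e <- e / sqrt(sum(e^2))
      return(e)
    }
    sv <- svd(xs, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (stats::cor(e, colMeans(xs)) < 0) e <- -e
    e
  }, numeric(ncol(m)))
  rownames(em) <- colnames(m)
  em
}

#' kME module membership
#'
#' Pearson correlation of each gene's expression profile with each module
#' eigengene (the signedKME convention).
#'
#' @param m Expression matrix (genes x samples).
#' @param eigengenes Samples x modules matrix from [module_eigengenes()].
#' @return Genes x modules matrix of correlations in [-1, 1].
#' @export
compute_kme <- function(m, eigengenes) {
  stats::cor(t(m), eigengenes)
}

#' Hub genes by kME percentile
#'
#' The hub threshold is the `percentile` quantile (type 7, linear
#' interpolation) of |own-module kME| over all assigned (non-M0) genes;
#' hubs are the genes strictly above it.
#'
#' @param kme kME matrix from [compute_kme()].
#' @param modules Module assignment.
#' @param percentile Quantile defining the cutoff (default 0.95).
#' @return List with `hubs` (gene ids), `threshold`, and `own_kme` (named
#'   |own-module kME| of every assigned gene).
#' @export
hub_genes <- function(kme, modules, percentile = 0.95) {
  assigned <- names(modules)[modules != "M0"]
  assigned <- intersect(assigned, rownames(kme))
  if (length(assigned) == 0) {
    return(list(hubs = character(0), threshold = NA_real_,
                own_kme = numeric(0)))
  }
  own <- abs(kme[cbind(assigned, modules[assigned])])
  names(own) <- assigned
  threshold <- stats::quantile(own, percentile, type = 7, names = FALSE)
  list(hubs = sort(names(own)[own > threshold]),
       threshold = threshold,
       own_kme = own)
}

#' Module x gene-set enrichment
#'
#' One-sided Fisher's exact test of the overlap between each module and a
#' gene set over a common universe, FDR-corrected across modules.
#'
#' @param modules Module assignment (all labels present are tested,
#'   including M0).
#' @param gene_set Character vector, subset of `universe`.
#' @param universe Character vector of all genes under consideration.
#' @return data.frame with columns module, a, b, c, d, odds_ratio, p, q.
#' @export
module_set_enrichment <- function(modules, gene_set, universe) {
  gene_set <- intersect(unique(gene_set), universe)
  labs <- sort(unique(modules))
  rows <- lapply(labs, function(mod) {
    members <- intersect(names(modules)[modules == mod], universe)
    fr <- fisher_enrichment(members, gene_set, universe)
    data.frame(module = mod, a = fr$a, b = fr$b, c = fr$c, d = fr$d,
               odds_ratio = fr$odds_ratio, p = fr$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p)
  out
}
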