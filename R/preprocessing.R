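# Transformations applied before all downstream analyses: log2(x + 1),
# zero-variance filtering, empirical-Bayes batch adjustment, PCA, gene-wise
# z-scoring and the per-treatment dendrogram.

#' Log2(x + 1) transform
#'
#' @param m Non-negative expression matrix (TPM scale).
#' @return Matrix of the same shape, entrywise log2(x + 1).
#' @export
log_transform <- function(m) {
  assert_expression_matrix(m, non_negative = TRUE)
  log2(m + 1)
}

#' Remove genes with zero variance across samples
#'
#' @param m Expression matrix with >= 2 samples.
#' @return The matrix restricted to genes whose sample variance is > 0,
#'   original order preserved. Warns if nothing is left.
#' @export
filter_zero_variance <- function(m) {
  assert_expression_matrix(m)
  keep <- row_vars(m) > 0
  if (!any(keep)) warning("all genes have zero variance; empty matrix returned")
  m[keep, , drop = FALSE]
}

#' Empirical-Bayes batch adjustment
#'
#' Parametric ComBat location/scale adjustment of per-batch effects, with no
#' covariates (only the batch label is modelled). The input is expected to be
#' log-transformed already. A single-batch input is returned unchanged (there
#' is nothing to adjust; the standardize/back-transform round trip is the
#' identity).
#'
#' @param m Log-scale expression matrix (genes x samples), no zero-variance
#'   genes.
#' @param batches Character/factor vector of batch (BioProject) labels, one
#'   per sample, or a metadata data.frame with `sample_id` and `bioproject`.
#' @return Adjusted matrix of the same shape and dimnames.
#' @export
combat_adjust <- function(m, batches) {
  assert_expression_matrix(m)
  if (is.data.frame(batches)) {
    batches <- align_metadata(batches, m)$bioproject
  }
  if (length(batches) != ncol(m)) {
    stop("need one batch label per sample", call. = FALSE)
  }
  batches <- as.character(batches)
  tab <- table(batches)
  if (any(tab < 2)) {
    stop("batch ", paste(names(tab)[tab < 2], collapse = ", "),
         " has fewer than 2 samples", call. = FALSE)
  }
  if (length(tab) == 1) return(m)
  if (any(row_vars(m) == 0)) {
    stop("remove zero-variance genes before batch adjustment", call. = FALSE)
  }
  out <- suppressMessages(sva::ComBat(dat = m, batch = batches,
                                      par.prior = TRUE, prior.plots = FALSE))
  dimnames(out) <- dimnames(m)
  out
}

#' Principal component analysis of samples
#'
#' Centered (not scaled) PCA of the samples in gene space. The sign of each
#' component is fixed so that its largest-magnitude gene loading is positive.
#'
#' @param m Expression matrix (genes x samples) with zero-variance genes
#'   removed.
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x components), `variance_explained`
#'   (fraction of total variance per returned component) and `loadings`
#'   (genes x components).
#' @export
pca_expression <- function(m, n_components = 2) {
  assert_expression_matrix(m)
  if (n_components > min(dim(m))) {
    stop("n_components exceeds min(n_genes, n_samples)", call. = FALSE)
  }
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  scores <- pc$x[, k, drop = FALSE]
  loadings <- pc$rotation[, k, drop = FALSE]
  for (i in k) {
    j <- which.max(abs(loadings[, i]))
    if (loadings[j, i] < 0) {
      loadings[, i] <- -loadings[, i]
      scores[, i] <- -scores[, i]
    }
  }
  list(scores = scores,
       variance_explained = (pc$sdev^2 / sum(pc$sdev^2))[k],
       loadings = loadings)
}

#' Gene-wise z-score
#'
#' Centers each gene to mean 0 and scales to unit population standard
#' deviation (denominator n, the StandardScaler convention), so applying the
#' transform twice equals applying it once.
#'
#' @param m Expression matrix without zero-variance genes.
#' @return Matrix of the same shape.
#' @export
zscore_genes <- function(m) {
  assert_expression_matrix(m)
  v <- row_vars(m) * (ncol(m) - 1) / ncol(m)
  if (any(v == 0)) {
    stop("zero-variance genes present; filter before z-scoring", call. = FALSE)
  }
  (m - rowMeans(m)) / sqrt(v)
}

#' Hierarchical clustering of treatment mean profiles
#'
#' Averages the (already z-scored) expression of each treatment's samples
#' into one profile per treatment and clusters the profiles agglomeratively
#' (Euclidean distance, average linkage by default).
#'
#' @param m Batch-corrected, log-transformed, gene-wise z-scored matrix.
#' @param meta Sample metadata with `treatment`.
#' @param method Linkage passed to [stats::hclust()].
#' @return An `hclust` tree with one leaf per treatment.
#' @export
treatment_dendrogram <- function(m, meta, method = "average") {
  meta <- align_metadata(meta, m)
  treatments <- unique(meta$treatment)
  counts <- table(factor(meta$treatment, levels = treatments))
  if (any(counts == 0)) {
    warning("treatments without samples excluded: ",
            paste(names(counts)[counts == 0], collapse = ", "))
    treatments <- names(counts)[counts > 0]
  }
  if (length(treatments) < 2) {
    stop("need >= 2 treatments with samples", call. = FALSE)
  }
  profiles <- vapply(treatments, function(tr) {
    rowMeans(m[, meta$treatment == tr, drop = FALSE])
  }, numeric(nrow(m)))
  stats::hclust(stats::dist(t(profiles)), method = method)
}
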