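# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_expression_matrix <- function(m, non_negative = FALSE) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expression matrix must be a numeric matrix (genes x samples)",
         call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m)) > 0) stop("duplicated gene ids", call. = FALSE)
  if (anyDuplicated(colnames(m)) > 0) stop("duplicated sample ids", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite values in expression matrix", call. = FALSE)
  if (non_negative && any(m < 0)) {
    stop("expression matrix must be non-negative (TPM scale expected)", call. = FALSE)
  }
  invisible(m)
}

#' @keywords internal
assert_metadata <- function(meta, m = NULL) {
  need <- c("sample_id", "bioproject", "treatment")
  if (!is.data.frame(meta) || !all(need %in% names(meta))) {
    stop("metadata must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id) > 0) {
    stop("duplicated sample ids in metadata", call. = FALSE)
  }
  if (!is.null(m)) {
    if (!setequal(colnames(m), meta$sample_id)) {
      stop("metadata sample_id set must match expression matrix columns",
           call. = FALSE)
    }
  }
  invisible(meta)
}

# Align metadata rows to the column order of an expression matrix.
#' @keywords internal
align_metadata <- function(meta, m) {
  assert_metadata(meta, m)
  meta[match(colnames(m), meta$sample_id), , drop = FALSE]
}

# Row-wise variance with the sample (n - 1) denominator.
#' @keywords internal
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) stop("need >= 2 samples to compute variances", call. = FALSE)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific seed from one global seed
#'
#' Hashes a stage label together with the global seed so that every pipeline
#' stage gets an independent, reproducible RNG stream. The result is always a
#' positive integer below 2^31.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483587 + 1)
}

# Stable gene ranking used wherever a "top k by importance" cut is taken:
# decreasing score, ties broken by gene id.
#' @keywords internal
rank_genes <- function(scores) {
  stopifnot(!is.null(names(scores)))
  names(scores)[order(-scores, names(scores), method = "radix")]
}
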