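# GENIE3-style regulatory network inference (per-target random-forest
# regression on TF expression, edge weight = impurity importance) and the
# repeated-Dunnett comparison of mean regulatory weights across gene classes
# (core, stress-specific, other).

#' Infer a TF -> target regulatory network
#'
#' For every target gene, a random-forest regression of its expression on all
#' TF expression profiles (the target itself excluded when it is a TF); the
#' weight of edge TF -> target is the TF's impurity-reduction importance,
#' normalized per target to sum to 1 when `normalize` is TRUE.
#'
#' @param m Batch-corrected log2 expression, genes x samples (>= 10 samples).
#' @param tf_list Character vector of regulator gene ids (>= 2 present in
#'   `m`).
#' @param seed Integer seed (per-target forests get derived seeds).
#' @param n_trees Trees per target forest (default 100).
#' @param targets Target genes (default: all genes in `m`).
#' @param normalize Normalize incoming weights per target to sum to 1.
#' @param mtry Candidate regulators per split: "all" (default; with modest
#'   TF panels every split sees every regulator, keeping competitor TFs from
#'   accruing chance importance), "sqrt", or an integer.
#' @return data.frame edge list with columns regulator, target, weight;
#'   attribute `n_zero_variance_targets` counts targets whose incoming
#'   weights were set to 0.
#' @export
infer_grn <- function(m, tf_list, seed = 1, n_trees = 100, targets = NULL,
                      normalize = TRUE, mtry = c("all", "sqrt")) {
  if (is.character(mtry)) mtry <- match.arg(mtry)
  assert_expression_matrix(m)
  tfs <- sort(intersect(unique(tf_list), rownames(m)))
  if (length(tfs) < 2) stop("need >= 2 TFs present in the matrix", call. = FALSE)
  if (ncol(m) < 10) stop("need >= 10 samples", call. = FALSE)
  targets <- targets %||% rownames(m)
  x_all <- t(m[tfs, , drop = FALSE])
  vars <- row_vars(m)
  n_zero <- 0L
  rows <- lapply(seq_along(targets), function(i) {
    tgt <- targets[i]
    preds <- setdiff(tfs, tgt)
    w <- stats::setNames(rep(0, length(preds)), preds)
    k <- if (identical(mtry, "all")) length(preds)
         else if (identical(mtry, "sqrt")) max(1L, floor(sqrt(length(preds))))
         else min(length(preds), max(1L, as.integer(mtry)))
    if (vars[tgt] > 0) {
      fit <- ranger::ranger(x = x_all[, preds, drop = FALSE],
                            y = m[tgt, ],
                            num.trees = n_trees,
                            mtry = k,
                            importance = "impurity",
                            seed = derive_seed(seed, paste0("grn_", tgt)),
                            num.threads = 1)
      w <- pmax(fit$variable.importance, 0)
      if (normalize && sum(w) > 0) w <- w / sum(w)
    } else {
      n_zero <<- n_zero + 1L
    }
    data.frame(regulator = names(w), target = tgt, weight = unname(w),
               stringsAsFactors = FALSE)
  })
  if (n_zero > 0) {
    warning(n_zero, " zero-variance target(s); incoming weights set to 0")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_zero_variance_targets") <- n_zero
  out
}

#' Area under the precision-recall curve for planted edges
#'
#' Ranks all candidate edges by decreasing weight (ties broken by regulator
#' then target id) and computes average precision over the true edges.
#'
#' @param edges Edge list from [infer_grn()].
#' @param regulator_targets Named list: TF id -> character vector of true
#'   target ids.
#' @return List with aupr, baseline (edge density of true edges among
#'   candidates), n_true and n_candidates.
#' @export
grn_aupr <- function(edges, regulator_targets) {
  truth <- mapply(function(reg, tgts) paste(reg, tgts, sep = "->"),
                  names(regulator_targets), regulator_targets,
                  SIMPLIFY = FALSE)
  truth <- unlist(truth, use.names = FALSE)
  key <- paste(edges$regulator, edges$target, sep = "->")
  pos <- key %in% truth
  ord <- order(-edges$weight, edges$regulator, edges$target, method = "radix")
  pos <- pos[ord]
  n_true <- sum(pos)
  if (n_true == 0) stop("no true edges among candidates", call. = FALSE)
  prec_at <- cumsum(pos) / seq_along(pos)
  list(aupr = sum(prec_at[pos]) / n_true,
       baseline = n_true / length(pos),
       n_true = n_true,
       n_candidates = length(pos))
}

#' Mean incoming regulatory weight per target
#'
#' @param edges Edge list from [infer_grn()].
#' @param focal_tfs Regulators to average over (e.g. core TFs of enriched
#'   families).
#' @param targets Optional target subset.
#' @return Named numeric vector: per target, the mean weight of edges from
#'   `focal_tfs`. Targets with no focal incoming edge are excluded; their
#'   count is in attribute `n_excluded`.
#' @export
mean_incoming_weight <- function(edges, focal_tfs, targets = NULL) {
  if (!all(focal_tfs %in% edges$regulator)) {
    stop("focal_tfs must be regulators in the edge list", call. = FALSE)
  }
  sub <- edges[edges$regulator %in% focal_tfs, , drop = FALSE]
  wanted <- targets %||% unique(edges$target)
  sub <- sub[sub$target %in% wanted, , drop = FALSE]
  mw <- tapply(sub$weight, sub$target, mean)
  out <- stats::setNames(as.numeric(mw), names(mw))
  out <- out[sort(names(out))]
  attr(out, "n_excluded") <- length(setdiff(wanted, names(out)))
  out
}

# Gauss-Legendre nodes/weights on (0, 1), cached per order (Golub-Welsch).
.quad_cache <- new.env(parent = emptyenv())
#' @keywords internal
gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.quad_cache[[key]])) return(.quad_cache[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  out <- list(nodes = (e$values[ord] + 1) / 2,
              weights = (2 * e$vectors[1, ]^2)[ord] / 2)
  .quad_cache[[key]] <- out
  out
}

# Two-sided Dunnett family-wise p-values. The many-to-one contrast
# statistics have the one-factor correlation rho_ij = lambda_i lambda_j, so
# P(all |T_i| <= t) reduces to a double integral over the shared normal
# factor and the pooled-variance chi scale, evaluated here by deterministic
# Gauss-Legendre quadrature (no Monte Carlo).
#' @keywords internal
dunnett_p_twosided <- function(tvals, lambda, df, n_z = 64, n_s = 32) {
  gz <- gauss_legendre(n_z)
  gs <- gauss_legendre(n_s)
  z <- stats::qnorm(gz$nodes)
  s <- sqrt(stats::qchisq(gs$nodes, df) / df)
  sql <- sqrt(1 - lambda^2)
  vapply(tvals, function(t) {
    t <- abs(t)
    prod_mat <- matrix(1, n_s, n_z)
    for (i in seq_along(lambda)) {
      lz <- lambda[i] * z
      up <- outer(t * s, lz, "-") / sql[i]
      lo <- outer(-t * s, lz, "-") / sql[i]
      prod_mat <- prod_mat * (stats::pnorm(up) - stats::pnorm(lo))
    }
    P <- as.numeric(gs$weights %*% prod_mat %*% gz$weights)
    min(1, max(0, 1 - P))
  }, numeric(1))
}

#' Dunnett's many-to-one comparison against a control group
#'
#' Classical Dunnett test: pooled equal-variance estimate, per-group
#' t statistics of the mean difference to the control group, and two-sided
#' family-wise adjusted p-values from the multivariate-t distribution of the
#' contrast statistics. The one-factor correlation structure of the
#' many-to-one contrasts is exploited to evaluate the distribution by
#' deterministic Gauss-Legendre quadrature; single-contrast cases use the
#' closed-form t distribution.
#'
#' @param values Numeric vector of observations.
#' @param groups Character/factor group label per observation.
#' @param control Control group label (default "other").
#' @param n_quad Quadrature orders (factor, scale) of the multivariate-t
#'   integration; the defaults give absolute error well below 1e-5.
#' @return data.frame with one row per non-control group: group, n, mean,
#'   diff (group mean - control mean), t and adjusted p. Control summary is
#'   in attributes `control_mean`, `control_n`, `df`.
#' @export
dunnett_compare <- function(values, groups, control = "other",
                            n_quad = c(64, 32)) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  if (!control %in% groups) stop("control group not present: ", control,
                                 call. = FALSE)
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (control %in% small) stop("control group needs >= 2 observations",
                               call. = FALSE)
  if (length(small) > 0) {
    warning("dropping groups with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    values <- values[keep]
    groups <- groups[keep]
    tab <- table(groups)
  }
  labs <- c(control, sort(setdiff(names(tab), control)))
  n <- as.numeric(tab[labs])
  means <- vapply(labs, function(g) mean(values[groups == g]), numeric(1))
  ss <- vapply(labs, function(g) {
    v <- values[groups == g]
    sum((v - mean(v))^2)
  }, numeric(1))
  df <- sum(n) - length(labs)
  s2 <- sum(ss) / df
  k <- length(labs) - 1
  diff <- means[-1] - means[1]
  se <- sqrt(s2 * (1 / n[-1] + 1 / n[1]))
  tstat <- diff / se
  lambda <- sqrt(n[-1] / (n[-1] + n[1]))
  p <- if (k == 1) {
    2 * stats::pt(-abs(tstat), df)
  } else {
    dunnett_p_twosided(tstat, lambda, df, n_z = n_quad[1], n_s = n_quad[2])
  }
  out <- data.frame(group = labs[-1], n = n[-1], mean = means[-1],
                    diff = unname(diff), t = unname(tstat), p = p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "control_mean") <- means[1]
  attr(out, "control_n") <- n[1]
  attr(out, "df") <- df
  out
}

#' Repeated Dunnett test with bootstrap p-value distribution
#'
#' Dunnett's test on fixed data is deterministic; to obtain a p-value
#' distribution from a single dataset, each repetition resamples the
#' observations within every group (with replacement, original group sizes)
#' and recomputes the test. A comparison is flagged significant when the
#' upper bound of the central 95% interval of its p-value distribution
#' (2.5th-97.5th percentiles) is below 0.05.
#'
#' @inheritParams dunnett_compare
#' @param n_reps Number of repetitions (default 5000; < 100 warns).
#' @param seed Integer seed for the resampling.
#' @return data.frame per non-control group: group, n, mean, diff,
#'   p_observed, ci_lower, ci_upper, significant. The matrix of repetition
#'   p-values is in attribute `p_reps`.
#' @export
repeated_dunnett <- function(values, groups, control = "other",
                             n_reps = 5000, seed = 1, n_quad = c(64, 32)) {
  if (n_reps < 100) warning("n_reps < 100 gives unstable confidence intervals")
  observed <- dunnett_compare(values, groups, control, n_quad = n_quad)
  groups <- as.character(groups)
  keep <- groups %in% c(observed$group, control)
  values <- values[keep]
  groups <- groups[keep]
  idx_by_group <- split(seq_along(values), groups)
  p_reps <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      idx <- unlist(lapply(idx_by_group, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
      dunnett_compare(values[idx], groups[idx], control,
                      n_quad = n_quad)$p
    }, numeric(nrow(observed)))
  })
  p_reps <- matrix(p_reps, nrow = nrow(observed),
                   dimnames = list(observed$group, NULL))
  ci <- apply(p_reps, 1, stats::quantile, probs = c(0.025, 0.975),
              type = 7, names = FALSE)
  out <- data.frame(group = observed$group, n = observed$n,
                    mean = observed$mean, diff = observed$diff,
                    p_observed = observed$p,
                    ci_lower = ci[1, ], ci_upper = ci[2, ],
                    significant = ci[2, ] < 0.05,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "p_reps") <- p_reps
  attr(out, "control_mean") <- attr(observed, "control_mean")
  out
}

#' Compare mean regulatory weights across target gene classes
#'
#' Builds per-target mean incoming weights from the focal TFs, assigns every
#' target to a gene class (first matching set in `group_sets`; targets in no
#' set form the control class "other") and runs [repeated_dunnett()].
#'
#' @param edges Edge list from [infer_grn()].
#' @param focal_tfs Focal regulators (e.g. core TFs from enriched families).
#' @param group_sets Named list of gene-id vectors (e.g. core,
#'   specific_heat, ...); assumed disjoint - on overlap the first name wins.
#' @param n_reps,seed,n_quad Passed to [repeated_dunnett()].
#' @return As [repeated_dunnett()].
#' @export
grn_group_comparison <- function(edges, focal_tfs, group_sets,
                                 n_reps = 5000, seed = 1,
                                 n_quad = c(64, 32)) {
  stopifnot(is.list(group_sets), !is.null(names(group_sets)))
  mw <- mean_incoming_weight(edges, focal_tfs,
                             targets = setdiff(unique(edges$target),
                                               focal_tfs))
  grp <- rep("other", length(mw))
  for (nm in rev(names(group_sets))) {
    grp[names(mw) %in% group_sets[[nm]]] <- nm
  }
  repeated_dunnett(as.numeric(mw), grp, control = "other",
                   n_reps = n_reps, seed = seed, n_quad = n_quad)
}
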