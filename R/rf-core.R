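# Hold-one-stressor-out random-forest classification of stressed vs control
# samples, SMOTE class balancing, hyperparameter search, importance-based
# iterative feature selection, and the intersection of per-model top
# importance sets that defines the random-forest core genes.

#' Random-forest configuration
#'
#' @param grid Named list of hyperparameter values sampled by the randomized
#'   search. Names map to ranger arguments: num.trees, max.depth (0 =
#'   unlimited), mtry_frac (fraction of genes; NA = ranger's sqrt default),
#'   min.bucket (minimum terminal-node size), min.node.size (minimum size of
#'   a node to be split) and replace (bootstrap vs subsampling).
#' @param n_candidates Hyperparameter combinations evaluated by the search.
#' @param cv_folds Stratified cross-validation folds on the training set.
#' @param subset_sizes Feature-subset sizes for the importance curve.
#' @param top_k Importance rank cutoff per model for the core intersection.
#' @param smote_k SMOTE nearest-neighbour count.
#' @param auc_tolerance A subset size counts as near-optimal if its AUC is
#'   within this tolerance of the best AUC over all sizes.
#' @param importance_num_trees Tree count for the final importance refit.
#'   Impurity-importance ranks need considerably more trees to stabilize
#'   than held-out predictions do, so the final model is grown with at least
#'   this many trees regardless of the tuned num.trees.
#' @return List of class `rf_config`.
#' @export
rf_config <- function(grid = list(num.trees = c(100, 200, 300),
                                  max.depth = c(0, 10, 20),
                                  mtry_frac = c(NA, 0.1, 0.3),
                                  min.bucket = c(1, 2, 4),
                                  min.node.size = c(2, 5, 10),
                                  replace = c(TRUE, FALSE)),
                      n_candidates = 8,
                      cv_folds = 3,
                      subset_sizes = c(50, 100, 250, 500, 1000, 1500, 2000,
                                       2500, 3000, 4000, 5000, 6000, 7000,
                                       8000, 10000, 15000),
                      top_k = 6000,
                      smote_k = 5,
                      auc_tolerance = 0.01,
                      importance_num_trees = 1000) {
  if (is.unsorted(subset_sizes, strictly = TRUE)) {
    stop("subset_sizes must be strictly increasing", call. = FALSE)
  }
  structure(as.list(environment()), class = "rf_config")
}

#' Hold-one-stressor-out train/test split
#'
#' The test set holds every sample (stressed and control) of every BioProject
#' that assayed the held-out stressor; all remaining samples form the
#' training set, so no experiment leaks across the split.
#'
#' @param meta Sample metadata.
#' @param stressor Held-out stressor label.
#' @return List with `train` and `test` sample-id vectors.
#' @export
split_hold_one_stressor <- function(meta, stressor) {
  assert_metadata(meta)
  bp <- unique(meta$bioproject[meta$treatment == stressor])
  if (length(bp) == 0) stop("stressor not present: ", stressor, call. = FALSE)
  test <- meta$sample_id[meta$bioproject %in% bp]
  list(train = setdiff(meta$sample_id, test), test = test)
}

#' Binary stress/control labels from metadata
#'
#' @param meta Sample metadata.
#' @return Factor with levels control, stress, named by sample id.
#' @export
stress_labels <- function(meta) {
  assert_metadata(meta)
  stats::setNames(
    factor(ifelse(meta$treatment == "control", "control", "stress"),
           levels = c("control", "stress")),
    meta$sample_id)
}

#' SMOTE class balancing
#'
#' Upsamples the minority class with synthetic points interpolated between a
#' minority sample and one of its k nearest minority neighbours (Euclidean).
#' Original samples are always retained; only training data should ever be
#' passed here.
#'
#' @param x Numeric matrix, samples x features.
#' @param y Factor of two class labels, one per row of `x`.
#' @param k Number of minority nearest neighbours.
#' @return List with balanced `x` and `y` (synthetic rows named `smote_i`).
#' @export
smote_balance <- function(x, y, k = 5) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("SMOTE needs both classes present", call. = FALSE)
  if (nlevels(y) > 2) stop("SMOTE here supports binary labels only", call. = FALSE)
  counts <- table(y)
  if (counts[1] == counts[2]) return(list(x = x, y = y))
  minority <- names(counts)[which.min(counts)]
  n_min <- min(counts)
  n_new <- max(counts) - n_min
  if (n_min < 2) {
    stop("minority class has fewer than 2 samples; cannot interpolate",
         call. = FALSE)
  }
  if (n_min <= k) {
    warning("minority class smaller than k + 1; reducing k to ", n_min - 1)
    k <- n_min - 1
  }
  xm <- x[y == minority, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- apply(d, 1, function(row) order(row)[seq_len(k)])
  nn <- matrix(nn, nrow = k)  # k x n_min
  base_idx <- sample.int(n_min, n_new, replace = TRUE)
  pick <- vapply(base_idx, function(i) nn[sample.int(k, 1), i], integer(1))
  lambda <- stats::runif(n_new)
  synth <- xm[base_idx, , drop = FALSE] +
    lambda * (xm[pick, , drop = FALSE] - xm[base_idx, , drop = FALSE])
  rownames(synth) <- sprintf("smote_%d", seq_len(n_new))
  list(x = rbind(x, synth),
       y = factor(c(as.character(y), rep(minority, n_new)),
                  levels = levels(y)))
}

# Stratified fold assignment, one integer per sample.
#' @keywords internal
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

# AUC of P(stress) against true labels; NA (with warning) if one class only.
#' @keywords internal
binary_auc <- function(y, prob_stress) {
  if (length(unique(y)) < 2) {
    warning("test set contains a single class; AUC undefined")
    return(NA_real_)
  }
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = prob_stress,
                                 levels = c("control", "stress"),
                                 direction = "<", quiet = TRUE)))
}

#' @keywords internal
binary_metrics <- function(y, prob_stress) {
  pred <- factor(ifelse(prob_stress > 0.5, "stress", "control"),
                 levels = c("control", "stress"))
  tp <- sum(pred == "stress" & y == "stress")
  fp <- sum(pred == "stress" & y == "control")
  fn <- sum(pred == "control" & y == "stress")
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else {
    2 * prec * rec / (prec + rec)
  }
  c(accuracy = mean(pred == y), auc = binary_auc(y, prob_stress), f1 = f1)
}

#' @keywords internal
fit_ranger <- function(x, y, hyper, seed, importance = "none") {
  mtry <- if (is.na(hyper$mtry_frac)) NULL else {
    max(1L, floor(hyper$mtry_frac * ncol(x)))
  }
  ranger::ranger(x = x, y = y, probability = TRUE,
                 num.trees = hyper$num.trees,
                 mtry = mtry,
                 max.depth = hyper$max.depth,
                 min.bucket = hyper$min.bucket,
                 min.node.size = hyper$min.node.size,
                 replace = hyper$replace,
                 importance = importance,
                 seed = seed, num.threads = 1)
}

#' @keywords internal
predict_prob_stress <- function(fit, x) {
  p <- stats::predict(fit, data = x, num.threads = 1)$predictions
  p[, "stress"]
}

#' Tune, fit and evaluate one held-out-stressor model
#'
#' Randomized hyperparameter search with stratified cross-validation on the
#' training samples only (SMOTE is applied inside each fold, so synthetic
#' points never leak into a validation fold), final refit on the
#' SMOTE-balanced full training set, and evaluation on the untouched test
#' set. Feature importance (impurity) is normalized to sum to 1.
#'
#' @param x_train,x_test Numeric matrices, samples x genes (batch-corrected
#'   log2 TPM).
#' @param y_train,y_test Factors with levels control/stress.
#' @param config [rf_config()].
#' @param seed Integer seed controlling the search, SMOTE and forests.
#' @return List: `hyperparameters`, `metrics` (accuracy, auc, f1),
#'   `importance` (named, sums to 1), `cv_auc`, `candidates`.
#' @export
tune_fit_evaluate <- function(x_train, y_train, x_test, y_test,
                              config = rf_config(), seed = 1) {
  stopifnot(inherits(config, "rf_config"))
  with_seed(seed, {
    candidates <- lapply(seq_len(config$n_candidates), function(i) {
      lapply(config$grid, function(vals) vals[[sample.int(length(vals), 1)]])
    })
    folds <- stratified_folds(y_train, config$cv_folds)
    cv_auc <- vapply(seq_along(candidates), function(ci) {
      hyper <- candidates[[ci]]
      aucs <- vapply(seq_len(config$cv_folds), function(f) {
        tr <- folds != f
        bal <- smote_balance(x_train[tr, , drop = FALSE], y_train[tr],
                             k = config$smote_k)
        fit <- fit_ranger(bal$x, bal$y, hyper, seed = seed + 131 * ci + f)
        binary_auc(y_train[!tr],
                   predict_prob_stress(fit, x_train[!tr, , drop = FALSE]))
      }, numeric(1))
      mean(aucs)
    }, numeric(1))
    best <- which.max(cv_auc)
    hyper <- candidates[[best]]

    bal <- smote_balance(x_train, y_train, k = config$smote_k)
    final_hyper <- hyper
    final_hyper$num.trees <- max(hyper$num.trees, config$importance_num_trees)
    fit <- fit_ranger(bal$x, bal$y, final_hyper, seed = seed,
                      importance = "impurity")
    imp <- pmax(fit$variable.importance, 0)
    if (sum(imp) > 0) imp <- imp / sum(imp)
    metrics <- binary_metrics(y_test, predict_prob_stress(fit, x_test))
    list(hyperparameters = hyper,
         metrics = metrics,
         importance = imp,
         cv_auc = cv_auc[best],
         candidates = data.frame(candidate = seq_along(cv_auc),
                                 cv_auc = cv_auc))
  })
}

#' Importance-ranked feature-subset performance curve
#'
#' Refits the model on the top-X genes by importance for each requested
#' subset size and records test metrics. The optimum is the smallest size
#' whose AUC is within `auc_tolerance` of the best AUC over all sizes.
#'
#' @inheritParams tune_fit_evaluate
#' @param importance Named importance vector from the full model.
#' @param hyper Chosen hyperparameter list.
#' @param subset_sizes Ordered subset sizes; sizes exceeding the gene count
#'   are skipped with a warning.
#' @return data.frame (size, accuracy, auc, f1) with attribute
#'   `optimum_size`.
#' @export
iterative_feature_selection <- function(x_train, y_train, x_test, y_test,
                                        importance, hyper,
                                        subset_sizes, seed = 1,
                                        smote_k = 5, auc_tolerance = 0.01) {
  ranking <- rank_genes(importance)
  valid <- subset_sizes[subset_sizes <= length(ranking)]
  if (length(valid) < length(subset_sizes)) {
    warning("skipping subset sizes larger than the gene count: ",
            paste(setdiff(subset_sizes, valid), collapse = ", "))
  }
  with_seed(seed, {
    bal <- smote_balance(x_train, y_train, k = smote_k)
    rows <- lapply(valid, function(X) {
      top <- ranking[seq_len(X)]
      fit <- fit_ranger(bal$x[, top, drop = FALSE], bal$y, hyper,
                        seed = seed + X)
      m <- binary_metrics(y_test,
                          predict_prob_stress(fit, x_test[, top, drop = FALSE]))
      data.frame(size = X, accuracy = m[["accuracy"]], auc = m[["auc"]],
                 f1 = m[["f1"]])
    })
  })
  curve <- do.call(rbind, rows)
  best_auc <- max(curve$auc, na.rm = TRUE)
  attr(curve, "optimum_size") <-
    min(curve$size[curve$auc >= best_auc - auc_tolerance])
  curve
}

#' Fit all hold-one-stressor-out models
#'
#' @param m Batch-corrected log2 TPM matrix (genes x samples).
#' @param meta Sample metadata.
#' @param config [rf_config()].
#' @param seed Global seed; each stressor's model gets a derived seed.
#' @return Named list (per stressor) of [tune_fit_evaluate()] results, each
#'   with the held-out stressor and split recorded.
#' @export
run_rf_models <- function(m, meta, config = rf_config(), seed = 1) {
  meta <- align_metadata(meta, m)
  labels <- stress_labels(meta)
  stressors <- sort(setdiff(unique(meta$treatment), "control"))
  x <- t(m)
  out <- lapply(stressors, function(s) {
    split <- split_hold_one_stressor(meta, s)
    res <- tune_fit_evaluate(x[split$train, , drop = FALSE],
                             labels[split$train],
                             x[split$test, , drop = FALSE],
                             labels[split$test],
                             config = config,
                             seed = derive_seed(seed, paste0("rf_", s)))
    res$held_out_stressor <- s
    res$split <- split
    res
  })
  names(out) <- stressors
  out
}

#' Random-forest core genes: intersection of per-model top importance sets
#'
#' Ties at the rank-`top_k` boundary are broken by gene id (stable sort on
#' decreasing importance, then id).
#'
#' @param results Named list of per-stressor model results (all stressors
#'   required unless `allow_partial`).
#' @param top_k Importance rank cutoff.
#' @param allow_partial Allow fewer models than stressors.
#' @param stressors Expected stressor names (defaults to `names(results)`).
#' @return Sorted character vector of core gene ids.
#' @export
rf_core_genes <- function(results, top_k = 6000, allow_partial = FALSE,
                          stressors = names(results)) {
  missing <- setdiff(stressors, names(results))
  if (length(missing) > 0 && !allow_partial) {
    stop("missing models for stressors: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tops <- lapply(results, function(r) {
    ranking <- rank_genes(r$importance)
    ranking[seq_len(min(top_k, length(ranking)))]
  })
  sort(Reduce(intersect, tops))
}

#' Cross-reference core genes against TN-ratio calls
#'
#' A gene counts as up if it was called up under at least one experiment and
#' as down analogously, so it may count in both directions (under different
#' stressors); `none` collects core genes never differentially expressed.
#'
#' @param core Character vector of core gene ids.
#' @param calls Output of [de_call_table()].
#' @return List with `counts` (up, down, none) and the member gene vectors.
#' @export
annotate_direction <- function(core, calls) {
  up <- intersect(core, unique(calls$gene[calls$call == "up"]))
  down <- intersect(core, unique(calls$gene[calls$call == "down"]))
  none <- setdiff(core, union(up, down))
  list(counts = c(up = length(up), down = length(down), none = length(none)),
       up = sort(up), down = sort(down), none = sort(none))
}
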