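#' Classifier specification for cross-validated evaluation
#'
#' @param kind `"random_forest"` (100 trees, `sqrt(d)` candidate features
#'   per split — the usual defaults) or `"part"` (the PART rule learner).
#' @param seed Integer seed (controls forest randomness; PART is
#'   deterministic and accepts the seed only for interface uniformity).
#' @param ... Hyperparameter overrides: `num_trees` for random forests;
#'   `prune_cf`, `min_leaf` for PART.
#' @return A `ClassifierSpec` list.
#' @export
classifier_spec <- function(kind = c("random_forest", "part"), seed = 1L, ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = as.integer(seed), params = list(...)),
            class = "ClassifierSpec")
}

#' Multiclass Matthews correlation coefficient
#'
#' The correlation-form generalization of the MCC to C classes:
#' `(N * sum_k C_kk - sum_k t_k p_k) / sqrt((N^2 - sum_k p_k^2) * (N^2 - sum_k t_k^2))`
#' where `t_k` are true-class totals (row sums) and `p_k` predicted-class
#' totals (column sums). At C = 2 it coincides with the classic binary
#' formula. Returns 0 when either variance term vanishes (e.g. all
#' predictions in one class).
#'
#' @param cm Square confusion matrix of non-negative counts; rows = true
#'   class, columns = predicted class.
#' @return MCC in `[-1, 1]`.
#' @export
multiclass_mcc <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) tfs_error("confusion matrix must be square",
                                      "tfs_dim_error")
  n <- sum(cm)
  if (n == 0) tfs_error("all-zero confusion matrix", "tfs_value_error")
  tk <- rowSums(cm)
  pk <- colSums(cm)
  num <- n * sum(diag(cm)) - sum(tk * pk)
  den2 <- (n^2 - sum(pk^2)) * (n^2 - sum(tk^2))
  if (den2 <= 0) return(0)
  num / sqrt(den2)
}

#' Confusion-matrix accuracies
#'
#' @param cm Confusion matrix (rows = true class).
#' @return List with `overall` (sum of diagonal / N) and `per_class`
#'   (per-class recall; NaN for classes with no cells).
#' @export
confusion_accuracies <- function(cm) {
  cm <- as.matrix(cm)
  list(overall = sum(diag(cm)) / sum(cm),
       per_class = diag(cm) / rowSums(cm))
}

#' Cross-validated evaluation of a classifier on a feature subset
#'
#' Stratified k-fold cross-validation: within every class, cells are dealt
#' into folds from the seed, each cell is predicted exactly once by a model
#' that never saw it, and the pooled out-of-fold predictions form one
#' confusion matrix (class order = the dataset's `class_names`).
#'
#' @param ds_view A `FeatureSubsetView` from [subset_features()].
#' @param spec A `ClassifierSpec`.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return List with `confusion`, `per_class_accuracy`, `overall_accuracy`,
#'   `mcc`.
#' @export
cross_validate <- function(ds_view, spec, folds = 10L, seed = 1L) {
  stopifnot(inherits(ds_view, "FeatureSubsetView"),
            inherits(spec, "ClassifierSpec"))
  ds <- ds_view$parent
  check_trainable(ds)
  y <- dataset_labels(ds)
  sizes <- table(y)
  if (any(sizes < folds)) {
    small <- names(sizes)[which(sizes < folds)[1]]
    tfs_error(sprintf(
      "class '%s' has %d cells, fewer than %d folds; reduce the fold count",
      small, sizes[[small]], folds), "tfs_fold_error")
  }

  X <- view_matrix(ds_view)
  n <- nrow(X)
  fold_id <- integer(n)
  with_local_seed(seed, {
    for (k in seq_along(levels(y))) {
      rows <- which(as.integer(y) == k)
      fold_id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
  })

  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (f in seq_len(folds)) {
    test <- which(fold_id == f)
    train <- which(fold_id != f)
    pred[test] <- fit_predict(spec, X[train, , drop = FALSE], y[train],
                              X[test, , drop = FALSE],
                              view_gene_ids(ds_view),
                              fold_seed = derive_seed(seed, paste0("fold", f)))
  }

  cm <- table(true = y, predicted = pred)
  acc <- confusion_accuracies(cm)
  list(confusion = unclass(cm),
       per_class_accuracy = acc$per_class,
       overall_accuracy = acc$overall,
       mcc = multiclass_mcc(cm))
}

# dispatch a ClassifierSpec to its training routine
fit_predict <- function(spec, Xtr, ytr, Xte, gene_ids, fold_seed) {
  if (spec$kind == "random_forest") {
    num_trees <- spec$params$num_trees %||% 100L
    rf_seed <- as.integer((as.numeric(spec$seed) + fold_seed) %% 2147483647)
    fit <- ranger::ranger(
      x = as.data.frame(Xtr), y = droplevels(ytr), num.trees = num_trees,
      seed = rf_seed, num.threads = 1)
    # predict() draws its own seed from the global RNG unless given one
    p <- stats::predict(fit, data = as.data.frame(Xte), seed = rf_seed,
                        num.threads = 1)$predictions
    factor(as.character(p), levels = levels(ytr))
  } else {
    colnames(Xtr) <- gene_ids
    colnames(Xte) <- gene_ids
    view <- subset_features(
      expression_dataset(Xtr, gene_ids, sprintf("tr%d", seq_len(nrow(Xtr))),
                         as.character(ytr), class_names = levels(ytr)),
      seq_along(gene_ids))
    rs <- train_part(view,
                     prune_cf = spec$params$prune_cf %||% 0.25,
                     min_leaf = spec$params$min_leaf %||% 2L,
                     seed = spec$seed)
    factor(predict_ruleset_matrix(rs, Xte), levels = levels(ytr))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Incremental feature selection over a ranked gene list
#'
#' Evaluates growing prefixes of a ranked feature list — `k = step, 2*step,
#' ... <= max_k` — with [cross_validate()], and reports the curve of MCC and
#' accuracies against `k`. The optimum is the smallest `k` attaining the
#' maximal MCC.
#'
#' @param ds An `ExpressionDataset`.
#' @param ranked A `RankedFeatureList`.
#' @param spec A `ClassifierSpec`.
#' @param step Grid step (default 5).
#' @param max_k Largest prefix size (default: full list length).
#' @param folds Cross-validation folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @return An `IFSCurve`: data frame with columns `k`, `mcc`,
#'   `overall_accuracy` and one `acc_<class>` column per class; attributes
#'   `optimum_k`, `optimum_mcc`, `per_class_at_optimum`, `method`.
#' @export
run_ifs <- function(ds, ranked, spec, step = 5L, max_k = nrow(ranked),
                    folds = 10L, seed = 1L) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            inherits(ranked, "RankedFeatureList"))
  if (step < 1) tfs_error("step must be >= 1", "tfs_param_error")
  if (max_k > nrow(ranked)) {
    tfs_error("max_k exceeds the ranked list length", "tfs_param_error")
  }
  ks <- seq(step, max_k, by = step)
  rows <- vector("list", length(ks))
  per_class <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    view <- subset_features(ds, ranked$feature[seq_len(ks[i])])
    cv <- cross_validate(view, spec, folds = folds, seed = seed)
    rows[[i]] <- data.frame(k = ks[i], mcc = cv$mcc,
                            overall_accuracy = cv$overall_accuracy)
    per_class[[i]] <- cv$per_class_accuracy
  }
  curve <- do.call(rbind, rows)
  pc <- do.call(rbind, per_class)
  colnames(pc) <- paste0("acc_", ds$class_names)
  curve <- cbind(curve, pc)
  rownames(curve) <- NULL

  best <- which(curve$mcc == max(curve$mcc))[1]  # smallest k on ties
  attr(curve, "optimum_k") <- curve$k[best]
  attr(curve, "optimum_mcc") <- curve$mcc[best]
  attr(curve, "per_class_at_optimum") <- pc[best, ]
  attr(curve, "method") <- attr(ranked, "method")
  class(curve) <- c("IFSCurve", class(curve))
  curve
}

#' @export
print.IFSCurve <- function(x, ...) {
  cat(sprintf("IFSCurve (%s ranking): %d grid points; optimum k = %d, MCC = %.3f\n",
              attr(x, "method") %||% "?", nrow(x),
              attr(x, "optimum_k"), attr(x, "optimum_mcc")))
  invisible(x)
}
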