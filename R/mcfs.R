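#' Parameters for Monte Carlo feature selection
#'
#' @param m Number of bootstrap resamples of cells.
#' @param t Number of random feature subsets; one tree is grown per
#'   (bootstrap, subset) combination, `m * t` trees in total.
#' @param s Features per subset; `"auto"` picks
#'   `max(ceiling(sqrt(d)), ceiling(d / 8))` for `d` candidates. Subsets
#'   must be large enough that several informative genes co-occur in one
#'   tree; with many classes, `sqrt(d)` subsets give each tree too little
#'   signal to separate more than a couple of classes.
#' @param u Exponent on the tree's weighted accuracy (default 1).
#' @param v Exponent on the node-sample fraction (default 1).
#' @param wacc Weighted-accuracy flavour: `"balanced"` (mean per-class
#'   recall on out-of-bag cells; robust to the heavy class imbalance of a
#'   tissue atlas) or `"plain"` (overall out-of-bag accuracy).
#' @param min_leaf Minimum cells per leaf when growing trees (default 2).
#' @param seed Integer seed.
#' @return An `MCFSParams` list.
#' @export
mcfs_params <- function(m = 30L, t = 50L, s = "auto", u = 1, v = 1,
                        wacc = c("balanced", "plain"), min_leaf = 2L,
                        seed = 1L) {
  wacc <- match.arg(wacc)
  if (!identical(s, "auto")) {
    if (!is.numeric(s) || s < 1) tfs_error("s must be >= 1 or 'auto'",
                                           "tfs_param_error")
    s <- as.integer(s)
  }
  if (m < 1 || t < 1) tfs_error("m and t must be >= 1", "tfs_param_error")
  structure(list(m = as.integer(m), t = as.integer(t), s = s,
                 u = u, v = v, wacc = wacc, min_leaf = as.integer(min_leaf),
                 seed = as.integer(seed)),
            class = "MCFSParams")
}

#' Relative-importance contribution of one tree
#'
#' For a single decision tree with account `account`, the contribution of a
#' feature to its relative importance is the sum over the tree's nodes that
#' split on the feature of
#' `wAcc^u * IG(node) * (n_node / n_tree)^v`,
#' and 0 when the feature splits no node.
#'
#' @param account A `TreeAccount`: list with `wacc` (number in `[0,1]`),
#'   `n_tree` (training cells in the tree), and `nodes`, a data frame with
#'   columns `feature` (column index split on), `ig` (information gain,
#'   bits) and `n_node` (cells at the node).
#' @param feature Feature (column) index.
#' @param params An `MCFSParams` (only `u` and `v` are used).
#' @return Numeric contribution (>= 0).
#' @examples
#' acct <- list(wacc = 0.8, n_tree = 10,
#'              nodes = data.frame(feature = 3, ig = 0.5, n_node = 10))
#' ri_contribution(acct, 3, mcfs_params())  # 0.8 * 0.5 * 1 = 0.4
#' @export
ri_contribution <- function(account, feature, params = mcfs_params()) {
  nd <- account$nodes
  rows <- nd$feature == feature
  if (!any(rows)) return(0)
  sum(account$wacc^params$u * nd$ig[rows] *
        (nd$n_node[rows] / account$n_tree)^params$v)
}

#' Monte Carlo feature selection ranking
#'
#' Draws `m` class-stratified bootstrap resamples of cells and `t` uniform
#' random `s`-feature subsets, grows one entropy decision tree (to purity,
#' `min_leaf` cells per leaf) for every (bootstrap, subset) combination, and
#' scores each tree's weighted accuracy `wAcc` on that bootstrap's
#' out-of-bag cells. The relative importance of a feature accumulates
#' [ri_contribution()] over all `m * t` trees; features are ranked by
#' decreasing RI with ties broken by original column index.
#'
#' @param ds An `ExpressionDataset` (>= 2 classes).
#' @param features Integer column indices of candidate genes (default: all).
#' @param params An `MCFSParams` from [mcfs_params()].
#' @param keep_accounts Keep the per-tree `TreeAccount`s (for auditing the
#'   RI sum); off by default to save memory.
#' @return A `RankedFeatureList` with attribute `method = "MCFS"` and,
#'   additionally, attributes `ri` (named by gene id, in ranked order —
#'   equal to `score`) and optionally `accounts`.
#' @export
run_mcfs <- function(ds, features = seq_len(ncol(ds$matrix)),
                     params = mcfs_params(), keep_accounts = FALSE) {
  stopifnot(inherits(ds, "ExpressionDataset"), inherits(params, "MCFSParams"))
  check_trainable(ds)
  features <- as.integer(features)
  d <- length(features)
  s <- if (identical(params$s, "auto")) {
    as.integer(max(ceiling(sqrt(d)), ceiling(d / 8)))
  } else {
    params$s
  }
  if (s > d) tfs_error("s exceeds the candidate feature count", "tfs_param_error")

  y <- as.integer(dataset_labels(ds)) - 1L
  nclass <- length(ds$class_names)
  n <- nrow(ds$matrix)
  X <- ds$matrix[, features, drop = FALSE]
  ri <- numeric(d)
  accounts <- if (keep_accounts) vector("list", params$m * params$t) else NULL

  with_local_seed(params$seed, {
    # class-stratified bootstraps: sample with replacement within each class
    class_rows <- split(seq_len(n), y)
    boots <- lapply(seq_len(params$m), function(b) {
      unlist(lapply(class_rows, function(r) {
        r[sample.int(length(r), length(r), replace = TRUE)]
      }), use.names = FALSE)
    })
    subsets <- lapply(seq_len(params$t), function(ss) {
      sort(sample.int(d, s))
    })

    ti <- 0L
    for (b in seq_len(params$m)) {
      rows <- boots[[b]]
      oob <- setdiff(seq_len(n), unique(rows))
      for (tt in seq_len(params$t)) {
        ti <- ti + 1L
        cols <- subsets[[tt]]
        Xs <- X[, cols, drop = FALSE]
        tree <- cpp_grow_tree(Xs, y, rows - 1L, nclass, params$min_leaf)
        wacc <- tree_wacc(tree, Xs, y, oob, nclass, params$wacc)
        internal <- tree$feature > 0
        if (any(internal)) {
          contrib <- wacc^params$u * tree$gain[internal] *
            (tree$n_node[internal] / length(rows))^params$v
          ri_idx <- cols[tree$feature[internal]]
          for (k in seq_along(ri_idx)) {
            ri[ri_idx[k]] <- ri[ri_idx[k]] + contrib[k]
          }
        }
        if (keep_accounts) {
          accounts[[ti]] <- list(
            wacc = wacc, n_tree = length(rows),
            nodes = data.frame(
              feature = features[cols[tree$feature[internal]]],
              ig = tree$gain[internal],
              n_node = tree$n_node[internal]))
        }
      }
    }
  })

  ord <- order(-ri, seq_len(d))
  out <- ranked_feature_list(features[ord], ds$gene_ids[features[ord]],
                             ri[ord], method = "MCFS")
  attr(out, "ri") <- setNames(ri[ord], ds$gene_ids[features[ord]])
  attr(out, "s_used") <- s
  if (keep_accounts) attr(out, "accounts") <- accounts
  out
}

# out-of-bag weighted accuracy of one grown tree
tree_wacc <- function(tree, Xs, y, oob, nclass, flavour) {
  if (length(oob) == 0) return(0)
  pred <- cpp_predict_tree(tree$feature, tree$threshold, tree$left,
                           tree$right, tree$pred,
                           Xs[oob, , drop = FALSE])
  truth <- y[oob]
  if (flavour == "plain") {
    acc <- mean(pred == truth)
  } else {
    recalls <- vapply(sort(unique(truth)), function(k) {
      mean(pred[truth == k] == k)
    }, numeric(1))
    acc <- mean(recalls)
  }
  min(max(acc, 0), 1)
}
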