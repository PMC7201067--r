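#' Importance Z-score
#'
#' The summary Boruta applies to a sequence of per-tree importance scores:
#' the mean divided by its standard error. Degenerate spreads follow the
#' usual conventions: zero spread with positive mean is `+Inf`, with zero
#' mean is `0`, with negative mean `-Inf`.
#'
#' @param importances Numeric vector of per-tree importance scores
#'   (length >= 2).
#' @return A single numeric Z-score.
#' @examples
#' zscore(c(1, 2, 3))  # 2 / (1 / sqrt(3)) = 2 * sqrt(3)
#' @export
zscore <- function(importances) {
  if (length(importances) < 2) {
    tfs_error("zscore needs at least 2 importance values", "tfs_value_error")
  }
  m <- mean(importances)
  s <- stats::sd(importances)
  if (s == 0) {
    return(if (m > 0) Inf else if (m < 0) -Inf else 0)
  }
  m / (s / sqrt(length(importances)))
}

#' Boruta all-relevant feature selection
#'
#' Repeatedly pits every real gene against "shadow" copies whose values are
#' permuted across cells. Each iteration: shadows are drawn fresh, a random
#' forest is fitted on the combined real + shadow matrix, and every real
#' gene whose impurity importance exceeds the maximum shadow importance
#' scores a "hit". Genes with significantly more (fewer) hits than the
#' Binomial(iterations, 1/2) null — two-sided binomial test, Bonferroni over
#' the still-undecided genes — are confirmed (rejected). All genes stay in
#' the model matrix for every iteration, keeping the shadow pool at full
#' width: a shrinking pool would let a gene that correlates with the labels
#' only by chance beat the few remaining shadows almost every round and be
#' falsely confirmed. The loop stops when nothing is tentative or `max_iter`
#' is reached. Tentative leftovers are reported as such and treated as not
#' selected downstream.
#'
#' @param ds An `ExpressionDataset` (>= 2 classes).
#' @param features Integer column indices to screen (default: all genes).
#' @param max_iter Maximum iterations (>= 5; default 100).
#' @param alpha Significance level of the binomial test (default 0.05).
#' @param seed Integer seed controlling permutations and forests.
#' @param num_trees Trees per forest (default 100).
#' @return A `BorutaResult` list: `status` (named factor
#'   confirmed/rejected/tentative per input feature), `hits`,
#'   `iterations` (per-feature iterations participated in),
#'   `shadow_max_trace`, `confirmed` (column indices of confirmed genes,
#'   in input order).
#' @export
run_boruta <- function(ds, features = seq_len(ncol(ds$matrix)),
                       max_iter = 100L, alpha = 0.05, seed = 1L,
                       num_trees = 100L) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  check_trainable(ds)
  features <- as.integer(features)
  if (length(features) < 1) tfs_error("no features to screen", "tfs_index_error")
  if (max_iter < 5) {
    tfs_error("max_iter must be >= 5 (the binomial test has no resolution below that)",
              "tfs_param_error")
  }

  y <- dataset_labels(ds)
  p <- length(features)
  hits <- integer(p)
  iters <- integer(p)
  status <- rep("tentative", p)
  shadow_trace <- numeric(0)
  X <- ds$matrix[, features, drop = FALSE]
  colnames(X) <- sprintf("f%d", seq_len(p))

  with_local_seed(seed, {
    for (it in seq_len(max_iter)) {
      shadow <- apply(X, 2, sample)
      colnames(shadow) <- sprintf("s%d", seq_len(p))
      df <- as.data.frame(cbind(X, shadow))
      fit <- ranger::ranger(
        x = df, y = y, num.trees = num_trees, importance = "impurity",
        seed = sample.int(.Machine$integer.max, 1), num.threads = 1)
      imp <- fit$variable.importance
      real_imp <- imp[seq_len(p)]
      shadow_max <- max(imp[-seq_len(p)])
      shadow_trace[it] <- shadow_max
      hits <- hits + as.integer(real_imp > shadow_max)
      iters[] <- it

      und <- which(status == "tentative")
      if (it >= 5 && length(und)) {
        thr <- alpha / length(und)
        for (i in und) {
          p_hi <- pbinom(hits[i] - 1L, iters[i], 0.5, lower.tail = FALSE)
          p_lo <- pbinom(hits[i], iters[i], 0.5)
          if (2 * p_hi <= thr) {
            status[i] <- "confirmed"
          } else if (2 * p_lo <= thr) {
            status[i] <- "rejected"
          }
        }
      }
      if (!any(status == "tentative")) break
    }
  })

  status <- factor(status, levels = c("confirmed", "rejected", "tentative"))
  names(status) <- ds$gene_ids[features]
  names(hits) <- names(status)
  structure(list(status = status, hits = hits, iterations = iters,
                 shadow_max_trace = shadow_trace,
                 features = features,
                 confirmed = features[status == "confirmed"]),
            class = "BorutaResult")
}

#' @export
print.BorutaResult <- function(x, ...) {
  tab <- table(x$status)
  cat(sprintf("BorutaResult: %d confirmed, %d rejected, %d tentative (%d iterations)\n",
              tab[["confirmed"]], tab[["rejected"]], tab[["tentative"]],
              max(x$iterations)))
  invisible(x)
}
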