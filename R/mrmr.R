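#' Rank genes by minimum redundancy, maximum relevance (mRMR)
#'
#' Greedy difference-form (MID) mRMR: the first gene picked maximizes MI to
#' the tissue label; every later step appends the candidate maximizing
#' `MI(candidate, labels) - mean MI(candidate, already-selected)`. All MI
#' values use the same rank-based equal-frequency binning as the MI screen
#' (gene-gene MI discretizes both genes). Ties break to the lower original
#' column index; the procedure is fully deterministic.
#'
#' @param ds An `ExpressionDataset` (>= 2 classes).
#' @param features Integer column indices of candidate genes (default: all).
#' @param bins Number of expression bins (default 5).
#' @return A `RankedFeatureList`: data frame with columns `rank`,
#'   `feature` (original column index), `gene_id`, `score` (the selection
#'   criterion value at pick time); attribute `method = "mRMR"`.
#' @export
rank_mrmr <- function(ds, features = seq_len(ncol(ds$matrix)), bins = 5L) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  check_trainable(ds)
  features <- as.integer(features)
  if (length(features) < 1) tfs_error("empty candidate set", "tfs_index_error")

  d <- length(features)
  y <- as.integer(dataset_labels(ds))
  codes <- lapply(features, function(j) discretize_ef(ds$matrix[, j], bins))
  relevance <- vapply(codes, function(b) mi_from_codes(b, y), numeric(1))

  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(d)
  red_sum <- numeric(d)  # sum of MI(candidate, selected so far)

  for (step in seq_len(d)) {
    crit <- if (step == 1) {
      relevance[remaining]
    } else {
      relevance[remaining] - red_sum[remaining] / (step - 1)
    }
    pick <- remaining[which.max(crit)]  # which.max: first max = lowest index
    selected[step] <- pick
    scores[step] <- max(crit)
    remaining <- remaining[remaining != pick]
    if (length(remaining)) {
      red_sum[remaining] <- red_sum[remaining] + vapply(
        remaining, function(i) mi_from_codes(codes[[i]], codes[[pick]]),
        numeric(1))
    }
  }

  ranked_feature_list(features[selected], ds$gene_ids[features[selected]],
                      scores, method = "mRMR")
}

# shared constructor for the two ranking methods
ranked_feature_list <- function(feature, gene_id, score, method) {
  out <- data.frame(rank = seq_along(feature), feature = feature,
                    gene_id = gene_id, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("RankedFeatureList", class(out))
  out
}

#' @export
print.RankedFeatureList <- function(x, ...) {
  cat(sprintf("RankedFeatureList (%s): %d features\n",
              attr(x, "method"), nrow(x)))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}
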