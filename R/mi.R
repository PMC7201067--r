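#' Equal-frequency discretization by rank
#'
#' Assigns each value to one of at most `bins` rank-quantile bins. Tied
#' values always land in the same bin (ties share the maximal rank), so the
#' binning depends only on the ordering of the values and is invariant under
#' any strictly monotone transform — a robust choice for dropout-heavy
#' single-cell expression where a large mass sits exactly at zero.
#'
#' @param values Numeric vector.
#' @param bins Positive integer, maximum number of bins.
#' @return Integer bin codes in `1..bins`.
#' @export
discretize_ef <- function(values, bins) {
  stopifnot(is.numeric(values), bins >= 1)
  n <- length(values)
  as.integer(ceiling(bins * rank(values, ties.method = "max") / n))
}

# MI in bits between two integer code vectors, plug-in estimator.
mi_from_codes <- function(bx, by) {
  tab <- table(bx, by)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

#' Mutual information between one gene and the cell labels
#'
#' Discretizes the expression values into at most `bins` equal-frequency
#' intervals (see [discretize_ef()]) and computes the plug-in mutual
#' information of the joint empirical frequency table with the class labels,
#' in bits (`0 * log 0 = 0`).
#'
#' @param values Per-cell expression of one gene (finite, length >= 2).
#' @param labels Per-cell class labels (same length).
#' @param bins Positive integer number of expression bins (default 5).
#' @return MI estimate in bits (non-negative).
#' @examples
#' estimate_mi(c(0, 0, 5, 5), c("A", "A", "B", "B"), bins = 2)  # 1 bit
#' @export
estimate_mi <- function(values, labels, bins = 5L) {
  if (length(values) != length(labels)) {
    tfs_error("values and labels differ in length", "tfs_dim_error")
  }
  if (length(values) < 2) tfs_error("need at least 2 cells", "tfs_dim_error")
  if (any(!is.finite(values))) {
    tfs_error("non-finite expression value", "tfs_value_error")
  }
  bx <- discretize_ef(values, bins)
  mi_from_codes(bx, as.integer(factor(labels)))
}

#' Screen genes by mutual information to the tissue label
#'
#' Scores every gene with [estimate_mi()] against the labels and keeps those
#' whose MI strictly exceeds `threshold` (default 0.02 bits). Genes are never
#' reordered, only filtered. An empty survivor set is legal and flagged with
#' a warning rather than an error.
#'
#' @param ds An `ExpressionDataset`.
#' @param threshold MI cutoff in bits; survivors satisfy `mi > threshold`.
#' @param bins Number of expression bins passed to [estimate_mi()].
#' @return An `MIResult` list: `scores` (named numeric, per gene),
#'   `bins`, `threshold`, `surviving` (integer column indices).
#' @export
mi_screen <- function(ds, threshold = 0.02, bins = 5L) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  y <- as.integer(dataset_labels(ds))
  scores <- vapply(seq_len(ncol(ds$matrix)), function(j) {
    mi_from_codes(discretize_ef(ds$matrix[, j], bins), y)
  }, numeric(1))
  names(scores) <- ds$gene_ids
  surviving <- which(scores > threshold)
  res <- structure(list(scores = scores, bins = as.integer(bins),
                        threshold = threshold, surviving = surviving),
                   class = "MIResult")
  if (length(surviving) == 0) {
    warning("MI screen left no surviving genes", call. = FALSE)
  }
  res
}

#' @export
print.MIResult <- function(x, ...) {
  cat(sprintf("MIResult: %d / %d genes above %.3g bits (%d bins)\n",
              length(x$surviving), length(x$scores), x$threshold, x$bins))
  invisible(x)
}
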