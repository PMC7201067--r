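#' Hypergeometric upper-tail overlap probability
#'
#' Probability of observing at least `k` common elements between a set of
#' size `K` and a set of size `n` drawn from a universe of size `N`:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Computed through the
#' log-space distribution function for numerical stability, one-sided in
#' the over-enrichment direction.
#'
#' @param N Universe size.
#' @param K Size of set A.
#' @param n Size of set B.
#' @param k Observed overlap.
#' @return The p-value in `[0, 1]`.
#' @examples
#' hypergeom_tail(10, 5, 4, 4)  # choose(5,4)/choose(10,4) = 5/210
#' @export
hypergeom_tail <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals < 0) || any(vals != floor(vals))) {
    tfs_error("counts must be non-negative integers", "tfs_value_error")
  }
  if (K > N || n > N || k > min(K, n)) {
    tfs_error(sprintf(
      "inconsistent counts: k=%d, K=%d, n=%d, N=%d (need k <= min(K, n) <= N)",
      k, K, n, N), "tfs_value_error")
  }
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Overlap of the top prefixes of two ranked gene lists
#'
#' Intersects the top-`topA` genes of one ranking with the top-`topB` genes
#' of another (e.g. mRMR vs. MCFS) and scores the overlap against the
#' hypergeometric null over a `universe` of candidate genes.
#'
#' @param listA,listB `RankedFeatureList`s over the same gene universe.
#' @param topA,topB Prefix sizes.
#' @param universe Universe size `N` (e.g. the post-filter gene pool).
#' @return An `OverlapReport`: list with `size_a`, `size_b`, `universe`,
#'   `intersection` (gene ids), `overlap`, `p_value`.
#' @export
overlap_report <- function(listA, topA, listB, topB,
                           universe = length(union(listA$gene_id,
                                                   listB$gene_id))) {
  stopifnot(inherits(listA, "RankedFeatureList"),
            inherits(listB, "RankedFeatureList"))
  if (topA > nrow(listA) || topB > nrow(listB)) {
    tfs_error("top prefix exceeds list length", "tfs_param_error")
  }
  if (!setequal(listA$gene_id, listB$gene_id)) {
    tfs_error("the two rankings cover different gene universes",
              "tfs_id_error")
  }
  a <- listA$gene_id[seq_len(topA)]
  b <- listB$gene_id[seq_len(topB)]
  common <- intersect(a, b)
  structure(list(size_a = topA, size_b = topB, universe = universe,
                 intersection = common, overlap = length(common),
                 p_value = hypergeom_tail(universe, topA, topB,
                                          length(common))),
            class = "OverlapReport")
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat(sprintf(
    "OverlapReport: |A|=%d, |B|=%d, universe=%d, overlap=%d, p=%.3g\n",
    x$size_a, x$size_b, x$universe, x$overlap, x$p_value))
  invisible(x)
}
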