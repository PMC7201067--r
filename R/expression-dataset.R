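#' Construct an expression dataset
#'
#' The core container consumed by every stage of the pipeline: a non-negative
#' cells x genes expression matrix (log-like scale, unitless) together with
#' per-cell tissue labels. Class names are ordered by first appearance in the
#' labels, and every confusion matrix downstream uses that order.
#'
#' @param matrix Numeric matrix, cells as rows, genes as columns; all values
#'   finite and non-negative.
#' @param gene_ids Character vector of unique gene identifiers, one per column.
#' @param cell_ids Character vector of unique cell identifiers, one per row.
#' @param labels Character vector of tissue labels, one per cell.
#' @param class_names Optional character vector fixing the class order;
#'   defaults to order of first appearance in `labels`.
#' @return An object of class `ExpressionDataset`.
#' @examples
#' m <- matrix(c(0, 1, 2, 3, 4, 5), nrow = 3)
#' ds <- expression_dataset(m, c("g1", "g2"), c("c1", "c2", "c3"),
#'                          c("A", "A", "B"))
#' ds$class_names
#' @export
expression_dataset <- function(matrix, gene_ids, cell_ids, labels,
                               class_names = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  labels <- as.character(labels)

  if (nrow(matrix) != length(cell_ids)) {
    tfs_error(sprintf(
      "matrix has %d rows but %d cell ids (cell axis mismatch)",
      nrow(matrix), length(cell_ids)), "tfs_dim_error")
  }
  if (ncol(matrix) != length(gene_ids)) {
    tfs_error(sprintf(
      "matrix has %d columns but %d gene ids (gene axis mismatch)",
      ncol(matrix), length(gene_ids)), "tfs_dim_error")
  }
  if (length(labels) != length(cell_ids)) {
    tfs_error(sprintf(
      "%d labels for %d cells (label axis mismatch)",
      length(labels), length(cell_ids)), "tfs_dim_error")
  }
  if (anyDuplicated(gene_ids)) tfs_error("gene ids must be unique", "tfs_id_error")
  if (anyDuplicated(cell_ids)) tfs_error("cell ids must be unique", "tfs_id_error")

  bad <- which(!is.finite(matrix) | matrix < 0)
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(matrix)) + 1
    j <- ((bad[1] - 1) %/% nrow(matrix)) + 1
    tfs_error(sprintf(
      "negative or non-finite expression value at cell %d (%s), gene %d (%s)",
      i, cell_ids[i], j, gene_ids[j]), "tfs_value_error")
  }

  if (is.null(class_names)) {
    class_names <- unique(labels)
  } else {
    class_names <- as.character(class_names)
    if (!all(labels %in% class_names)) {
      tfs_error("labels contain classes absent from class_names", "tfs_label_error")
    }
  }

  dimnames(matrix) <- list(cell_ids, gene_ids)
  structure(
    list(matrix = matrix, gene_ids = gene_ids, cell_ids = cell_ids,
         labels = labels, class_names = class_names),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d cells x %d genes, %d classes\n",
              nrow(x$matrix), ncol(x$matrix), length(x$class_names)))
  cat("classes:", paste(utils::head(x$class_names, 6), collapse = ", "),
      if (length(x$class_names) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$matrix)

#' Labels as a factor in the dataset's canonical class order
#' @param ds An `ExpressionDataset`.
#' @return A factor with levels `ds$class_names`.
#' @export
dataset_labels <- function(ds) factor(ds$labels, levels = ds$class_names)

#' Select a subset of genes as a lightweight view
#'
#' Creates a `FeatureSubsetView` exposing the requested columns in the given
#' order; cell order and labels are untouched. This is the object the
#' incremental feature selection loop iterates over ("top k features").
#'
#' @param ds An `ExpressionDataset`.
#' @param indices Integer column indices, unique and in range.
#' @return A `FeatureSubsetView`.
#' @export
subset_features <- function(ds, indices) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  indices <- as.integer(indices)
  if (anyNA(indices) || any(indices < 1L) || any(indices > ncol(ds$matrix))) {
    tfs_error("feature index out of range", "tfs_index_error")
  }
  if (anyDuplicated(indices)) {
    tfs_error("duplicated feature index", "tfs_index_error")
  }
  structure(list(parent = ds, feature_indices = indices),
            class = "FeatureSubsetView")
}

#' @export
print.FeatureSubsetView <- function(x, ...) {
  cat(sprintf("FeatureSubsetView: %d of %d genes, %d cells\n",
              length(x$feature_indices), ncol(x$parent$matrix),
              nrow(x$parent$matrix)))
  invisible(x)
}

#' Materialize the expression matrix of a view
#' @param view A `FeatureSubsetView`.
#' @return Numeric matrix cells x selected genes.
#' @export
view_matrix <- function(view) {
  stopifnot(inherits(view, "FeatureSubsetView"))
  view$parent$matrix[, view$feature_indices, drop = FALSE]
}

#' Gene identifiers of a view, in view order
#' @param view A `FeatureSubsetView`.
#' @return Character vector.
#' @export
view_gene_ids <- function(view) view$parent$gene_ids[view$feature_indices]

# internal: require >= 2 classes for any training operation
check_trainable <- function(ds) {
  if (length(unique(ds$labels)) < 2) {
    tfs_error("at least 2 classes are required for training", "tfs_label_error")
  }
}
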