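#' Write an expression dataset to disk
#'
#' Emits the matrix plus gene/cell/label sidecars under a common path prefix.
#' Two formats are supported: MatrixMarket coordinate (`mtx`) with one-id-per-
#' line `genes.tsv` / `cells.tsv` sidecars, and a dense CSV (`csv`) whose
#' header holds gene ids and whose first column holds cell ids. Labels are
#' always written as `labels.tsv` with lines `cell_id<TAB>tissue`.
#' [load_dataset()] inverts the output exactly.
#'
#' @param ds An `ExpressionDataset`.
#' @param out_prefix Path prefix; files are written as `<prefix>.<name>`.
#' @param fmt `"mtx"` or `"csv"`.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_dataset <- function(ds, out_prefix, fmt = c("mtx", "csv")) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!is.character(fmt) || !fmt[1] %in% c("mtx", "csv")) {
    tfs_error(sprintf("unsupported format '%s' (use mtx or csv)",
                      as.character(fmt[1])), "tfs_format_error")
  }
  fmt <- fmt[1]
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)

  labels_path <- paste0(out_prefix, ".labels.tsv")
  write.table(data.frame(cell = ds$cell_ids, tissue = ds$labels),
              labels_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  if (fmt == "mtx") {
    paths <- c(matrix = paste0(out_prefix, ".mtx"),
               genes = paste0(out_prefix, ".genes.tsv"),
               cells = paste0(out_prefix, ".cells.tsv"),
               labels = labels_path)
    sp <- Matrix::Matrix(ds$matrix, sparse = TRUE)
    dimnames(sp) <- NULL
    Matrix::writeMM(sp, paths[["matrix"]])
    writeLines(ds$gene_ids, paths[["genes"]])
    writeLines(ds$cell_ids, paths[["cells"]])
  } else {
    paths <- c(matrix = paste0(out_prefix, ".csv"), labels = labels_path)
    df <- as.data.frame(ds$matrix)
    names(df) <- ds$gene_ids
    df <- cbind(cell_id = ds$cell_ids, df)
    write.csv(df, paths[["matrix"]], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Load an expression dataset from disk
#'
#' Reads a matrix and its sidecars back into a validated
#' [expression_dataset()]. MTX files stored either cells x genes or
#' genes x cells are accepted: orientation is disambiguated against the
#' sidecar lengths and normalized to cells-as-rows.
#'
#' @param matrix_path Path to the `.mtx` or `.csv` matrix file.
#' @param genes_path Path to the gene-id sidecar (one id per line; `mtx` only).
#' @param cells_path Path to the cell-id sidecar (one id per line; `mtx` only).
#' @param labels_path Path to the labels TSV (`cell_id<TAB>tissue`).
#' @param fmt `"mtx"` or `"csv"`.
#' @return An `ExpressionDataset`.
#' @export
load_dataset <- function(matrix_path, genes_path = NULL, cells_path = NULL,
                         labels_path, fmt = c("mtx", "csv")) {
  if (!is.character(fmt) || !fmt[1] %in% c("mtx", "csv")) {
    tfs_error(sprintf("unsupported format '%s' (use mtx or csv)",
                      as.character(fmt[1])), "tfs_format_error")
  }
  fmt <- fmt[1]
  for (p in c(matrix_path, labels_path)) {
    if (!file.exists(p)) tfs_error(paste("file not found:", p), "tfs_io_error")
  }

  lab <- read.delim(labels_path, header = FALSE, sep = "\t",
                    colClasses = "character", col.names = c("cell", "tissue"))

  if (fmt == "mtx") {
    for (p in c(genes_path, cells_path)) {
      if (is.null(p) || !file.exists(p)) {
        tfs_error("mtx input requires genes and cells sidecars", "tfs_io_error")
      }
    }
    gene_ids <- readLines(genes_path)
    cell_ids <- readLines(cells_path)
    m <- as.matrix(Matrix::readMM(matrix_path))
    if (nrow(m) == length(cell_ids) && ncol(m) == length(gene_ids)) {
      # cells x genes already
    } else if (nrow(m) == length(gene_ids) && ncol(m) == length(cell_ids)) {
      m <- t(m)
    } else {
      tfs_error(sprintf(
        "matrix is %d x %d but sidecars declare %d cells and %d genes",
        nrow(m), ncol(m), length(cell_ids), length(gene_ids)),
        "tfs_dim_error")
    }
  } else {
    df <- read.csv(matrix_path, check.names = FALSE,
                   colClasses = c("character"))
    cell_ids <- df[[1]]
    gene_ids <- names(df)[-1]
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
  }

  miss <- setdiff(cell_ids, lab$cell)
  if (length(miss)) {
    tfs_error(paste("labels file has no entry for cell:", miss[1]),
              "tfs_label_error")
  }
  extra <- setdiff(lab$cell, cell_ids)
  if (length(extra)) {
    tfs_error(paste("unknown cell id in labels file:", extra[1]),
              "tfs_label_error")
  }
  labels <- lab$tissue[match(cell_ids, lab$cell)]
  # class order: first appearance in the labels FILE, not the matrix
  expression_dataset(m, gene_ids, cell_ids, labels,
                     class_names = unique(lab$tissue))
}
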