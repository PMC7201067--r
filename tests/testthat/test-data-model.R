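test_that("constructor validates dimensions, values and ids", {
  ds <- tiny_dataset()
  expect_s3_class(ds, "ExpressionDataset")
  expect_equal(dim(ds), c(3, 2))
  expect_equal(ds$class_names, c("A", "B"))

  m <- matrix(0, 3, 2)
  expect_error(expression_dataset(m, c("g1", "g2"), c("c1", "c2", "c3", "c4"),
                                  rep("A", 4)),
               class = "tfs_dim_error")
  expect_error(expression_dataset(matrix(c(0, -1, 0, 0, 0, 0), 3, 2),
                                  c("g1", "g2"), c("c1", "c2", "c3"),
                                  c("A", "A", "B")),
               class = "tfs_value_error")
  expect_error(expression_dataset(matrix(c(0, NA, 0, 0, 0, 0), 3, 2),
                                  c("g1", "g2"), c("c1", "c2", "c3"),
                                  c("A", "A", "B")),
               class = "tfs_value_error")
  expect_error(expression_dataset(m, c("g1", "g1"), c("c1", "c2", "c3"),
                                  c("A", "A", "B")),
               class = "tfs_id_error")
})

test_that("class names follow first appearance in the labels", {
  m <- matrix(0, 4, 1)
  ds <- expression_dataset(m, "g1", paste0("c", 1:4), c("Z", "A", "Z", "B"))
  expect_equal(ds$class_names, c("Z", "A", "B"))
  expect_equal(levels(dataset_labels(ds)), c("Z", "A", "B"))
})

test_that("subset_features views select columns in order and validate indices", {
  ds <- expression_dataset(matrix(1:9, 3, 3), c("g0", "g1", "g2"),
                           c("c1", "c2", "c3"), c("A", "A", "B"))
  v <- subset_features(ds, c(3, 1))
  expect_equal(view_gene_ids(v), c("g2", "g0"))
  expect_equal(view_matrix(v), ds$matrix[, c(3, 1)])

  v_all <- subset_features(ds, 1:3)
  expect_equal(view_matrix(v_all), ds$matrix)

  expect_error(subset_features(ds, c(1, 1)), class = "tfs_index_error")
  expect_error(subset_features(ds, 4), class = "tfs_index_error")
})

test_that("write/load round-trips exactly in both formats", {
  specs <- list(
    synthetic_spec(n_classes = 2, class_sizes = c(6, 9), markers_per_class = 2,
                   n_noise_genes = 5, dropout_rate = 0.5, seed = 3),
    synthetic_spec(n_classes = 3, class_sizes = c(4, 4, 4),
                   markers_per_class = 1, n_noise_genes = 0, seed = 4))
  for (spec in specs) {
    ds <- generate_dataset(spec)$dataset
    for (fmt in c("mtx", "csv")) {
      prefix <- file.path(withr::local_tempdir(), "rt")
      paths <- write_dataset(ds, prefix, fmt)
      back <- load_dataset(paths[["matrix"]], paths["genes"], paths["cells"],
                           paths[["labels"]], fmt = fmt)
      expect_equal(back$matrix, ds$matrix, tolerance = 1e-12)
      expect_identical(back$gene_ids, ds$gene_ids)
      expect_identical(back$cell_ids, ds$cell_ids)
      expect_identical(back$labels, ds$labels)
      expect_identical(back$class_names, ds$class_names)
    }
  }
})

test_that("MTX orientation is disambiguated by sidecar lengths", {
  ds <- generate_dataset(synthetic_spec(n_classes = 2, class_sizes = c(5, 7),
                                        markers_per_class = 1,
                                        n_noise_genes = 2, seed = 9))$dataset
  prefix <- file.path(withr::local_tempdir(), "tr")
  paths <- write_dataset(ds, prefix, "mtx")
  # rewrite the matrix transposed (genes x cells, the other common dialect)
  sp <- Matrix::Matrix(t(ds$matrix), sparse = TRUE)
  Matrix::writeMM(sp, paths[["matrix"]])
  back <- load_dataset(paths[["matrix"]], paths["genes"], paths["cells"],
                       paths[["labels"]], fmt = "mtx")
  expect_equal(back$matrix, ds$matrix, tolerance = 1e-12)
})

test_that("sparse MTX stores exactly the nonzero entries", {
  ds <- generate_dataset(synthetic_spec(n_classes = 2, class_sizes = c(20, 20),
                                        markers_per_class = 2,
                                        n_noise_genes = 10,
                                        dropout_rate = 0.5, seed = 5))$dataset
  prefix <- file.path(withr::local_tempdir(), "sp")
  paths <- write_dataset(ds, prefix, "mtx")
  lines <- readLines(paths[["matrix"]], n = 5)
  dims <- lines[!startsWith(lines, "%")][1]
  stored_nnz <- as.integer(strsplit(trimws(dims), "\\s+")[[1]][3])
  expect_equal(stored_nnz, sum(ds$matrix != 0))
})

test_that("degenerate and invalid I/O cases are handled", {
  ds0 <- expression_dataset(matrix(0, 3, 0), character(0),
                            c("c1", "c2", "c3"), c("A", "A", "B"))
  prefix <- file.path(withr::local_tempdir(), "zero")
  paths <- write_dataset(ds0, prefix, "mtx")
  back <- load_dataset(paths[["matrix"]], paths["genes"], paths["cells"],
                       paths[["labels"]], fmt = "mtx")
  expect_equal(ncol(back$matrix), 0)

  expect_error(write_dataset(ds0, prefix, "xlsx"), class = "tfs_format_error")

  # labels file missing one cell
  ds <- tiny_dataset()
  prefix2 <- file.path(withr::local_tempdir(), "bad")
  paths2 <- write_dataset(ds, prefix2, "csv")
  writeLines("c1\tA", paths2[["labels"]])
  expect_error(load_dataset(paths2[["matrix"]], labels_path = paths2[["labels"]],
                            fmt = "csv"),
               class = "tfs_label_error")
})

test_that("permuting cells together with labels gives the same data up to order", {
  ds <- generate_dataset(synthetic_spec(n_classes = 3, class_sizes = c(5, 6, 7),
                                        markers_per_class = 1,
                                        n_noise_genes = 3, seed = 2))$dataset
  perm <- withr::with_seed(1, sample(nrow(ds$matrix)))
  ds2 <- expression_dataset(ds$matrix[perm, ], ds$gene_ids,
                            ds$cell_ids[perm], ds$labels[perm],
                            class_names = ds$class_names)
  ord <- match(ds$cell_ids, ds2$cell_ids)
  expect_equal(ds2$matrix[ord, ], ds$matrix)
  expect_identical(ds2$labels[ord], ds$labels)
})
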