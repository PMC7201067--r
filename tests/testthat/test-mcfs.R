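test_that("RI contribution evaluates the weighted per-node sum", {
  acct <- list(wacc = 0.8, n_tree = 10,
               nodes = data.frame(feature = 3L, ig = 0.5, n_node = 10L))
  expect_equal(ri_contribution(acct, 3, mcfs_params()), 0.8 * 0.5 * 1)
  expect_equal(ri_contribution(acct, 5, mcfs_params()), 0)

  acct2 <- list(wacc = 0.8, n_tree = 10,
                nodes = data.frame(feature = 3L, ig = 0.5, n_node = 5L))
  expect_equal(ri_contribution(acct2, 3, mcfs_params(v = 2)),
               0.8 * 0.5 * 0.25)
  expect_equal(ri_contribution(acct2, 3, mcfs_params(u = 2, v = 1)),
               0.8^2 * 0.5 * 0.5)

  # several nodes on the same feature accumulate
  acct3 <- list(wacc = 0.5, n_tree = 8,
                nodes = data.frame(feature = c(1L, 2L, 1L),
                                   ig = c(1, 0.25, 0.5),
                                   n_node = c(8L, 4L, 2L)))
  expect_equal(ri_contribution(acct3, 1, mcfs_params()),
               0.5 * (1 * 1 + 0.5 * 0.25))
})

test_that("a feature that enters no subset has RI exactly zero", {
  g <- generate_dataset(synthetic_spec(n_classes = 2, class_sizes = c(30, 30),
                                       markers_per_class = 1,
                                       n_noise_genes = 8, seed = 3))
  # s = 1 and t = 1: only one feature is ever drawn
  r <- run_mcfs(g$dataset, params = mcfs_params(m = 2, t = 1, s = 1, seed = 5))
  expect_equal(sum(r$score > 0) <= 1, TRUE)
  expect_gte(min(r$score), 0)
  # zero-RI features rank after all positive-RI features
  if (any(r$score > 0)) {
    expect_true(max(which(r$score > 0)) < min(which(r$score == 0)))
  }
})

test_that("total RI is conserved against the per-tree accounts", {
  g <- generate_dataset(synthetic_spec(n_classes = 3,
                                       class_sizes = c(25, 25, 25),
                                       markers_per_class = 2,
                                       n_noise_genes = 10, seed = 9))
  params <- mcfs_params(m = 4, t = 6, s = 5, seed = 11)
  r <- run_mcfs(g$dataset, params = params, keep_accounts = TRUE)
  accounts <- attr(r, "accounts")
  expect_length(accounts, 4 * 6)
  total_from_accounts <- sum(vapply(accounts, function(a) {
    if (nrow(a$nodes) == 0) return(0)
    sum(a$wacc^params$u * a$nodes$ig * (a$nodes$n_node / a$n_tree)^params$v)
  }, numeric(1)))
  expect_equal(sum(r$score), total_from_accounts, tolerance = 1e-9)

  # per-feature: ranked RI equals the sum of per-account contributions
  for (f in r$feature[c(1, 5, 9)]) {
    expect_equal(r$score[r$feature == f],
                 sum(vapply(accounts, ri_contribution, numeric(1),
                            feature = f, params = params)),
                 tolerance = 1e-9)
  }
})

test_that("single full tree reproduces the hand-walked RI sum", {
  g <- generate_dataset(synthetic_spec(n_classes = 2, class_sizes = c(10, 10),
                                       markers_per_class = 1,
                                       n_noise_genes = 3, effect_size = 3,
                                       dropout_rate = 0, seed = 4))
  params <- mcfs_params(m = 1, t = 1, s = 5, seed = 2)
  r <- run_mcfs(g$dataset, params = params, keep_accounts = TRUE)
  acct <- attr(r, "accounts")[[1]]
  for (i in seq_len(nrow(r))) {
    expect_equal(r$score[i], ri_contribution(acct, r$feature[i], params),
                 tolerance = 1e-12)
  }
})

test_that("planted markers rise to the top of the MCFS ranking", {
  spec <- synthetic_spec(n_classes = 5, class_sizes = rep(80, 5),
                         markers_per_class = 4, n_noise_genes = 100,
                         effect_size = 2, seed = 2)
  g <- generate_dataset(spec)
  r <- run_mcfs(g$dataset, params = mcfs_params(m = 20, t = 30, seed = 2))
  expect_gte(sum(r$feature[1:40] <= 20), 18)
})

test_that("with permuted labels former markers hold no rank advantage", {
  spec <- synthetic_spec(n_classes = 3, class_sizes = rep(60, 3),
                         markers_per_class = 3, n_noise_genes = 40,
                         effect_size = 2, seed = 6)
  g <- generate_dataset(spec)
  perm <- withr::with_seed(123, sample(g$dataset$labels))
  null_ds <- expression_dataset(g$dataset$matrix, g$dataset$gene_ids,
                                g$dataset$cell_ids, perm,
                                class_names = g$dataset$class_names)
  r <- run_mcfs(null_ds, params = mcfs_params(m = 10, t = 20, seed = 6))
  marker_ranks <- match(1:9, r$feature)
  # rank-sum test against uniformity over the 49 features
  pv <- stats::wilcox.test(marker_ranks, setdiff(1:49, marker_ranks))$p.value
  expect_gt(pv, 0.01)
})

test_that("invalid subset sizes are rejected", {
  g <- generate_dataset(synthetic_spec(n_classes = 2, class_sizes = c(10, 10),
                                       markers_per_class = 1,
                                       n_noise_genes = 3, seed = 1))
  expect_error(run_mcfs(g$dataset, params = mcfs_params(s = 99)),
               class = "tfs_param_error")
  expect_error(mcfs_params(m = 0), class = "tfs_param_error")
})
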