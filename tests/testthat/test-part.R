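mk_xy <- function(values, labels) {
  X <- matrix(values, ncol = 1, dimnames = list(NULL, "gene1"))
  list(X = X, y = factor(labels))
}

test_that("pure and degenerate instance sets give condition-free rules", {
  d <- mk_xy(c(1, 2, 3, 4), c("A", "A", "A", "A"))
  pt <- build_partial_tree(d$X, d$y)
  expect_equal(nrow(pt$rule$conditions), 0)
  expect_equal(pt$rule$class, "A")
  expect_equal(pt$rule$coverage, 4)
  expect_equal(sort(pt$matched), 1:4)

  d2 <- mk_xy(c(1, 2, 8, 9), c("A", "A", "B", "B"))
  pt2 <- build_partial_tree(d2$X, d2$y, min_leaf = 10L)
  expect_equal(nrow(pt2$rule$conditions), 0)
  expect_equal(pt2$rule$coverage, 4)

  expect_error(build_partial_tree(d$X[0, , drop = FALSE], factor(character())),
               class = "tfs_value_error")
})

test_that("a clean two-class threshold is found at the midpoint", {
  d <- mk_xy(c(1, 2, 8, 9), c("A", "A", "B", "B"))
  pt <- build_partial_tree(d$X, d$y)
  expect_equal(nrow(pt$rule$conditions), 1)
  expect_equal(pt$rule$conditions$thr, 5)
  expect_equal(pt$rule$coverage, 2)
  expect_true(pt$rule$class %in% c("A", "B"))
  # the matched side agrees with the rule's class
  expect_equal(length(pt$matched), 2)
})

test_that("separable classes yield few rules with perfect training accuracy", {
  # three classes in disjoint value ranges of one gene
  vals <- c(runif(20, 0, 1), runif(20, 4, 5), runif(20, 8, 9))
  labs <- rep(c("A", "B", "C"), each = 20)
  ds <- expression_dataset(matrix(vals, ncol = 1), "g1",
                           sprintf("c%d", 1:60), labs)
  rs <- train_part(subset_features(ds, 1L))
  expect_lte(length(rs$rules), 3)
  correct <- sum(vapply(rs$rules, function(r) r$correct, numeric(1))) +
    rs$default_correct
  expect_equal(correct, 60)
})

test_that("first-match coverage counts always total the training size", {
  g <- generate_dataset(synthetic_spec(n_classes = 3,
                                       class_sizes = c(40, 30, 20),
                                       markers_per_class = 2,
                                       n_noise_genes = 6, seed = 12))
  rs <- train_part(subset_features(g$dataset,
                                   seq_len(ncol(g$dataset$matrix))))
  total <- sum(vapply(rs$rules, function(r) r$coverage, numeric(1))) +
    rs$default_coverage
  expect_equal(total, nrow(g$dataset$matrix))
})

test_that("rule-set prediction replays the stored training counts", {
  g <- generate_dataset(synthetic_spec(n_classes = 3,
                                       class_sizes = c(30, 30, 30),
                                       markers_per_class = 2,
                                       n_noise_genes = 5, seed = 13))
  view <- subset_features(g$dataset, seq_len(ncol(g$dataset$matrix)))
  rs <- train_part(view)
  X <- view_matrix(view)
  remaining <- rep(TRUE, nrow(X))
  for (r in rs$rules) {
    m <- remaining
    for (i in seq_len(nrow(r$conditions))) {
      v <- X[, r$conditions$gene[i]]
      m <- m & if (r$conditions$op[i] == "<=") v <= r$conditions$thr[i] else
        v > r$conditions$thr[i]
    }
    expect_equal(sum(m), r$coverage)
    expect_equal(sum(g$dataset$labels[m] == r$class), r$correct)
    remaining <- remaining & !m
  }
  expect_equal(sum(remaining), rs$default_coverage)
})

test_that("prediction follows first-match semantics with a guaranteed default", {
  rule <- structure(list(
    conditions = data.frame(gene = "g1", op = ">", thr = 2,
                            stringsAsFactors = FALSE),
    class = "B", coverage = 0L, correct = 0L), class = "Rule")
  rs <- structure(list(rules = list(rule), default_class = "A",
                       default_coverage = 0L, default_correct = 0L,
                       gene_ids = c("g1")), class = "RuleSet")
  expect_equal(predict_ruleset(rs, c(g1 = 3)), "B")
  expect_equal(predict_ruleset(rs, c(g1 = 1)), "A")
  expect_error(predict_ruleset(rs, c(g2 = 1)), "g1",
               class = "tfs_value_error")

  # default-only rule set predicts the default everywhere
  rs0 <- structure(list(rules = list(), default_class = "A",
                        default_coverage = 0L, default_correct = 0L,
                        gene_ids = character()), class = "RuleSet")
  expect_equal(predict_ruleset(rs0, c(g1 = 99)), "A")
})

test_that("export writes readable conditions and JSON round-trips exactly", {
  rule <- structure(list(
    conditions = data.frame(gene = c("Lgals7", "Hexb"), op = c(">", "<="),
                            thr = c(2.5, 0.75), stringsAsFactors = FALSE),
    class = "Skin", coverage = 12L, correct = 11L), class = "Rule")
  rs <- structure(list(rules = list(rule), default_class = "Liver",
                       default_coverage = 3L, default_correct = 2L,
                       gene_ids = c("Lgals7", "Hexb")), class = "RuleSet")
  path <- file.path(withr::local_tempdir(), "rules.txt")
  out <- export_rules(rs, path)
  lines <- readLines(out[["text"]])
  expect_length(lines, 2)
  expect_match(lines[1], "Lgals7 > 2.5", fixed = TRUE)
  expect_match(lines[1], "THEN Skin (12/11)", fixed = TRUE)
  expect_match(lines[2], "default")

  back <- import_rules(out[["json"]])
  expect_equal(back$rules[[1]]$conditions, rs$rules[[1]]$conditions)
  expect_equal(back$rules[[1]]$class, "Skin")
  expect_equal(back$default_class, "Liver")
  expect_equal(back$gene_ids, rs$gene_ids)

  # a default-only set exports a single line
  rs0 <- structure(list(rules = list(), default_class = "A",
                        default_coverage = 5L, default_correct = 5L,
                        gene_ids = character()), class = "RuleSet")
  p0 <- file.path(withr::local_tempdir(), "d.txt")
  export_rules(rs0, p0)
  expect_length(readLines(p0), 1)
})

test_that("separate-and-conquer terminates and never exceeds the rule cap", {
  vals <- c(seq(0, 1, length.out = 20), seq(4, 5, length.out = 20),
            seq(8, 9, length.out = 20))
  ds <- expression_dataset(matrix(vals, ncol = 1), "g1",
                           sprintf("c%d", 1:60),
                           rep(c("A", "B", "C"), each = 20))
  view <- subset_features(ds, 1L)
  expect_error(train_part(view, max_rules = 1), class = "tfs_rule_cap_error")

  g <- generate_dataset(synthetic_spec(n_classes = 2,
                                       class_sizes = c(25, 25),
                                       markers_per_class = 1,
                                       n_noise_genes = 4,
                                       effect_size = 0.5, seed = 21))
  rs <- train_part(subset_features(g$dataset,
                                   seq_len(ncol(g$dataset$matrix))))
  expect_lte(length(rs$rules), nrow(g$dataset$matrix))
})
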