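# PART rule induction: repeated partial C4.5-style trees, one rule per tree,
# combined by separate-and-conquer. Splits use gain ratio with midpoint
# thresholds; pruning uses the C4.5 pessimistic (upper-confidence) error.

# Pessimistic error count for a node with n instances, e misclassified:
# n times the upper binomial confidence bound at level cf (Clopper-Pearson).
pessimistic_errors <- function(n, e, cf) {
  if (n == 0) return(0)
  if (e >= n) return(n)
  n * qbeta(1 - cf, e + 1, n - e)
}

#' Build a partial decision tree and extract its best rule
#'
#' Grows a C4.5-style tree over the given instances, but only partially: at
#' every step the unexpanded subset with the lowest class entropy is
#' expanded first, and as soon as a fully-expanded subtree resists
#' pessimistic pruning, growth stops and the remaining subsets stay as
#' majority-class leaves. Numeric splits are binary at midpoints between
#' adjacent sorted values, chosen by gain ratio. The returned rule is the
#' path from the root to the leaf covering the most instances (ties: the
#' leaf created first).
#'
#' @param X Numeric matrix of instances x genes, with gene ids as column
#'   names.
#' @param y Factor of class labels, one per row of `X`.
#' @param prune_cf Pruning confidence (default 0.25, the C4.5 convention).
#' @param min_leaf Minimum instances per leaf (default 2).
#' @return List with `rule` (a `Rule`: `conditions` data frame with columns
#'   `gene`, `op`, `thr`; `class`; `coverage`; `correct`) and `matched`
#'   (integer row indices of `X` covered by the rule).
#' @export
build_partial_tree <- function(X, y, prune_cf = 0.25, min_leaf = 2L) {
  if (nrow(X) == 0) tfs_error("empty instance set", "tfs_value_error")
  stopifnot(is.factor(y), length(y) == nrow(X))
  pt <- cpp_partial_tree(X, as.integer(y) - 1L, seq_len(nrow(X)) - 1L,
                         nlevels(y), as.integer(min_leaf), prune_cf)
  conds <- data.frame(gene = colnames(X)[pt$feature],
                      op = c(">", "<=")[pt$leq + 1L],
                      thr = pt$threshold,
                      stringsAsFactors = FALSE)
  # a path may test the same gene repeatedly with tightening thresholds;
  # keep the binding bound per (gene, direction) — semantics unchanged
  if (nrow(conds) > 1) {
    key <- paste(conds$gene, conds$op)
    keep <- vapply(split(seq_len(nrow(conds)), key), function(ix) {
      if (conds$op[ix[1]] == "<=") ix[which.min(conds$thr[ix])]
      else ix[which.max(conds$thr[ix])]
    }, integer(1))
    conds <- conds[sort(unname(keep)), , drop = FALSE]
    rownames(conds) <- NULL
  }
  rule <- list(conditions = conds,
               class = levels(y)[pt$pred + 1L],
               coverage = pt$coverage,
               correct = pt$correct)
  class(rule) <- "Rule"
  list(rule = rule, matched = pt$matched)
}

#' Train a PART rule set
#'
#' Separate-and-conquer: [build_partial_tree()] is run on the instances not
#' yet covered, the extracted rule is appended and its matched instances
#' removed, until every instance is covered. A condition-free terminal rule
#' becomes the default class; otherwise the default predicts the majority
#' class of the final residue (global majority if the residue is empty).
#' Per-rule coverage/correct counts are recorded by replaying the finished
#' rule set over the full training set with first-match semantics.
#'
#' @param ds_view A `FeatureSubsetView` (>= 2 classes present).
#' @param prune_cf Pruning confidence (default 0.25).
#' @param min_leaf Minimum instances per leaf (default 2).
#' @param seed Accepted for interface uniformity with [classifier_spec()];
#'   PART is deterministic and ignores it.
#' @param max_rules Guard against rule explosion (default 20000): exceeding
#'   it raises a structured error.
#' @return A `RuleSet`: list with `rules` (ordered list of `Rule`),
#'   `default_class`, `gene_ids`.
#' @export
train_part <- function(ds_view, prune_cf = 0.25, min_leaf = 2L, seed = 1L,
                       max_rules = 20000L) {
  stopifnot(inherits(ds_view, "FeatureSubsetView"))
  check_trainable(ds_view$parent)
  X <- view_matrix(ds_view)
  colnames(X) <- view_gene_ids(ds_view)
  y <- dataset_labels(ds_view$parent)

  residual <- seq_len(nrow(X))
  rules <- list()
  default_class <- NULL
  while (length(residual) > 0) {
    pt <- build_partial_tree(X[residual, , drop = FALSE], y[residual],
                             prune_cf = prune_cf, min_leaf = min_leaf)
    if (nrow(pt$rule$conditions) == 0) {
      # terminal condition-free rule: it is the default
      default_class <- pt$rule$class
      residual <- integer(0)
      break
    }
    rules[[length(rules) + 1L]] <- pt$rule
    if (length(rules) > max_rules) {
      tfs_error(sprintf("rule count exceeded the cap of %d", max_rules),
                "tfs_rule_cap_error")
    }
    residual <- residual[-pt$matched]
  }
  if (is.null(default_class)) {
    pool <- if (length(residual)) y[residual] else y
    cnt <- table(pool)
    default_class <- names(cnt)[which.max(cnt)]
  }

  rs <- structure(list(rules = rules, default_class = default_class,
                       gene_ids = colnames(X)),
                  class = "RuleSet")
  replay_counts(rs, X, as.character(y))
}

# recompute per-rule coverage/correct on the training set, first-match
replay_counts <- function(rs, X, labels) {
  remaining <- rep(TRUE, nrow(X))
  for (i in seq_along(rs$rules)) {
    m <- remaining & rule_mask(rs$rules[[i]], X)
    rs$rules[[i]]$coverage <- sum(m)
    rs$rules[[i]]$correct <- sum(labels[m] == rs$rules[[i]]$class)
    remaining <- remaining & !m
  }
  rs$default_coverage <- sum(remaining)
  rs$default_correct <- sum(labels[remaining] == rs$default_class)
  rs
}

rule_mask <- function(rule, X) {
  m <- rep(TRUE, nrow(X))
  cd <- rule$conditions
  for (i in seq_len(nrow(cd))) {
    v <- X[, cd$gene[i]]
    m <- m & if (cd$op[i] == "<=") v <= cd$thr[i] else v > cd$thr[i]
  }
  m
}

#' Predict the class of one cell from a rule set
#'
#' Returns the prediction of the first rule whose conditions the cell
#' satisfies; the default rule guarantees an answer.
#'
#' @param rs A `RuleSet`.
#' @param cell Named numeric vector of expression values covering every
#'   gene the rule set references.
#' @return Predicted class (character scalar).
#' @export
predict_ruleset <- function(rs, cell) {
  stopifnot(inherits(rs, "RuleSet"))
  need <- unique(unlist(lapply(rs$rules, function(r) r$conditions$gene)))
  missing <- setdiff(need, names(cell))
  if (length(missing)) {
    tfs_error(paste("missing expression value for gene:", missing[1]),
              "tfs_value_error")
  }
  for (r in rs$rules) {
    cd <- r$conditions
    ok <- TRUE
    for (i in seq_len(nrow(cd))) {
      v <- cell[[cd$gene[i]]]
      if (!(if (cd$op[i] == "<=") v <= cd$thr[i] else v > cd$thr[i])) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(r$class)
  }
  rs$default_class
}

# vectorized prediction over the rows of a matrix with gene colnames
predict_ruleset_matrix <- function(rs, X) {
  out <- rep(rs$default_class, nrow(X))
  remaining <- rep(TRUE, nrow(X))
  for (r in rs$rules) {
    m <- remaining & rule_mask(r, X)
    out[m] <- r$class
    remaining <- remaining & !m
    if (!any(remaining)) break
  }
  out
}

#' @export
print.RuleSet <- function(x, ...) {
  cat(sprintf("RuleSet: %d rules + default '%s' over %d genes\n",
              length(x$rules), x$default_class, length(x$gene_ids)))
  invisible(x)
}

#' Export a rule set to text and JSON
#'
#' Writes human-readable lines
#' `IF gene > x AND gene2 <= y THEN tissue (coverage/correct)` to `path`,
#' plus a machine-readable JSON twin at `<path>.json` which
#' [import_rules()] inverts exactly.
#'
#' @param rs A `RuleSet`.
#' @param path Output path for the text file.
#' @return Invisibly, `c(text = path, json = <path>.json)`.
#' @export
export_rules <- function(rs, path) {
  stopifnot(inherits(rs, "RuleSet"))
  fmt_rule <- function(r) {
    cd <- r$conditions
    lhs <- if (nrow(cd) == 0) "TRUE" else {
      paste(sprintf("%s %s %s", cd$gene, cd$op,
                    format(cd$thr, trim = TRUE, digits = 15)),
            collapse = " AND ")
    }
    sprintf("IF %s THEN %s (%d/%d)", lhs, r$class, r$coverage, r$correct)
  }
  lines <- c(vapply(rs$rules, fmt_rule, character(1)),
             sprintf("IF TRUE THEN %s (%d/%d) [default]", rs$default_class,
                     rs$default_coverage %||% 0L, rs$default_correct %||% 0L))
  writeLines(lines, path)

  json_path <- paste0(path, ".json")
  payload <- list(
    rules = lapply(rs$rules, function(r) {
      list(conditions = r$conditions, class = r$class,
           coverage = r$coverage, correct = r$correct)
    }),
    default_class = rs$default_class,
    default_coverage = rs$default_coverage %||% 0L,
    default_correct = rs$default_correct %||% 0L,
    gene_ids = rs$gene_ids)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(text = path, json = json_path))
}

#' Import a rule set from its JSON export
#'
#' @param json_path Path written by [export_rules()].
#' @return A `RuleSet` equal field-by-field to the exported one.
#' @export
import_rules <- function(json_path) {
  p <- jsonlite::read_json(json_path, simplifyVector = TRUE,
                           simplifyDataFrame = TRUE)
  rules <- lapply(seq_len(length(p$rules$class %||% character())), function(i) {
    cd <- p$rules$conditions[[i]]
    if (is.null(cd) || length(cd) == 0 || nrow(as.data.frame(cd)) == 0) {
      cd <- data.frame(gene = character(), op = character(), thr = numeric(),
                       stringsAsFactors = FALSE)
    } else {
      cd <- as.data.frame(cd, stringsAsFactors = FALSE)
      cd$thr <- as.numeric(cd$thr)
    }
    r <- list(conditions = cd, class = p$rules$class[i],
              coverage = as.integer(p$rules$coverage[i]),
              correct = as.integer(p$rules$correct[i]))
    class(r) <- "Rule"
    r
  })
  structure(list(rules = rules, default_class = p$default_class,
                 default_coverage = as.integer(p$default_coverage),
                 default_correct = as.integer(p$default_correct),
                 gene_ids = p$gene_ids),
            class = "RuleSet")
}
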