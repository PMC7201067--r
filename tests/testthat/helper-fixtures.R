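# Shared fixtures: small hand-built datasets and independent mini-oracles.

# 3-cell x 2-gene dataset used across the data-model tests
tiny_dataset <- function() {
  m <- matrix(c(0, 1.5, 2,
                3, 0, 5), nrow = 3)
  expression_dataset(m, c("g1", "g2"), c("c1", "c2", "c3"), c("A", "A", "B"))
}

# dataset whose first gene is a copy of the class code (perfectly separable)
label_copy_dataset <- function(n_per_class = 100, n_noise = 10, seed = 1,
                               n_classes = 2) {
  withr::with_seed(seed, {
    n <- n_per_class * n_classes
    labels <- rep(LETTERS[seq_len(n_classes)], each = n_per_class)
    m <- cbind(as.numeric(factor(labels)),
               matrix(runif(n * n_noise), n, n_noise))
    expression_dataset(m, sprintf("g%d", seq_len(n_noise + 1)),
                       sprintf("c%d", seq_len(n)), labels)
  })
}

# wrap arbitrary feature indices as a RankedFeatureList
ranked_list_for_test <- function(idx, ds, method = "mRMR") {
  tissueFS:::ranked_feature_list(as.integer(idx), ds$gene_ids[idx],
                                 rev(seq_along(idx)), method)
}

# brute-force plug-in MI oracle (bits) on already-discretized codes
oracle_mi <- function(bx, by) {
  out <- 0
  n <- length(bx)
  for (x in unique(bx)) {
    for (y in unique(by)) {
      pxy <- sum(bx == x & by == y) / n
      if (pxy > 0) {
        out <- out + pxy * log2(pxy / ((sum(bx == x) / n) * (sum(by == y) / n)))
      }
    }
  }
  out
}

# exhaustive-enumeration hypergeometric upper tail via factorials
oracle_hyper_tail <- function(N, K, n, k) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# binary MCC from the textbook 2x2 formula
oracle_binary_mcc <- function(cm) {
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# independent brute-force oracle: evaluate every candidate at every greedy
# step directly from the definition
oracle_mrmr <- function(ds, features, bins = 5) {
  y <- as.integer(dataset_labels(ds))
  codes <- lapply(features, function(j) discretize_ef(ds$matrix[, j], bins))
  rel <- vapply(codes, function(b) oracle_mi(b, y), numeric(1))
  chosen <- integer(0)
  remaining <- seq_along(features)
  while (length(remaining)) {
    crit <- vapply(remaining, function(i) {
      if (length(chosen) == 0) return(rel[i])
      rel[i] - mean(vapply(chosen, function(s) {
        oracle_mi(codes[[i]], codes[[s]])
      }, numeric(1)))
    }, numeric(1))
    pick <- remaining[which.max(crit)]
    chosen <- c(chosen, pick)
    remaining <- setdiff(remaining, pick)
  }
  features[chosen]
}
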