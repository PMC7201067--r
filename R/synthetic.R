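#' Cell counts of the 18-tissue mouse atlas
#'
#' The per-tissue sample sizes of the single-cell atlas the pipeline is
#' designed around: 18 mouse tissues totalling 53,760 cells, from Bladder
#' (1,638 cells) to Trachea (1,391 cells), in atlas index order.
#'
#' @return A named integer vector, tissue -> cell count.
#' @examples
#' sum(atlas_tissue_sizes())  # 53760
#' @export
atlas_tissue_sizes <- function() {
  c(Bladder = 1638L, `Brain microglia` = 4762L, `Brain neurons` = 5799L,
    Colon = 4149L, Fat = 5862L, Heart = 7115L, Kidney = 865L, Liver = 981L,
    Lung = 1923L, Mammary = 2663L, Marrow = 5355L, Muscle = 2102L,
    Pancreas = 1961L, Skin = 2464L, Spleen = 1718L, Thymus = 1580L,
    Tongue = 1432L, Trachea = 1391L)
}

#' Specify a synthetic tissue-atlas dataset
#'
#' Describes a cells x genes dataset with unbalanced tissue classes, a small
#' set of planted tissue-specific marker genes per class and a large
#' background of uninformative genes. Expression is simulated on a log-like
#' scale: Gaussian noise around `base_mean` (markers shifted by `effect_size`
#' in their home tissue), clamped at zero, then zeroed independently with
#' probability `dropout_rate` to emulate single-cell dropout.
#'
#' @param n_classes Number of tissue classes (default 18).
#' @param class_sizes Integer vector of per-class cell counts; defaults to
#'   the atlas profile of [atlas_tissue_sizes()] (truncated/recycled is an error —
#'   length must equal `n_classes`).
#' @param markers_per_class Planted marker genes per class.
#' @param n_noise_genes Count of uninformative background genes.
#' @param effect_size Mean log-expression shift of a marker in its home
#'   tissue (positive).
#' @param base_mean Baseline mean expression (positive).
#' @param noise_sd Gaussian noise standard deviation (positive).
#' @param dropout_rate Probability in `[0, 1]` that any value is zeroed.
#' @param seed Integer seed; generation is a pure function of it.
#' @return A `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_classes = 18L,
                           class_sizes = unname(atlas_tissue_sizes()),
                           markers_per_class = 5L,
                           n_noise_genes = 400L,
                           effect_size = 2,
                           base_mean = 2,
                           noise_sd = 1,
                           dropout_rate = 0.3,
                           seed = 1L) {
  chk <- function(ok, field) {
    if (!ok) tfs_error(paste("invalid synthetic spec field:", field),
                       "tfs_spec_error")
  }
  chk(is.numeric(n_classes) && n_classes >= 1, "n_classes")
  chk(is.numeric(class_sizes) && length(class_sizes) == n_classes &&
        all(class_sizes >= 1), "class_sizes")
  chk(is.numeric(markers_per_class) && markers_per_class >= 1,
      "markers_per_class")
  chk(is.numeric(n_noise_genes) && n_noise_genes >= 0, "n_noise_genes")
  chk(is.numeric(effect_size) && effect_size >= 0, "effect_size")
  chk(is.numeric(base_mean) && base_mean > 0, "base_mean")
  chk(is.numeric(noise_sd) && noise_sd > 0, "noise_sd")
  chk(is.numeric(dropout_rate) && dropout_rate >= 0 && dropout_rate <= 1,
      "dropout_rate")
  chk(is.numeric(seed), "seed")
  structure(list(
    n_classes = as.integer(n_classes),
    class_sizes = as.integer(class_sizes),
    markers_per_class = as.integer(markers_per_class),
    n_noise_genes = as.integer(n_noise_genes),
    effect_size = as.numeric(effect_size),
    base_mean = as.numeric(base_mean),
    noise_sd = as.numeric(noise_sd),
    dropout_rate = as.numeric(dropout_rate),
    seed = as.integer(seed)), class = "SyntheticSpec")
}

#' Scaled-down atlas specification
#'
#' Convenience constructor for a spec with the 18 atlas tissues whose sizes
#' are `ceiling(scale * atlas size)`, so the class imbalance of the full
#' atlas is preserved at a tractable cell count.
#'
#' @param scale Scaling factor in `(0, 1]`.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [synthetic_spec()].
#' @return A `SyntheticSpec` whose class names follow the atlas tissues.
#' @examples
#' spec <- scaled_atlas_spec(0.01, seed = 1)
#' spec$class_sizes[7]  # Kidney: ceiling(0.01 * 865) = 9
#' @export
scaled_atlas_spec <- function(scale, seed = 1L, ...) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0 || scale > 1) {
    tfs_error("scale must lie in (0, 1]", "tfs_spec_error")
  }
  sizes <- as.integer(ceiling(scale * atlas_tissue_sizes()))
  spec <- synthetic_spec(n_classes = 18L, class_sizes = sizes, seed = seed, ...)
  attr(spec, "class_names") <- names(atlas_tissue_sizes())
  spec
}

#' Generate a synthetic dataset with planted markers
#'
#' Each cell of class `c` draws its class-`c` marker genes from
#' `N(base_mean + effect_size, noise_sd)` and every other gene from
#' `N(base_mean, noise_sd)`; draws are clamped at zero and then each value is
#' independently set to zero with probability `dropout_rate`. Gene order is
#' markers first (class by class), then noise genes. The returned truth maps
#' every planted marker to its home tissue, which downstream recovery tests
#' score against.
#'
#' @param spec A `SyntheticSpec` from [synthetic_spec()] or
#'   [scaled_atlas_spec()].
#' @return A list with elements `dataset` (an `ExpressionDataset`) and
#'   `truth` (a `MarkerTruth` data frame with columns `gene_id`, `tissue`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  class_names <- attr(spec, "class_names")
  if (is.null(class_names)) {
    class_names <- sprintf("tissue%02d", seq_len(spec$n_classes))
  }
  n_cells <- sum(spec$class_sizes)
  n_marker <- spec$n_classes * spec$markers_per_class
  n_genes <- n_marker + spec$n_noise_genes

  marker_class <- rep(seq_len(spec$n_classes), each = spec$markers_per_class)
  gene_ids <- c(sprintf("marker_%s_%d",
                        gsub("[^A-Za-z0-9]", "", class_names[marker_class]),
                        sequence(rep(spec$markers_per_class, spec$n_classes))),
                if (spec$n_noise_genes > 0)
                  sprintf("noise_%04d", seq_len(spec$n_noise_genes)))
  cell_class <- rep(seq_len(spec$n_classes), times = spec$class_sizes)
  cell_ids <- sprintf("cell_%05d", seq_len(n_cells))
  labels <- class_names[cell_class]

  m <- with_local_seed(spec$seed, {
    mu <- matrix(spec$base_mean, n_cells, n_genes)
    if (n_marker > 0 && spec$effect_size != 0) {
      for (cls in seq_len(spec$n_classes)) {
        rows <- which(cell_class == cls)
        cols <- which(marker_class == cls)
        mu[rows, cols] <- mu[rows, cols] + spec$effect_size
      }
    }
    x <- mu + matrix(rnorm(n_cells * n_genes, sd = spec$noise_sd),
                     n_cells, n_genes)
    x[x < 0] <- 0
    if (spec$dropout_rate > 0) {
      drop <- matrix(runif(n_cells * n_genes) < spec$dropout_rate,
                     n_cells, n_genes)
      x[drop] <- 0
    }
    x
  })

  ds <- expression_dataset(m, gene_ids, cell_ids, labels,
                           class_names = class_names)
  truth <- data.frame(gene_id = gene_ids[seq_len(n_marker)],
                      tissue = class_names[marker_class],
                      stringsAsFactors = FALSE)
  class(truth) <- c("MarkerTruth", class(truth))
  list(dataset = ds, truth = truth)
}
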