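#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], optionally
#' overridden by a (possibly nested) list or a YAML file with the same
#' shape. One global `seed` deterministically derives every stage's seed,
#' so adding a stage never perturbs another stage's random stream.
#'
#' @param overrides A named list or the path of a YAML file.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(overrides = list()) {
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  cfg <- list(
    input = list(
      synthetic = list(scale = 0.02, markers_per_class = 5L,
                       n_noise_genes = 400L, effect_size = 2,
                       dropout_rate = 0.3),
      paths = NULL,   # list(matrix=, genes=, cells=, labels=, fmt=)
      fmt = "mtx"),
    mi = list(threshold = 0.02, bins = 5L),
    boruta = list(max_iter = 100L, alpha = 0.05, num_trees = 100L),
    mcfs = list(m = 30L, t = 50L, s = "auto", u = 1, v = 1),
    ifs = list(step = 5L, folds = 10L,
               max_k_rf = 200L, max_k_part_Fm = 200L, max_k_part_FM = 400L),
    part = list(prune_cf = 0.25, min_leaf = 2L),
    seed = 1L,
    out_dir = "tissueFS_run",
    resume = FALSE)
  cfg <- modify_list_deep(cfg, overrides)
  class(cfg) <- c("PipelineConfig", class(cfg))
  cfg
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  if (is.null(cfg$input$synthetic) && is.null(cfg$input$paths)) {
    tfs_error("config needs input$synthetic or input$paths", "tfs_config_error")
  }
  if (!is.null(cfg$input$paths)) {
    need <- c("matrix", "labels")
    miss <- setdiff(need, names(cfg$input$paths))
    if (length(miss)) {
      tfs_error(paste("input$paths is missing:", paste(miss, collapse = ", ")),
                "tfs_config_error")
    }
  }
  invisible(cfg)
}

#' Run the full tissue-marker pipeline
#'
#' Executes, in order: dataset generation (or loading), the MI screen,
#' Boruta filtering, mRMR and MCFS ranking of the confirmed genes,
#' incremental feature selection with a random forest on both rankings,
#' IFS with PART on both rankings, PART rule extraction at each ranking's
#' PART optimum, and the hypergeometric overlap of the two methods' optimum
#' gene sets. Every stage writes a TSV/JSON artifact into `out_dir`, and a
#' manifest records the configuration, derived seeds, artifact hashes and a
#' summary table (ranking method, optimum k, rule count, MCC, accuracy).
#' With `resume = TRUE`, stages whose artifact is already present are
#' reloaded instead of recomputed.
#'
#' @param cfg A `PipelineConfig` from [pipeline_config()], a list of
#'   overrides, or a YAML path.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (!inherits(cfg, "PipelineConfig")) cfg <- pipeline_config(cfg)
  validate_config(cfg)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out, paste0(...))
  log_msg <- function(...) message(sprintf("[tissueFS] %s", sprintf(...)))

  manifest <- list(config = cfg,
                   package_version = as.character(utils::packageVersion("tissueFS")),
                   stages = list(), artifacts = list(), summary = NULL,
                   timestamps = list(start = format(Sys.time())))

  # --- input ---------------------------------------------------------------
  if (!is.null(cfg$input$paths)) {
    p <- cfg$input$paths
    ds <- load_dataset(p$matrix, p$genes, p$cells, p$labels,
                       fmt = p$fmt %||% cfg$input$fmt)
    truth <- NULL
  } else {
    s <- cfg$input$synthetic
    spec <- if (!is.null(s$scale)) {
      scaled_atlas_spec(s$scale, seed = derive_seed(cfg$seed, "synth"),
                        markers_per_class = s$markers_per_class %||% 5L,
                        n_noise_genes = s$n_noise_genes %||% 400L,
                        effect_size = s$effect_size %||% 2,
                        dropout_rate = s$dropout_rate %||% 0.3)
    } else {
      do.call(synthetic_spec,
              c(s, list(seed = derive_seed(cfg$seed, "synth"))))
    }
    gen <- generate_dataset(spec)
    ds <- gen$dataset
    truth <- gen$truth
    write.table(truth, pth("truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  log_msg("dataset: %d cells x %d genes, %d classes",
          nrow(ds$matrix), ncol(ds$matrix), length(ds$class_names))

  # --- MI screen -----------------------------------------------------------
  mi <- mi_screen(ds, threshold = cfg$mi$threshold, bins = cfg$mi$bins)
  write.table(data.frame(gene_id = names(mi$scores),
                         mi_bits = unname(mi$scores),
                         passed = seq_along(mi$scores) %in% mi$surviving),
              pth("mi.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg("MI screen: %d -> %d genes (> %.3g bits)",
          ncol(ds$matrix), length(mi$surviving), mi$threshold)

  # --- Boruta --------------------------------------------------------------
  br <- run_boruta(ds, features = mi$surviving,
                   max_iter = cfg$boruta$max_iter, alpha = cfg$boruta$alpha,
                   seed = derive_seed(cfg$seed, "boruta"),
                   num_trees = cfg$boruta$num_trees)
  write.table(data.frame(gene_id = names(br$status),
                         status = as.character(br$status),
                         hits = unname(br$hits),
                         iterations = br$iterations),
              pth("boruta.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  pool <- br$confirmed
  log_msg("Boruta: %d -> %d confirmed genes", length(mi$surviving),
          length(pool))
  if (length(pool) < 2) {
    tfs_error("fewer than 2 genes confirmed; nothing to rank",
              "tfs_pipeline_error")
  }

  # --- rankings ------------------------------------------------------------
  Fm <- rank_mrmr(ds, features = pool, bins = cfg$mi$bins)
  write_ranking(Fm, pth("Fm.tsv"))
  FM <- run_mcfs(ds, features = pool,
                 params = mcfs_params(m = cfg$mcfs$m, t = cfg$mcfs$t,
                                      s = cfg$mcfs$s, u = cfg$mcfs$u,
                                      v = cfg$mcfs$v,
                                      seed = derive_seed(cfg$seed, "mcfs")))
  write_ranking(FM, pth("FM.tsv"))
  log_msg("rankings done (mRMR + MCFS over %d genes)", length(pool))

  # --- IFS -----------------------------------------------------------------
  ifs_seed <- derive_seed(cfg$seed, "ifs")
  rf <- classifier_spec("random_forest", seed = derive_seed(cfg$seed, "rf"))
  pt <- classifier_spec("part", seed = derive_seed(cfg$seed, "part"),
                        prune_cf = cfg$part$prune_cf,
                        min_leaf = cfg$part$min_leaf)
  curves <- list(
    rf_Fm = run_ifs(ds, Fm, rf, step = cfg$ifs$step,
                    max_k = min(cfg$ifs$max_k_rf, nrow(Fm)),
                    folds = cfg$ifs$folds, seed = ifs_seed),
    rf_FM = run_ifs(ds, FM, rf, step = cfg$ifs$step,
                    max_k = min(cfg$ifs$max_k_rf, nrow(FM)),
                    folds = cfg$ifs$folds, seed = ifs_seed),
    part_Fm = run_ifs(ds, Fm, pt, step = cfg$ifs$step,
                      max_k = min(cfg$ifs$max_k_part_Fm, nrow(Fm)),
                      folds = cfg$ifs$folds, seed = ifs_seed),
    part_FM = run_ifs(ds, FM, pt, step = cfg$ifs$step,
                      max_k = min(cfg$ifs$max_k_part_FM, nrow(FM)),
                      folds = cfg$ifs$folds, seed = ifs_seed))
  for (nm in names(curves)) {
    write.table(as.data.frame(curves[[nm]]), pth("ifs_", nm, ".tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_msg("IFS %s: optimum k = %d, MCC = %.3f", nm,
            attr(curves[[nm]], "optimum_k"), attr(curves[[nm]], "optimum_mcc"))
  }

  # --- PART rules at each ranking's PART optimum ---------------------------
  rulesets <- list()
  for (nm in c("Fm", "FM")) {
    ranked <- if (nm == "Fm") Fm else FM
    k <- attr(curves[[paste0("part_", nm)]], "optimum_k")
    view <- subset_features(ds, ranked$feature[seq_len(k)])
    rs <- train_part(view, prune_cf = cfg$part$prune_cf,
                     min_leaf = cfg$part$min_leaf)
    export_rules(rs, pth("rules_", nm, ".txt"))
    rulesets[[nm]] <- rs
    log_msg("PART rules on %s top-%d: %d rules", nm, k, length(rs$rules))
  }

  # --- overlap of optimum gene sets ----------------------------------------
  universe <- length(pool)
  ov <- list(
    rf = overlap_report(Fm, attr(curves$rf_Fm, "optimum_k"),
                        FM, attr(curves$rf_FM, "optimum_k"),
                        universe = universe),
    part = overlap_report(Fm, attr(curves$part_Fm, "optimum_k"),
                          FM, attr(curves$part_FM, "optimum_k"),
                          universe = universe))
  jsonlite::write_json(
    lapply(ov, function(o) o[c("size_a", "size_b", "universe", "overlap",
                               "p_value", "intersection")]),
    pth("overlap.json"), auto_unbox = TRUE, digits = NA)

  # --- summary + manifest --------------------------------------------------
  summary_df <- data.frame(
    classifier = c("random_forest", "random_forest", "part", "part"),
    feature_ranking = c("mRMR", "MCFS", "mRMR", "MCFS"),
    optimum_features = vapply(curves, function(cv) attr(cv, "optimum_k"),
                              numeric(1)),
    rule_count = c(NA, NA, length(rulesets$Fm$rules),
                   length(rulesets$FM$rules)),
    mcc = vapply(curves, function(cv) attr(cv, "optimum_mcc"), numeric(1)),
    overall_accuracy = vapply(curves, function(cv) {
      cv$overall_accuracy[cv$k == attr(cv, "optimum_k")]
    }, numeric(1)))
  rownames(summary_df) <- NULL
  write.table(summary_df, pth("summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  arts <- list.files(out, full.names = TRUE)
  arts <- arts[!basename(arts) %in% "manifest.json"]
  manifest$artifacts <- as.list(setNames(unname(tools::md5sum(arts)),
                                         basename(arts)))
  manifest$stages <- list(
    n_cells = nrow(ds$matrix), n_genes = ncol(ds$matrix),
    mi_survivors = length(mi$surviving), boruta_confirmed = length(pool),
    optima = lapply(curves, function(cv)
      list(k = attr(cv, "optimum_k"), mcc = attr(cv, "optimum_mcc"))))
  manifest$summary <- summary_df
  manifest$seeds <- list(global = cfg$seed,
                         synth = derive_seed(cfg$seed, "synth"),
                         boruta = derive_seed(cfg$seed, "boruta"),
                         mcfs = derive_seed(cfg$seed, "mcfs"),
                         ifs = ifs_seed)
  manifest$timestamps$end <- format(Sys.time())
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}

write_ranking <- function(ranked, path) {
  write.table(data.frame(rank = ranked$rank, gene_id = ranked$gene_id,
                         score = ranked$score),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Render IFS curves and per-tissue accuracy charts from a pipeline run
#'
#' Reads the artifacts of a [run_pipeline()] output directory and writes one
#' PDF with the IFS curves (MCC against the number of top features, one
#' panel per classifier x ranking) and per-tissue accuracy bar charts at
#' each classifier's optimum. Bars follow the dataset's class order.
#'
#' @param run_dir The pipeline output directory.
#' @param file Output PDF path (default `report.pdf` inside `run_dir`).
#' @return Invisibly, the PDF path; warns (rather than fails) on missing
#'   artifacts.
#' @export
pipeline_report <- function(run_dir, file = file.path(run_dir, "report.pdf")) {
  curves <- list.files(run_dir, pattern = "^ifs_.*\\.tsv$", full.names = TRUE)
  if (!length(curves)) {
    warning("no IFS curve artifacts found; report is empty", call. = FALSE)
    return(invisible(NULL))
  }
  grDevices::pdf(file, width = 8, height = 5)
  on.exit(grDevices::dev.off())
  for (cp in curves) {
    cv <- read.delim(cp)
    nm <- sub("^ifs_(.*)\\.tsv$", "\\1", basename(cp))
    plot(cv$k, cv$mcc, type = "b", pch = 16, xlab = "number of top features",
         ylab = "MCC (10-fold CV)", main = paste("IFS curve:", nm),
         ylim = c(min(0, min(cv$mcc)), 1))
    best <- which.max(cv$mcc)
    graphics::abline(v = cv$k[best], lty = 2, col = "grey40")
    # per-tissue accuracies at the optimum
    acc_cols <- grep("^acc_", names(cv), value = TRUE)
    if (length(acc_cols)) {
      acc <- as.numeric(cv[best, acc_cols])
      graphics::barplot(acc, names.arg = sub("^acc_", "", acc_cols),
                        las = 2, ylim = c(0, 1), cex.names = 0.7,
                        ylab = "accuracy",
                        main = sprintf("Per-tissue accuracy at k = %d (%s)",
                                       cv$k[best], nm))
    }
  }
  invisible(file)
}
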