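#' Run the full classification pipeline on simulated arrays
#'
#' Exercises every stage end to end on synthetic data with known truth:
#' simulate two-channel arrays, score array quality and drop failures,
#' compute M/A values, print-tip Lowess normalize each array, assemble the
#' two batches into separate training (batch 1) and test (batch >= 2)
#' expression matrices, run each classification strategy (nested-LOOCV
#' grid search, final model, independent test evaluation), and produce the
#' report artefacts: per-strategy accuracy table, class-vs-rest fold-change
#' gene tables for the one-vs-rest classifiers, gene-list overlaps against
#' the multi-class signature, and sample clustering on the multi-class
#' classifier genes. The whole run is a deterministic function of
#' `config$seed`.
#'
#' @param config A [sim_config()] object (needs `n_batches >= 2`).
#' @param n_printtips,bias_amplitude Passed to
#'   [simulate_two_channel_arrays()].
#' @param span Lowess span for normalization.
#' @param qc_threshold Retention threshold for [array_qc_score()].
#' @param grid Gene-number grid.
#' @param strategies Named list of [strategy_spec()] objects; defaults to
#'   the study's eight comparisons.
#' @param outdir Optional directory for heat maps and TSV/CSV outputs;
#'   `NULL` keeps everything in memory.
#' @return An object of class `gep_pipeline`: list with `accuracy_table`,
#'   `strategies` (list of `strategy_result`), `qc` (per-array score
#'   table), `train`/`test` (`expr_matrix` objects), `gene_tables`,
#'   `overlap`, `sample_cluster_order` and `truth`.
#' @export
run_pipeline <- function(config = sim_config(),
                         n_printtips = 16L,
                         bias_amplitude = 0.8,
                         span = 0.3,
                         qc_threshold = 1,
                         grid = default_grid(),
                         strategies = default_strategies(),
                         outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_batches < 2L)
    stop("the pipeline needs a training and a test batch", call. = FALSE)

  sim <- simulate_two_channel_arrays(config, n_printtips = n_printtips,
                                     bias_amplitude = bias_amplitude)

  qc <- lapply(sim$arrays, array_qc_score, threshold = qc_threshold)
  qc_tab <- data.frame(
    array_id = vapply(qc, `[[`, character(1), "array_id"),
    qc_cv_score = vapply(qc, `[[`, numeric(1), "qc_cv_score"),
    retained = vapply(qc, `[[`, logical(1), "retained"),
    stringsAsFactors = FALSE
  )
  rownames(qc_tab) <- NULL
  kept <- sim$arrays[qc_tab$retained]
  if (!length(kept)) stop("every array failed QC", call. = FALSE)

  normalized <- lapply(kept, function(a)
    printtip_lowess_normalize(compute_ma(a), span = span))

  sheet <- sim$sample_sheet
  batch_of <- stats::setNames(sheet$batch, sheet$sample_id)
  ids <- names(normalized)
  train_ids <- ids[batch_of[ids] == 1L]
  test_ids <- ids[batch_of[ids] >= 2L]
  if (!length(train_ids) || !length(test_ids))
    stop("QC filtering emptied the training or test batch", call. = FALSE)
  train <- assemble_matrix(normalized[train_ids],
                           sheet[sheet$batch == 1L, , drop = FALSE])
  test <- assemble_matrix(normalized[test_ids],
                          sheet[sheet$batch >= 2L, , drop = FALSE])

  train_labels <- train$sample_sheet$class
  test_labels <- test$sample_sheet$class
  results <- lapply(strategies, function(sp)
    run_strategy(train$values, train_labels, test$values, test_labels,
                 sp, grid = grid))

  accuracy_table <- data.frame(
    strategy = vapply(results, function(r) r$spec$name, character(1)),
    mode = vapply(results, function(r) r$spec$mode, character(1)),
    optimal_p = vapply(results, function(r) r$cv_profile$optimal_p,
                       integer(1)),
    training_accuracy = vapply(results, `[[`, numeric(1),
                               "training_accuracy"),
    test_accuracy = vapply(results, `[[`, numeric(1), "test_accuracy"),
    stringsAsFactors = FALSE
  )
  rownames(accuracy_table) <- NULL

  # report artefacts: fold-change tables for one-vs-rest classifiers,
  # overlap of their gene lists with the multi-class signature, and sample
  # clustering on the multi-class classifier genes
  gene_tables <- list()
  binary_lists <- list()
  for (nm in names(results)) {
    r <- results[[nm]]
    if (r$spec$mode == "global_binary") {
      gene_tables[[nm]] <- classifier_gene_table(
        train$values, train_labels, r$final_model$genes,
        r$spec$positive_class)
      binary_lists[[nm]] <- r$final_model$genes
    }
  }
  multiclass_nm <- names(results)[vapply(results, function(r)
    r$spec$mode == "multiclass", logical(1))]
  overlap <- NULL
  cluster_order <- NULL
  if (length(multiclass_nm)) {
    mc <- results[[multiclass_nm[1]]]
    if (length(binary_lists) >= 2L)
      overlap <- classifier_overlap(binary_lists,
                                    reference = mc$final_model$genes)
    keep <- relabel(train_labels, mc$spec)
    slice <- train$values[mc$final_model$genes, keep$keep, drop = FALSE]
    cluster_order <- hcluster(slice, "columns")$order
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      plot_heatmap(slice, classes = keep$labels,
                   path = file.path(outdir, "multiclass_heatmap.png"))
    }
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.csv(qc_tab, file.path(outdir, "qc_report.csv"), row.names = FALSE)
    write_expression_matrix(train, file.path(outdir, "train_matrix.tsv"))
    write_expression_matrix(test, file.path(outdir, "test_matrix.tsv"))
    write.csv(accuracy_table, file.path(outdir, "accuracy_table.csv"),
              row.names = FALSE)
    for (nm in names(gene_tables))
      write.table(gene_tables[[nm]],
                  file.path(outdir, paste0("genes_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }

  structure(list(config = config,
                 qc = qc_tab,
                 train = train,
                 test = test,
                 strategies = results,
                 accuracy_table = accuracy_table,
                 gene_tables = gene_tables,
                 overlap = overlap,
                 sample_cluster_order = cluster_order,
                 truth = sim$truth),
            class = "gep_pipeline")
}

#' @export
print.gep_pipeline <- function(x, ...) {
  cat("Expression-profiling classification pipeline\n")
  cat("  arrays:", nrow(x$qc), "simulated,", sum(x$qc$retained),
      "retained after QC\n")
  cat("  training:", ncol(x$train$values), "samples | test:",
      ncol(x$test$values), "samples |", nrow(x$train$values), "probes\n\n")
  tab <- x$accuracy_table
  tab$training_accuracy <- sprintf("%.1f", tab$training_accuracy)
  tab$test_accuracy <- sprintf("%.1f", tab$test_accuracy)
  print(tab, row.names = FALSE)
  invisible(x)
}
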