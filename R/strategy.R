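#' Define a classification strategy
#'
#' Three strategy families mirror the study design:
#' \describe{
#'   \item{`multiclass`}{one model classifying >= 3 diagnosis classes in a
#'     single step; samples outside `classes_included` are excluded.}
#'   \item{`local_binary`}{a two-group comparison on a subset of the data;
#'     `relabel_map` maps each participating raw class to one of exactly
#'     two analysis labels (e.g. pooling all lymphoma subtypes against
#'     reactive tissue), and unmapped samples are excluded.}
#'   \item{`global_binary`}{one class of interest against *all* remaining
#'     samples, relabelled `"rest"` (one-vs-rest over the full data,
#'     including classes that are never a target themselves).}
#' }
#'
#' @param name Human-readable strategy name.
#' @param mode `"multiclass"`, `"local_binary"` or `"global_binary"`.
#' @param classes_included For `multiclass`: classes kept (>= 3); `NULL`
#'   keeps every class present.
#' @param relabel_map For `local_binary`: named character vector, raw class
#'   -> analysis label (exactly 2 distinct analysis labels).
#' @param positive_class For `global_binary`: the class of interest.
#' @return An object of class `strategy_spec`.
#' @examples
#' strategy_spec("cHL v NHL", "local_binary",
#'   relabel_map = c(cHL = "cHL", DLBCL = "NHL", FL = "NHL",
#'                   otherNHL = "NHL"))
#' strategy_spec("FL v rest", "global_binary", positive_class = "FL")
#' @export
strategy_spec <- function(name,
                          mode = c("multiclass", "local_binary",
                                   "global_binary"),
                          classes_included = NULL,
                          relabel_map = NULL,
                          positive_class = NULL) {
  mode <- match.arg(mode)
  if (mode == "local_binary") {
    if (is.null(relabel_map) || is.null(names(relabel_map)))
      stop("local_binary needs a named relabel_map", call. = FALSE)
    if (length(unique(relabel_map)) != 2L)
      stop("local_binary relabel_map must define exactly 2 analysis labels",
           call. = FALSE)
  }
  if (mode == "global_binary" && is.null(positive_class))
    stop("global_binary needs a positive_class", call. = FALSE)
  if (mode == "multiclass" && !is.null(classes_included) &&
      length(classes_included) < 3L)
    stop("multiclass needs at least 3 classes", call. = FALSE)
  structure(list(name = name, mode = mode,
                 classes_included = classes_included,
                 relabel_map = relabel_map,
                 positive_class = positive_class),
            class = "strategy_spec")
}

#' @export
print.strategy_spec <- function(x, ...) {
  cat("Strategy '", x$name, "' (", x$mode, ")\n", sep = "")
  invisible(x)
}

#' Relabel samples for a classification strategy
#'
#' Applies a [strategy_spec()] to raw diagnosis labels: one-vs-rest keeps
#' every sample and maps non-positive classes to `"rest"`; local binary
#' comparisons keep only the mapped classes; multi-class keeps the listed
#' classes under their own names.
#'
#' @param labels Raw class label per sample.
#' @param spec A `strategy_spec`.
#' @return A list with `keep` (logical mask over samples) and `labels`
#'   (character vector of analysis labels for the kept samples).
#' @export
relabel <- function(labels, spec) {
  stopifnot(inherits(spec, "strategy_spec"))
  labels <- as.character(labels)
  present <- unique(labels)
  if (spec$mode == "global_binary") {
    if (!spec$positive_class %in% present)
      stop("positive class '", spec$positive_class,
           "' not present among samples", call. = FALSE)
    keep <- rep(TRUE, length(labels))
    out <- ifelse(labels == spec$positive_class, spec$positive_class, "rest")
    if (length(unique(out)) < 2L)
      stop("strategy '", spec$name, "' yields a single class", call. = FALSE)
  } else if (spec$mode == "local_binary") {
    keep <- labels %in% names(spec$relabel_map)
    out <- unname(spec$relabel_map[labels[keep]])
    # both analysis labels must be populated; catches unknown/typo classes
    empty <- setdiff(unique(spec$relabel_map), out)
    if (length(empty) || length(unique(out)) < 2L)
      stop("strategy '", spec$name, "' yields a single class",
           if (length(empty)) paste0(" (no samples map to '",
                                     paste(empty, collapse = "', '"), "')"),
           call. = FALSE)
  } else {
    incl <- if (is.null(spec$classes_included)) sort_c(present) else
      spec$classes_included
    unknown <- setdiff(incl, present)
    if (length(unknown))
      stop("class(es) in strategy '", spec$name,
           "' unknown among samples: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    if (length(incl) < 3L)
      stop("multiclass strategy '", spec$name,
           "' has fewer than 3 classes", call. = FALSE)
    keep <- labels %in% incl
    out <- labels[keep]
  }
  list(keep = keep, labels = out)
}

#' Train, cross-validate and independently test one strategy
#'
#' Runs the full supervised workflow for a single [strategy_spec()]: the
#' training samples are relabelled, the nested-LOOCV error profile over the
#' gene-number grid picks the optimal gene count, a final DLDA rule is
#' built from the *complete* training set using that many top-ranked genes
#' (re-ranked on the full training data), and the rule classifies the
#' relabelled independent test samples. Test labels are only consulted in
#' the final scoring step. Training accuracy is 100 minus the minimal
#' LOOCV error; test accuracy is the percent of test samples whose
#' prediction matches their relabelled diagnosis.
#'
#' @param train_x,test_x Numeric matrices, genes x samples. Probe sets are
#'   intersected (a message reports any asymmetry).
#' @param train_labels,test_labels Raw class label per sample.
#' @param spec A `strategy_spec`.
#' @param grid Gene-number grid, as in [grid_search()].
#' @return An object of class `strategy_result`: list with `spec`,
#'   `cv_profile`, `training_accuracy`, `test_accuracy`, `final_model`,
#'   `test_calls` (data frame `sample_id`, `true`, `predicted`) and
#'   `n_train`/`n_test`.
#' @export
run_strategy <- function(train_x, train_labels, test_x, test_labels, spec,
                         grid = default_grid()) {
  stopifnot(inherits(spec, "strategy_spec"))
  common <- intersect(rownames(train_x), rownames(test_x))
  if (!length(common))
    stop("training and test matrices share no probes", call. = FALSE)
  if (length(common) < nrow(train_x) || length(common) < nrow(test_x))
    message("restricting to the ", length(common),
            " probes shared by training and test data")
  common <- sort_c(common)
  train_x <- train_x[common, , drop = FALSE]
  test_x <- test_x[common, , drop = FALSE]

  tr <- relabel(train_labels, spec)
  te <- relabel(test_labels, spec)
  xtr <- train_x[, tr$keep, drop = FALSE]
  xte <- test_x[, te$keep, drop = FALSE]

  profile <- grid_search(xtr, tr$labels, grid)
  scores <- bss_wss(xtr, tr$labels)
  final_genes <- top_genes(scores, profile$optimal_p)
  final_model <- dlda(xtr, tr$labels, genes = final_genes)

  pred <- as.character(predict(final_model, xte))
  test_accuracy <- 100 * mean(pred == te$labels)
  ids <- colnames(xte)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(xte)))

  structure(list(
    spec = spec,
    cv_profile = profile,
    training_accuracy = accuracy_from_error(profile$optimal_error),
    test_accuracy = test_accuracy,
    final_model = final_model,
    test_calls = data.frame(sample_id = ids, true = te$labels,
                            predicted = pred, stringsAsFactors = FALSE),
    n_train = ncol(xtr),
    n_test = ncol(xte)
  ), class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat("Strategy '", x$spec$name, "' (", x$spec$mode, ")\n", sep = "")
  cat(sprintf("  optimal genes: %d | training accuracy %.1f%% (n=%d) | test accuracy %.1f%% (n=%d)\n",
              x$cv_profile$optimal_p, x$training_accuracy, x$n_train,
              x$test_accuracy, x$n_test))
  invisible(x)
}

#' @export
summary.strategy_result <- function(object, ...) {
  tab <- table(true = object$test_calls$true,
               predicted = object$test_calls$predicted)
  sens <- vapply(rownames(tab), function(k) {
    correct <- if (k %in% colnames(tab)) tab[k, k] else 0L
    100 * correct / sum(tab[k, ])
  }, numeric(1))
  out <- list(name = object$spec$name,
              optimal_p = object$cv_profile$optimal_p,
              training_accuracy = object$training_accuracy,
              test_accuracy = object$test_accuracy,
              confusion = tab,
              per_class_sensitivity = sens)
  class(out) <- "summary.strategy_result"
  out
}

#' @export
print.summary.strategy_result <- function(x, ...) {
  cat("Strategy '", x$name, "': ", x$optimal_p, " genes, training ",
      sprintf("%.1f%%", x$training_accuracy), ", test ",
      sprintf("%.1f%%", x$test_accuracy), "\n", sep = "")
  cat("Test-set confusion:\n")
  print(x$confusion)
  cat("Per-class sensitivity (%):\n")
  print(round(x$per_class_sensitivity, 1))
  invisible(x)
}

#' The study's default strategy set
#'
#' The eight comparisons run by default: the four-class global analysis,
#' three local binary comparisons (all lymphoma v RL, cHL v NHL with RL
#' excluded, FL v DLBCL), and one-vs-rest comparisons for each of the four
#' diagnosis classes (the `otherNHL` pool joins the lymphoma and rest
#' sides but is never a target class).
#'
#' @return Named list of [strategy_spec()] objects.
#' @export
default_strategies <- function() {
  list(
    multiclass = strategy_spec(
      "RL v cHL v FL v DLBCL", "multiclass",
      classes_included = c("RL", "cHL", "FL", "DLBCL")),
    lymphoma_v_rl = strategy_spec(
      "RL v Lymphoma", "local_binary",
      relabel_map = c(RL = "RL", cHL = "Lymphoma", DLBCL = "Lymphoma",
                      FL = "Lymphoma", otherNHL = "Lymphoma")),
    chl_v_nhl = strategy_spec(
      "cHL v NHL", "local_binary",
      relabel_map = c(cHL = "cHL", DLBCL = "NHL", FL = "NHL",
                      otherNHL = "NHL")),
    fl_v_dlbcl = strategy_spec(
      "FL v DLBCL", "local_binary",
      relabel_map = c(FL = "FL", DLBCL = "DLBCL")),
    chl_v_rest = strategy_spec("cHL v remaining cases", "global_binary",
                               positive_class = "cHL"),
    fl_v_rest = strategy_spec("FL v remaining cases", "global_binary",
                              positive_class = "FL"),
    dlbcl_v_rest = strategy_spec("DLBCL v remaining cases", "global_binary",
                                 positive_class = "DLBCL"),
    rl_v_rest = strategy_spec("RL v remaining cases", "global_binary",
                              positive_class = "RL")
  )
}
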