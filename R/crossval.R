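#' The default gene-number grid
#'
#' Gene-set sizes 10, 20, ..., 500 (50 sizes), the grid over which the
#' optimal classifier size is searched.
#'
#' @return Integer vector of gene-set sizes.
#' @export
default_grid <- function() seq(10L, 500L, by = 10L)

check_cv_inputs <- function(x, labels) {
  stopifnot(is.matrix(x), is.numeric(x))
  labels <- as.character(labels)
  if (length(labels) != ncol(x))
    stop("labels must have one entry per sample", call. = FALSE)
  tab <- table(labels)
  if (any(tab < 3))
    stop("leave-one-out CV needs >= 3 samples per class; offending ",
         "class(es): ", paste(names(tab)[tab < 3], collapse = ", "),
         call. = FALSE)
  labels
}

#' Leave-one-out cross-validated error with in-fold gene selection
#'
#' For each sample i, genes are ranked by [bss_wss()] on all samples except
#' i, the top `p` are selected, a DLDA model is fitted on the same reduced
#' data, and sample i is predicted. Feature selection happens inside every
#' fold, never on the full data, so the estimate is free of selection bias.
#'
#' @param x Numeric matrix, genes x samples.
#' @param labels Class label per sample; >= 3 samples per class so each
#'   fold retains >= 2.
#' @param p Gene-set size (<= number of genes).
#' @return A list with `error` (percent misclassified, 0-100) and `calls`
#'   (data frame `sample_id`, `true`, `predicted`).
#' @export
loocv_error <- function(x, labels, p) {
  labels <- check_cv_inputs(x, labels)
  if (p > nrow(x)) stop("p exceeds the number of genes", call. = FALSE)
  n <- ncol(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    sc <- bss_wss(x[, -i, drop = FALSE], labels[-i])
    g <- top_genes(sc, p)
    fit <- dlda(x[, -i, drop = FALSE], labels[-i], genes = g)
    pred[i] <- as.character(predict(fit, x[, i]))
  }
  ids <- colnames(x)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  list(error = 100 * mean(pred != labels),
       calls = data.frame(sample_id = ids, true = labels, predicted = pred,
                          stringsAsFactors = FALSE))
}

#' Nested-LOOCV error profile over a gene-number grid
#'
#' Computes the leave-one-out error at every gene-set size in `grid`, with
#' gene ranking redone inside each fold. One ranking and one set of
#' per-gene DLDA statistics per fold serve all grid sizes: the discriminant
#' score at size p is the cumulative sum of per-gene score contributions
#' over the fold's top-ranked genes, which is algebraically identical to
#' refitting at each p. The optimal size is the smallest p attaining the
#' minimum error (parsimony tie-break).
#'
#' @param x Numeric matrix, genes x samples.
#' @param labels Class label per sample (>= 3 per class).
#' @param grid Integer vector of gene-set sizes; sizes exceeding the number
#'   of genes are dropped with a warning.
#' @return An object of class `cv_profile`: list with `grid`,
#'   `error_rate` (percent per grid size), `optimal_p`, `optimal_error`,
#'   `per_sample_calls` (data frame `p`, `sample_id`, `true`, `predicted`)
#'   and `n`.
#' @seealso [loocv_error()] for a single size, [accuracy_from_error()].
#' @export
grid_search <- function(x, labels, grid = default_grid()) {
  labels <- check_cv_inputs(x, labels)
  grid <- sort(unique(as.integer(grid)))
  if (any(grid < 1)) stop("grid sizes must be positive", call. = FALSE)
  over <- grid > nrow(x)
  if (any(over)) {
    warning("dropping grid size(s) exceeding the ", nrow(x),
            " available genes: ", paste(grid[over], collapse = ", "),
            call. = FALSE)
    grid <- grid[!over]
  }
  if (!length(grid)) stop("empty gene-number grid", call. = FALSE)

  n <- ncol(x)
  p_max <- max(grid)
  cls <- sort_c(unique(labels))
  pred <- matrix(NA_character_, nrow = n, ncol = length(grid))
  for (i in seq_len(n)) {
    sc <- bss_wss(x[, -i, drop = FALSE], labels[-i])
    ranked <- sc$probe_id[seq_len(p_max)]
    fit <- dlda(x[, -i, drop = FALSE], labels[-i], genes = ranked)
    contrib <- (x[ranked, i] - fit$means)^2 / fit$pooled_var
    cum <- apply(contrib, 2, cumsum)
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
    scores_p <- cum[grid, , drop = FALSE]
    pred[i, ] <- cls[max.col(-scores_p, ties.method = "first")]
  }
  err <- 100 * colMeans(pred != labels)
  opt_i <- which(err == min(err))[1]

  ids <- colnames(x)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  calls <- data.frame(
    p = rep(grid, each = n),
    sample_id = rep(ids, times = length(grid)),
    true = rep(labels, times = length(grid)),
    predicted = as.vector(pred),
    stringsAsFactors = FALSE
  )
  structure(list(grid = grid,
                 error_rate = stats::setNames(err, grid),
                 optimal_p = grid[opt_i],
                 optimal_error = err[[opt_i]],
                 per_sample_calls = calls,
                 n = n),
            class = "cv_profile")
}

#' @export
print.cv_profile <- function(x, ...) {
  cat("Nested-LOOCV profile over", length(x$grid), "gene-set sizes (",
      min(x$grid), "-", max(x$grid), ")\n")
  cat(sprintf("  optimal p = %d genes: error %.1f%% (accuracy %.1f%%) on %d samples\n",
              x$optimal_p, x$optimal_error,
              accuracy_from_error(x$optimal_error), x$n))
  invisible(x)
}

#' @export
plot.cv_profile <- function(x, ...) {
  graphics::plot(x$grid, x$error_rate, type = "b", pch = 16, cex = 0.7,
                 xlab = "number of genes", ylab = "LOOCV error rate (%)",
                 ...)
  graphics::abline(v = x$optimal_p, lty = 2, col = "grey40")
  invisible(x)
}

#' Convert an error rate to an accuracy rate
#'
#' Training-set accuracy is defined as 100 minus the LOOCV error rate, both
#' in percent.
#'
#' @param error Error rate(s) in percent, within `[0, 100]`.
#' @return `100 - error`.
#' @examples
#' accuracy_from_error(16.4)  # 83.6
#' @export
accuracy_from_error <- function(error) {
  if (any(!is.finite(error)) || any(error < 0) || any(error > 100))
    stop("error rate must lie in [0, 100]", call. = FALSE)
  100 - error
}
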