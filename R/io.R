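#' Write / read an expression matrix as TSV
#'
#' The on-disk layout is a tab-delimited table whose first column
#' `probe_id` holds probe identifiers and whose header row holds sample
#' ids.
#'
#' @param x Numeric matrix (probes x samples) or an `expr_matrix` object.
#' @param path File path.
#' @return `write_expression_matrix()` returns `path` invisibly;
#'   `read_expression_matrix()` returns a numeric matrix with dimnames.
#' @export
write_expression_matrix <- function(x, path) {
  if (inherits(x, "expr_matrix")) x <- x$values
  stopifnot(is.matrix(x))
  out <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "probe_id")
    stop("expression matrix file must start with a 'probe_id' column",
         call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$probe_id
  m
}

#' Write / read a sample sheet as CSV
#'
#' Columns: `sample_id`, `class`, `batch`.
#'
#' @param sheet Data frame with the three columns above.
#' @param path File path.
#' @return `write_sample_sheet()` returns `path` invisibly;
#'   `read_sample_sheet()` returns the data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  stopifnot(all(c("sample_id", "class", "batch") %in% names(sheet)))
  write.csv(sheet[, c("sample_id", "class", "batch")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("sample_id", "class", "batch"), names(sheet))
  if (length(missing))
    stop("sample sheet missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  sheet
}

#' Write a simulation ground-truth record as JSON
#'
#' Serializes the informative gene sets, class assignments and (for
#' two-channel simulations) the per-print-tip bias-curve parameters; the
#' bulky per-spot truth tables are omitted. Curves can be re-evaluated
#' with [bias_curve_fun()].
#'
#' @param truth A truth record from the simulators.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_record <- function(truth, path) {
  doc <- list(informative_genes = truth$informative_genes,
              class_assignments = as.list(truth$class_assignments),
              bias_curves = truth$bias_curves)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
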