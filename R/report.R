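#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering with Euclidean distance and complete linkage,
#' the combination used for the study's heat maps. `axis = "columns"`
#' clusters samples (the usual case), `axis = "rows"` clusters genes.
#' Merges are deterministic given the input order (equal-distance merges
#' follow the lowest-index pair, as in [stats::hclust()]).
#'
#' @param x Numeric matrix slice (genes x samples).
#' @param axis `"columns"` (samples) or `"rows"` (genes).
#' @return An [stats::hclust] tree (merge history, heights, leaf order).
#' @export
hcluster <- function(x, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  m <- if (axis == "columns") t(x) else x
  if (nrow(m) < 2L)
    stop("need at least 2 items to cluster on the ", axis, " axis",
         call. = FALSE)
  hclust(dist(m, method = "euclidean"), method = "complete")
}

#' Render a clustered red-green expression heat map
#'
#' Standardizes each gene to zero mean and unit SD across samples (constant
#' genes map to zero), clusters genes and samples by complete-linkage
#' Euclidean clustering of those same standardized values, and writes a
#' heat map with genes as rows, samples as columns, a red (high) to green
#' (low) colour scale, dendrograms on both axes and a class colour bar for
#' the columns.
#'
#' @param x Numeric matrix slice, genes x samples (e.g. classifier genes).
#' @param classes Optional class label per sample for the column
#'   annotation bar.
#' @param path Output image path (extension selects the device, e.g.
#'   `.png` or `.pdf`).
#' @return Invisibly, a list with `path`, `row_order` and `col_order` (the
#'   dendrogram leaf orders actually rendered).
#' @export
plot_heatmap <- function(x, classes = NULL, path) {
  stopifnot(is.matrix(x), nrow(x) >= 2L, ncol(x) >= 2L)
  sds <- apply(x, 1, sd)
  z <- (x - rowMeans(x)) / ifelse(sds > 0, sds, 1)
  hr <- hcluster(z, "rows")
  hc <- hcluster(z, "columns")
  ann <- NA
  if (!is.null(classes)) {
    if (is.null(colnames(z)))
      colnames(z) <- sprintf("s%03d", seq_len(ncol(z)))
    ann <- data.frame(class = as.character(classes),
                      row.names = colnames(z))
  }
  lim <- max(abs(z), 1e-6)
  pheatmap::pheatmap(
    z,
    cluster_rows = hr, cluster_cols = hc,
    color = colorRampPalette(c("green", "black", "red"))(101),
    breaks = seq(-lim, lim, length.out = 102),
    annotation_col = ann,
    show_rownames = nrow(z) <= 60,
    filename = path, silent = TRUE
  )
  invisible(list(path = path, row_order = hr$order, col_order = hc$order))
}

#' Classifier-gene table with class-vs-rest fold changes
#'
#' For each classifier gene, the fold change is the linear ratio
#' `2^(mean log2 ratio in the positive class - mean log2 ratio in the
#' rest)`; values above 1 mark genes expressed higher in the class of
#' interest. Rows are sorted by decreasing fold change.
#'
#' @param x Numeric matrix, genes x samples (log2 ratios).
#' @param labels Class label per sample.
#' @param genes Classifier probe ids (non-empty, subset of `rownames(x)`).
#' @param positive_class The class characterized by the table.
#' @param annotation Optional named character vector probe id -> gene
#'   symbol.
#' @return A data frame with `probe_id`, `symbol`, `fold_change`.
#' @export
classifier_gene_table <- function(x, labels, genes, positive_class,
                                  annotation = NULL) {
  if (!length(genes)) stop("empty gene set", call. = FALSE)
  missing_genes <- setdiff(genes, rownames(x))
  if (length(missing_genes))
    stop("gene(s) not in matrix: ",
         paste(head(missing_genes, 5), collapse = ", "), call. = FALSE)
  labels <- as.character(labels)
  if (!positive_class %in% labels)
    stop("positive class '", positive_class, "' not present", call. = FALSE)
  pos <- labels == positive_class
  xg <- x[genes, , drop = FALSE]
  fc <- 2^(rowMeans(xg[, pos, drop = FALSE]) -
             rowMeans(xg[, !pos, drop = FALSE]))
  out <- data.frame(
    probe_id = genes,
    symbol = if (is.null(annotation)) NA_character_ else
      unname(annotation[genes]),
    fold_change = as.vector(fc),
    stringsAsFactors = FALSE
  )
  out <- out[order_c(-out$fold_change, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap between classifier gene lists
#'
#' Pairwise intersection sizes between gene lists, and optionally the size
#' of the intersection between the union of all lists and a reference list
#' (e.g. binary-classifier genes versus the multi-class signature).
#'
#' @param lists Named list (>= 2) of character vectors of probe ids.
#' @param reference Optional reference gene list.
#' @return A list with `pairwise` (symmetric count matrix whose diagonal
#'   holds the list sizes), `union_size`, and `union_vs_reference` (count,
#'   or `NA` without a reference).
#' @examples
#' classifier_overlap(list(a = c("A", "B", "C"), b = c("B", "C", "D")))
#' @export
classifier_overlap <- function(lists, reference = NULL) {
  stopifnot(is.list(lists))
  if (length(lists) < 2L) stop("need at least 2 gene lists", call. = FALSE)
  if (is.null(names(lists)))
    names(lists) <- sprintf("list%d", seq_along(lists))
  lists <- lapply(lists, unique)
  k <- length(lists)
  pw <- matrix(0L, k, k, dimnames = list(names(lists), names(lists)))
  for (i in seq_len(k)) for (j in seq_len(k))
    pw[i, j] <- length(intersect(lists[[i]], lists[[j]]))
  un <- unique(unlist(lists, use.names = FALSE))
  list(pairwise = pw,
       union_size = length(un),
       union_vs_reference = if (is.null(reference)) NA_integer_ else
         length(intersect(un, unique(reference))))
}
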