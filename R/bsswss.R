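#' Rank genes by the between/within sum-of-squares ratio
#'
#' For each gene g with class means `xbar_kg`, grand mean `xbar_g` and class
#' sizes `n_k`:
#' `BSS_g = sum_k n_k (xbar_kg - xbar_g)^2` and
#' `WSS_g = sum_k sum_{i in k} (x_ig - xbar_kg)^2`.
#' Genes are ranked by `BSS/(WSS + epsilon)` in decreasing order; a tiny
#' `epsilon` keeps zero-within-variance genes finite (they rank first, as
#' the criterion intends), and ties are broken by probe id so rankings are
#' fully deterministic. The class-size-weighted BSS is the standard ANOVA
#' decomposition.
#'
#' @param x Numeric matrix, genes x samples, with probe ids as row names.
#' @param labels Class label per sample (length `ncol(x)`, >= 2 classes,
#'   no missing values).
#' @param epsilon Stabilizer added to WSS in the ratio.
#' @return A data frame with `probe_id`, `bss`, `wss`, `ratio`, `rank`
#'   (1-based), sorted by rank.
#' @examples
#' x <- rbind(g1 = c(0, 2, 3, 5), g2 = c(1, 3, 1, 3))
#' bss_wss(x, c("A", "A", "B", "B"))
#' @export
bss_wss <- function(x, labels, epsilon = 1e-12) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(rownames(x))) stop("x must have probe ids as row names",
                                 call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != ncol(x))
    stop("labels must have one entry per sample", call. = FALSE)
  if (anyNA(labels)) stop("every sample must be labelled", call. = FALSE)
  cls <- sort_c(unique(labels))
  if (length(cls) < 2L) stop("need at least 2 classes", call. = FALSE)
  n_k <- vapply(cls, function(k) sum(labels == k), numeric(1))
  if (any(n_k == 0)) stop("class with 0 samples: ",
                          paste(cls[n_k == 0], collapse = ", "),
                          call. = FALSE)

  # centre per gene first: exact location invariance and stable sums
  xc <- x - rowMeans(x)
  ind <- vapply(cls, function(k) as.numeric(labels == k),
                numeric(length(labels)))
  means_c <- (xc %*% ind) %*% diag(1 / n_k, nrow = length(cls))
  bss <- as.vector(means_c^2 %*% n_k)
  wss <- rowSums(xc^2) - bss
  wss <- pmax(wss, 0)
  ratio <- bss / (wss + epsilon)

  ord <- order_c(-ratio, rownames(x))
  data.frame(
    probe_id = rownames(x)[ord],
    bss = bss[ord],
    wss = wss[ord],
    ratio = ratio[ord],
    rank = seq_len(nrow(x)),
    stringsAsFactors = FALSE
  )
}

#' Select the top-ranked genes
#'
#' @param scores A score table from [bss_wss()].
#' @param p Number of genes to keep (1 <= p <= number of genes).
#' @return Character vector of the first `p` probe ids in rank order.
#' @export
top_genes <- function(scores, p) {
  stopifnot(is.data.frame(scores), "probe_id" %in% names(scores))
  if (length(p) != 1L || is.na(p) || p < 1 || p > nrow(scores))
    stop("p must be between 1 and the number of scored genes (",
         nrow(scores), ")", call. = FALSE)
  scores$probe_id[seq_len(p)]
}
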