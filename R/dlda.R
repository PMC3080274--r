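#' Fit a diagonal linear discriminant classifier
#'
#' DLDA is the Gaussian classifier with a diagonal covariance matrix shared
#' across classes: per gene it stores the class means and the pooled
#' within-class variance
#' `s2_g = sum_k sum_{i in k} (x_ig - xbar_kg)^2 / (n - K)`
#' (unbiased pooled estimate, floored at `var_floor` so degenerate genes
#' keep finite scores). No class priors enter the rule by default, giving
#' the pure minimum-distance form standard for expression arrays; supply
#' `priors` to add a `-2 log pi_k` term.
#'
#' @param x Numeric matrix, genes x samples, probe ids as row names.
#' @param labels Class label per sample; every class needs >= 2 samples.
#' @param genes Probe ids to use (default: all rows), kept in the given
#'   order.
#' @param priors Optional named vector of class prior probabilities.
#' @param var_floor Lower bound on the pooled variance.
#' @return An object of class `dlda` with components `classes` (sorted
#'   labels), `genes`, `means` (genes x classes), `pooled_var`,
#'   `n_per_class` and `priors`.
#' @seealso [predict.dlda()]
#' @examples
#' x <- rbind(g1 = c(0, 2, 3, 5))
#' fit <- dlda(x, c("A", "A", "B", "B"))
#' fit$pooled_var  # (1 + 1 + 1 + 1) / (4 - 2) = 2
#' @export
dlda <- function(x, labels, genes = rownames(x), priors = NULL,
                 var_floor = 1e-8) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(rownames(x))) stop("x must have probe ids as row names",
                                 call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != ncol(x))
    stop("labels must have one entry per sample", call. = FALSE)
  missing_genes <- setdiff(genes, rownames(x))
  if (length(missing_genes))
    stop("gene(s) not in matrix: ",
         paste(head(missing_genes, 5), collapse = ", "), call. = FALSE)
  cls <- sort_c(unique(labels))
  if (length(cls) < 2L) stop("need at least 2 classes", call. = FALSE)
  n_k <- vapply(cls, function(k) sum(labels == k), numeric(1))
  if (any(n_k < 2))
    stop("class(es) with fewer than 2 samples: ",
         paste(cls[n_k < 2], collapse = ", "), call. = FALSE)
  if (!is.null(priors)) {
    if (is.null(names(priors)) || !setequal(names(priors), cls))
      stop("priors must be named by class", call. = FALSE)
    priors <- priors[cls] / sum(priors)
  }

  xs <- x[genes, , drop = FALSE]
  centre <- rowMeans(xs)
  xc <- xs - centre
  ind <- vapply(cls, function(k) as.numeric(labels == k),
                numeric(length(labels)))
  means_c <- (xc %*% ind) %*% diag(1 / n_k, nrow = length(cls))
  pooled_ss <- rowSums(xc^2) - as.vector(means_c^2 %*% n_k)
  pooled_var <- pmax(pooled_ss / (length(labels) - length(cls)), var_floor)
  means <- means_c + centre
  dimnames(means) <- list(genes, cls)

  structure(list(classes = cls,
                 genes = genes,
                 means = means,
                 pooled_var = stats::setNames(as.vector(pooled_var), genes),
                 n_per_class = stats::setNames(as.integer(n_k), cls),
                 priors = priors),
            class = "dlda")
}

#' Predict classes with a fitted DLDA model
#'
#' Computes, for each sample and class, the variance-weighted squared
#' distance to the class centroid,
#' `score_k = sum_g (x_g - mu_kg)^2 / s2_g` (minus `2 log pi_k` when priors
#' are present), and assigns the class with the smallest score. Ties go to
#' the first class in the model's class order, deterministically.
#'
#' @param object A `dlda` model.
#' @param newdata Numeric matrix (genes x samples) or a named numeric
#'   vector for a single sample; must provide a value for every model gene.
#' @param type `"class"` (default) for labels, `"scores"` for the
#'   samples x classes score matrix.
#' @param ... Unused.
#' @return A factor of predicted labels (with the score matrix as
#'   attribute `"scores"`), or the score matrix if `type = "scores"`.
#' @export
predict.dlda <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, ncol = 1,
                      dimnames = list(names(newdata), "sample"))
  }
  if (is.null(rownames(newdata)))
    stop("newdata must carry probe ids", call. = FALSE)
  missing_genes <- setdiff(object$genes, rownames(newdata))
  if (length(missing_genes))
    stop("newdata is missing value(s) for probe(s): ",
         paste(head(missing_genes, 5), collapse = ", "), call. = FALSE)
  nd <- newdata[object$genes, , drop = FALSE]
  scores <- vapply(object$classes, function(k) {
    colSums((nd - object$means[, k])^2 / object$pooled_var)
  }, numeric(ncol(nd)))
  scores <- matrix(scores, ncol = length(object$classes),
                   dimnames = list(colnames(nd), object$classes))
  if (!is.null(object$priors))
    scores <- sweep(scores, 2, 2 * log(object$priors), `-`)
  if (type == "scores") return(scores)
  pick <- max.col(-scores, ties.method = "first")
  out <- factor(object$classes[pick], levels = object$classes)
  names(out) <- colnames(nd)
  attr(out, "scores") <- scores
  out
}

#' @export
print.dlda <- function(x, ...) {
  cat("DLDA classifier:", length(x$genes), "genes,",
      length(x$classes), "classes (",
      paste(sprintf("%s n=%d", x$classes, x$n_per_class), collapse = ", "),
      ")\n")
  if (!is.null(x$priors))
    cat("  priors:", paste(sprintf("%s=%.3f", x$classes, x$priors),
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.dlda <- function(object, ...) object$means

#' Serialize a DLDA model to JSON
#'
#' Writes classes, genes, class means, pooled variances, class sizes and
#' priors to a JSON document that [read_dlda()] restores exactly.
#'
#' @param model A `dlda` model.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dlda <- function(model, path) {
  stopifnot(inherits(model, "dlda"))
  doc <- list(
    classes = model$classes,
    genes = model$genes,
    means = as.data.frame(model$means),
    pooled_var = as.vector(model$pooled_var),
    n_per_class = as.vector(model$n_per_class),
    priors = if (is.null(model$priors)) NULL else as.vector(model$priors)
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Restore a DLDA model written by [write_dlda()]
#'
#' @param path Path to the JSON document.
#' @return A `dlda` model.
#' @export
read_dlda <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  means <- as.matrix(doc$means)
  dimnames(means) <- list(doc$genes, doc$classes)
  structure(list(classes = doc$classes,
                 genes = doc$genes,
                 means = means,
                 pooled_var = stats::setNames(doc$pooled_var, doc$genes),
                 n_per_class = stats::setNames(as.integer(doc$n_per_class),
                                               doc$classes),
                 priors = if (!length(doc$priors)) NULL else
                   stats::setNames(unlist(doc$priors), doc$classes)),
            class = "dlda")
}
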