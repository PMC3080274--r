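#' Configuration for the synthetic expression study generator
#'
#' Describes a two-batch, multi-class gene expression study with a known
#' number of class-specific informative genes. The defaults emulate a
#' lymph-node biopsy study design: five diagnosis groups (reactive
#' lymphadenopathy `RL`, classical Hodgkin lymphoma `cHL`, diffuse large
#' B-cell lymphoma `DLBCL`, follicular lymphoma `FL`, and a pool of other
#' non-Hodgkin lymphomas `otherNHL`) split into a training batch of 81
#' arrays and an independent test batch of 35.
#'
#' Informative genes for a class have their mean log2 ratio shifted by
#' `effect_size * noise_sd` in samples of that class; the informative sets of
#' distinct classes are disjoint. All randomness downstream derives from the
#' single master `seed`.
#'
#' @param n_genes Number of probes on the simulated array.
#' @param class_spec Named integer vector: samples per diagnosis class.
#' @param n_informative_per_class Number of informative genes per class.
#' @param effect_size Standardized mean shift of informative genes, in units
#'   of `noise_sd`.
#' @param noise_sd Within-class standard deviation of log2 ratios.
#' @param baseline_sd Standard deviation of per-gene baseline means.
#' @param n_batches Number of array batches.
#' @param batch_sizes Integer vector of samples per batch; must sum to
#'   `sum(class_spec)`.
#' @param batch_alloc Optional classes x batches integer matrix allocating
#'   each class across batches (row sums = `class_spec`, column sums =
#'   `batch_sizes`). With the default study layout this is the published
#'   train/test split; otherwise classes are interleaved across batches.
#' @param noise `"gaussian"` (default) or `"t"` for heavier-tailed
#'   within-class noise (scaled to the same SD).
#' @param t_df Degrees of freedom when `noise = "t"` (must exceed 2).
#' @param flag_frac Fraction of spots flagged bad in two-channel simulation.
#' @param seed Master integer seed.
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 200, class_spec = c(A = 10, B = 10),
#'                   n_batches = 1, batch_sizes = 20, seed = 7)
#' cfg
#' @export
sim_config <- function(n_genes = 2000L,
                       class_spec = c(RL = 23L, cHL = 19L, DLBCL = 19L,
                                      FL = 35L, otherNHL = 20L),
                       n_informative_per_class = 20L,
                       effect_size = 2,
                       noise_sd = 0.5,
                       baseline_sd = 0.5,
                       n_batches = 2L,
                       batch_sizes = c(81L, 35L),
                       batch_alloc = NULL,
                       noise = c("gaussian", "t"),
                       t_df = 4,
                       flag_frac = 0.01,
                       seed = 1L) {
  noise <- match.arg(noise)
  fail <- function(field, msg) {
    stop("invalid sim_config: field '", field, "' ", msg, call. = FALSE)
  }
  if (length(n_genes) != 1L || is.na(n_genes) || n_genes < 1)
    fail("n_genes", "must be a positive count")
  if (is.null(names(class_spec)) || any(!nzchar(names(class_spec))))
    fail("class_spec", "must be a named vector of class sizes")
  if (anyDuplicated(names(class_spec)))
    fail("class_spec", "has duplicated class labels")
  if (length(class_spec) < 2L) fail("class_spec", "needs at least 2 classes")
  if (any(is.na(class_spec)) || any(class_spec < 1))
    fail("class_spec", "must contain positive counts")
  if (length(n_informative_per_class) != 1L || n_informative_per_class < 0)
    fail("n_informative_per_class", "must be a non-negative count")
  if (n_informative_per_class * length(class_spec) > n_genes)
    fail("n_informative_per_class",
         "times the number of classes exceeds n_genes")
  if (!is.finite(effect_size)) fail("effect_size", "must be finite")
  if (!is.finite(noise_sd) || noise_sd <= 0)
    fail("noise_sd", "must be > 0")
  if (!is.finite(baseline_sd) || baseline_sd < 0)
    fail("baseline_sd", "must be >= 0")
  if (length(n_batches) != 1L || n_batches < 1)
    fail("n_batches", "must be a positive count")
  if (length(batch_sizes) != n_batches)
    fail("batch_sizes", "must have length n_batches")
  if (any(batch_sizes < 1)) fail("batch_sizes", "must contain positive counts")
  if (sum(batch_sizes) != sum(class_spec))
    fail("batch_sizes", "must sum to the total number of samples")
  if (noise == "t" && t_df <= 2) fail("t_df", "must be > 2")
  if (flag_frac < 0 || flag_frac >= 1) fail("flag_frac", "must be in [0, 1)")
  if (length(seed) != 1L || is.na(seed)) fail("seed", "must be an integer")

  if (is.null(batch_alloc)) {
    batch_alloc <- default_batch_alloc(class_spec, batch_sizes)
  } else {
    batch_alloc <- as.matrix(batch_alloc)
    if (nrow(batch_alloc) != length(class_spec) ||
        ncol(batch_alloc) != n_batches)
      fail("batch_alloc", "must be a classes x batches matrix")
    if (is.null(rownames(batch_alloc)))
      rownames(batch_alloc) <- names(class_spec)
    if (!identical(rownames(batch_alloc), names(class_spec)))
      fail("batch_alloc", "row names must match class_spec labels")
    if (any(batch_alloc < 0)) fail("batch_alloc", "has negative counts")
    if (!all(rowSums(batch_alloc) == class_spec))
      fail("batch_alloc", "row sums must equal class_spec")
    if (!all(colSums(batch_alloc) == batch_sizes))
      fail("batch_alloc", "column sums must equal batch_sizes")
  }

  structure(list(
    n_genes = as.integer(n_genes),
    class_spec = stats::setNames(as.integer(class_spec), names(class_spec)),
    n_informative_per_class = as.integer(n_informative_per_class),
    effect_size = effect_size,
    noise_sd = noise_sd,
    baseline_sd = baseline_sd,
    n_batches = as.integer(n_batches),
    batch_sizes = as.integer(batch_sizes),
    batch_alloc = batch_alloc,
    noise = noise,
    t_df = t_df,
    flag_frac = flag_frac,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Allocation of classes across batches. The published study layout gets its
# actual train/test split; any other design interleaves samples class by
# class so every batch receives a near-proportional mix.
default_batch_alloc <- function(class_spec, batch_sizes) {
  study <- c(RL = 23L, cHL = 19L, DLBCL = 19L, FL = 35L, otherNHL = 20L)
  if (identical(stats::setNames(as.integer(class_spec), names(class_spec)),
                study) &&
      identical(as.integer(batch_sizes), c(81L, 35L))) {
    alloc <- rbind(RL = c(16L, 7L), cHL = c(12L, 7L), DLBCL = c(8L, 11L),
                   FL = c(25L, 10L), otherNHL = c(20L, 0L))
    colnames(alloc) <- NULL
    return(alloc)
  }
  lab <- rep(names(class_spec), times = class_spec)
  within <- unlist(lapply(class_spec, seq_len), use.names = FALSE)
  ord <- order(within, match(lab, names(class_spec)))
  batch <- rep(seq_along(batch_sizes), times = batch_sizes)
  alloc <- table(factor(lab[ord], levels = names(class_spec)), batch)
  alloc <- matrix(as.integer(alloc), nrow = length(class_spec),
                  dimnames = list(names(class_spec), NULL))
  alloc
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat("  genes:", x$n_genes,
      "| informative/class:", x$n_informative_per_class, "\n")
  cat("  classes:",
      paste(sprintf("%s=%d", names(x$class_spec), x$class_spec),
            collapse = ", "), "\n")
  cat("  batches:", paste(x$batch_sizes, collapse = "/"),
      "| effect size:", x$effect_size, "SD | noise SD:", x$noise_sd, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
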