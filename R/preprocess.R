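#' Compute M and A values from a two-channel array
#'
#' Background-corrects both channels (median background subtracted per spot,
#' corrected intensity floored at 1 so logs stay finite), excludes flagged
#' spots, and returns the standard two-colour quantities
#' `M = log2(R/G)` and `A = (log2 R + log2 G)/2` with R the red (Cy5,
#' patient) and G the green (Cy3, reference) corrected intensity.
#'
#' @param array A `two_channel_array` object.
#' @param background `"subtract"` (default) for median-background
#'   subtraction, `"none"` to use raw foregrounds.
#' @return An object of class `ma_values`: a data frame with `block`,
#'   `row`, `column`, `probe_id`, `M`, `A` for the retained (unflagged)
#'   spots, with the array id as attribute `array_id`.
#' @export
compute_ma <- function(array, background = c("subtract", "none")) {
  stopifnot(inherits(array, "two_channel_array"))
  background <- match.arg(background)
  s <- array$spots[array$spots$flag >= 0, , drop = FALSE]
  if (!nrow(s))
    stop("no usable spots on array '", array$array_id,
         "': every spot is flagged", call. = FALSE)
  R <- corrected_intensity(s$f_red, s$b_red, background)
  G <- corrected_intensity(s$f_green, s$b_green, background)
  ma <- data.frame(
    block = s$block, row = s$row, column = s$column,
    probe_id = s$probe_id,
    M = log2(R / G), A = (log2(R) + log2(G)) / 2,
    stringsAsFactors = FALSE
  )
  attr(ma, "array_id") <- array$array_id
  class(ma) <- c("ma_values", "data.frame")
  ma
}

corrected_intensity <- function(fg, bg, background) {
  if (background == "subtract") pmax(fg - bg, 1) else pmax(fg, 1)
}

#' Within-array print-tip Lowess normalization
#'
#' Fits, independently for each print-tip group (block), a robust Lowess
#' curve of M on A and subtracts the fitted value:
#' `M_norm = M - fit(A)`; A is unchanged. Groups with fewer than
#' `min_spots` usable spots fall back to the whole-array fit (reported via
#' a message). This removes smooth intensity-dependent dye bias separately
#' for each print tip.
#'
#' @param ma An `ma_values` object from [compute_ma()].
#' @param span Lowess smoother span (fraction of spots in each local fit),
#'   in (0, 1].
#' @param iter Robustifying iterations passed to [stats::lowess()].
#' @param min_spots Minimum usable spots for a per-tip fit.
#' @return An `ma_values` object with normalized M and an added `fit`
#'   column holding the subtracted curve value per spot.
#' @export
printtip_lowess_normalize <- function(ma, span = 0.3, iter = 3L,
                                      min_spots = 10L) {
  stopifnot(inherits(ma, "ma_values"))
  if (length(span) != 1L || !is.finite(span) || span <= 0 || span > 1)
    stop("span must be in (0, 1]", call. = FALSE)
  fit <- numeric(nrow(ma))
  whole <- NULL
  small <- integer(0)
  for (b in unique(ma$block)) {
    idx <- which(ma$block == b)
    if (length(idx) >= min_spots) {
      fit[idx] <- lowess_fit_at(ma$A[idx], ma$M[idx], span, iter)
    } else {
      small <- c(small, b)
      if (is.null(whole)) whole <- lowess_fit_at(ma$A, ma$M, span, iter)
      idx_all <- idx
      fit[idx_all] <- whole[idx_all]
    }
  }
  if (length(small))
    message("print-tip group(s) ", paste(small, collapse = ", "),
            " had < ", min_spots,
            " usable spots; whole-array Lowess fit used")
  out <- ma
  out$M <- ma$M - fit
  out$fit <- fit
  attr(out, "array_id") <- attr(ma, "array_id")
  class(out) <- class(ma)
  out
}

# Lowess curve of y on x, evaluated back at every x (ties averaged).
lowess_fit_at <- function(x, y, span, iter) {
  lo <- lowess(x, y, f = span, iter = iter)
  approx(lo$x, lo$y, xout = x, rule = 2, ties = mean)$y
}

#' Replicate-CV array quality score
#'
#' Scores one array by the median, over probes printed at least twice, of
#' the coefficient of variation (sample SD / mean) of the
#' background-corrected intensities across replicate spots, averaged over
#' the two channels. Flagged spots are ignored. Arrays whose score exceeds
#' `threshold` are marked for removal (`retained = FALSE`), mirroring the
#' "CV QC score > 1 is sub-optimal" filtering rule. If no probe is
#' replicated, the score falls back to the median per-print-tip SD of M
#' (reported via a message).
#'
#' @param array A `two_channel_array` object.
#' @param threshold Retention threshold on the score (default 1).
#' @param background Background policy, as in [compute_ma()].
#' @return An object of class `array_quality`: list with `array_id`,
#'   `qc_cv_score`, `retained` and the scoring `method` used
#'   (`"replicate_cv"` or `"tip_dispersion"`).
#' @export
array_qc_score <- function(array, threshold = 1,
                           background = c("subtract", "none")) {
  stopifnot(inherits(array, "two_channel_array"))
  background <- match.arg(background)
  s <- array$spots[array$spots$flag >= 0, , drop = FALSE]
  if (!nrow(s))
    stop("no usable spots on array '", array$array_id, "'", call. = FALSE)
  reps <- table(s$probe_id)
  if (any(reps >= 2)) {
    R <- corrected_intensity(s$f_red, s$b_red, background)
    G <- corrected_intensity(s$f_green, s$b_green, background)
    cv_r <- replicate_cv(R, s$probe_id)
    cv_g <- replicate_cv(G, s$probe_id)
    score <- median((cv_r + cv_g) / 2)
    method <- "replicate_cv"
  } else {
    message("array '", array$array_id,
            "' has no replicated probes; using per-tip M dispersion")
    ma <- compute_ma(array, background)
    score <- median(tapply(ma$M, ma$block, sd), na.rm = TRUE)
    method <- "tip_dispersion"
  }
  structure(list(array_id = array$array_id,
                 qc_cv_score = as.numeric(score),
                 retained = as.numeric(score) <= threshold,
                 method = method),
            class = "array_quality")
}

# Per-probe CV (sample SD / mean) for probes with >= 2 replicate spots,
# computed with grouped sums for speed.
replicate_cv <- function(x, probe) {
  g <- factor(probe)
  n <- as.vector(table(g))
  sx <- as.vector(rowsum(x, g))
  sxx <- as.vector(rowsum(x^2, g))
  keep <- n >= 2
  m <- sx[keep] / n[keep]
  v <- (sxx[keep] - n[keep] * m^2) / (n[keep] - 1)
  v <- pmax(v, 0)  # guard tiny negative values from cancellation
  sqrt(v) / m
}

#' @export
print.array_quality <- function(x, ...) {
  cat(sprintf("Array '%s': QC CV score %.4f (%s) -> %s\n", x$array_id,
              x$qc_cv_score, x$method,
              if (x$retained) "retained" else "removed"))
  invisible(x)
}

#' Assemble normalized arrays into an expression matrix
#'
#' Collapses each array's normalized M values to one value per probe (mean
#' over duplicate spots), aligns arrays on the sorted union of probe ids,
#' drops probes missing in more than `max_missing_frac` of the samples
#' (count reported via a message), and imputes any remaining gaps with the
#' probe's median across samples. Samples keep the order of the sample
#' sheet; batch labels are carried along as annotation. Normalization is
#' strictly within-array, so assembling batches separately or together
#' never mixes information across arrays.
#'
#' @param ma_list Named list of (normalized) `ma_values`, names = sample
#'   ids; unnamed entries use their `array_id` attribute.
#' @param sample_sheet Data frame with columns `sample_id`, `class`,
#'   `batch` covering every array.
#' @param max_missing_frac Maximum tolerated fraction of samples missing a
#'   probe before the probe is dropped.
#' @return An object of class `expr_matrix`: list with `values` (probes x
#'   samples numeric matrix, no missing values), `sample_sheet` (rows for
#'   the assembled samples), `batch` (named vector) and `dropped_probes`.
#' @export
assemble_matrix <- function(ma_list, sample_sheet, max_missing_frac = 0.5) {
  stopifnot(is.list(ma_list), is.data.frame(sample_sheet))
  if (is.null(names(ma_list)) || any(!nzchar(names(ma_list))))
    names(ma_list) <- vapply(ma_list, function(m) {
      id <- attr(m, "array_id")
      if (is.null(id)) NA_character_ else id
    }, character(1))
  ids <- names(ma_list)
  unknown <- setdiff(ids, sample_sheet$sample_id)
  if (length(unknown))
    stop("array(s) not in sample sheet: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  collapsed <- lapply(ma_list, function(m) {
    g <- factor(m$probe_id)
    stats::setNames(as.vector(rowsum(m$M, g)) / as.vector(table(g)),
                    levels(g))
  })
  probes <- sort_c(unique(unlist(lapply(collapsed, names), use.names = FALSE)))
  values <- matrix(NA_real_, nrow = length(probes), ncol = length(ids),
                   dimnames = list(probes, ids))
  for (i in seq_along(collapsed))
    values[names(collapsed[[i]]), i] <- collapsed[[i]]

  miss_frac <- rowMeans(is.na(values))
  drop <- miss_frac > max_missing_frac
  if (any(drop))
    message(sum(drop), " probe(s) missing in > ",
            round(100 * max_missing_frac), "% of samples dropped")
  values <- values[!drop, , drop = FALSE]
  if (anyNA(values)) {
    med <- apply(values, 1, median, na.rm = TRUE)
    na_idx <- which(is.na(values), arr.ind = TRUE)
    values[na_idx] <- med[na_idx[, 1]]
  }

  sheet <- sample_sheet[match(ids, sample_sheet$sample_id), , drop = FALSE]
  ord <- order(match(sheet$sample_id, sample_sheet$sample_id))
  sheet <- sheet[ord, , drop = FALSE]
  rownames(sheet) <- NULL
  values <- values[, sheet$sample_id, drop = FALSE]

  structure(list(values = values,
                 sample_sheet = sheet,
                 batch = stats::setNames(sheet$batch, sheet$sample_id),
                 dropped_probes = probes[drop]),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "probes x",
      ncol(x$values), "samples\n")
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$sample_sheet$class)),
                                  table(x$sample_sheet$class)),
                          collapse = ", "), "\n")
  cat("  batches:", paste(sort(unique(x$batch)), collapse = ", "), "\n")
  invisible(x)
}
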