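#' Simulate a labelled log2-ratio expression matrix
#'
#' Draws a probes x samples matrix under the generative model behind DLDA:
#' per-gene baseline means `b_g ~ N(0, baseline_sd)`, homoscedastic
#' within-class noise of SD `noise_sd` (Gaussian by default, optionally
#' scaled-t), and, for each class, a disjoint set of informative genes whose
#' mean is shifted upwards by `effect_size * noise_sd` in samples of that
#' class. Identical seeds give bit-identical output.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list with components
#'   \item{matrix}{numeric matrix, probes x samples, with dimnames.}
#'   \item{sample_sheet}{data frame with `sample_id`, `class`, `batch`.}
#'   \item{truth}{ground-truth record: `informative_genes` (named list of
#'     probe id sets per class), `class_assignments` (named vector) and the
#'     generating `config`.}
#' @examples
#' sim <- simulate_labeled_matrix(sim_config(n_genes = 100,
#'   class_spec = c(A = 5, B = 5), n_informative_per_class = 10,
#'   n_batches = 1, batch_sizes = 10, seed = 1))
#' dim(sim$matrix)
#' @export
simulate_labeled_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_labeled_core(config))
}

# Core generator; assumes the RNG is already seeded by the caller.
simulate_labeled_core <- function(config) {
  G <- config$n_genes
  classes <- names(config$class_spec)
  K <- length(classes)
  m <- config$n_informative_per_class
  n <- sum(config$class_spec)

  probe_ids <- sprintf("g%05d", seq_len(G))
  baseline <- rnorm(G, 0, config$baseline_sd)

  inf_idx <- if (m > 0) sample.int(G, K * m) else integer(0)
  informative <- split(probe_ids[inf_idx],
                       factor(rep(classes, each = m), levels = classes))
  informative <- lapply(informative, sort_c)

  # sample sheet in batch-major order (batch 1 = training batch first)
  alloc <- config$batch_alloc
  sheet <- do.call(rbind, lapply(seq_len(config$n_batches), function(b) {
    cls <- rep(classes, times = alloc[, b])
    if (!length(cls)) return(NULL)
    data.frame(class = cls, batch = b, stringsAsFactors = FALSE)
  }))
  sheet$sample_id <- sprintf("s%03d", seq_len(n))
  sheet <- sheet[, c("sample_id", "class", "batch")]
  rownames(sheet) <- NULL

  delta <- config$effect_size * config$noise_sd
  mu <- matrix(baseline, nrow = G, ncol = n)
  if (m > 0 && delta != 0) {
    for (k in classes) {
      rows <- match(informative[[k]], probe_ids)
      cols <- which(sheet$class == k)
      mu[rows, cols] <- mu[rows, cols] + delta
    }
  }
  eps <- if (config$noise == "gaussian") {
    rnorm(G * n, 0, config$noise_sd)
  } else {
    rt(G * n, df = config$t_df) /
      sqrt(config$t_df / (config$t_df - 2)) * config$noise_sd
  }
  values <- mu + matrix(eps, nrow = G, ncol = n)
  dimnames(values) <- list(probe_ids, sheet$sample_id)

  truth <- list(
    informative_genes = informative,
    class_assignments = stats::setNames(sheet$class, sheet$sample_id),
    config = config
  )
  list(matrix = values, sample_sheet = sheet, truth = truth)
}

#' Simulate raw two-channel arrays with print-tip dye bias
#'
#' Builds on [simulate_labeled_matrix()]: every sample becomes one
#' two-colour array whose spot-level true log2 ratio M is the sample's gene
#' value, perturbed by a smooth per-print-tip sinusoidal function of the
#' mean log intensity A (the classic intensity-dependent dye bias that
#' print-tip Lowess normalization removes). Channels are reconstructed as
#' `log2 R = A + M/2`, `log2 G = A - M/2`, placed on top of positive random
#' backgrounds, and a small fraction of spots is flagged bad. Each probe is
#' printed `spot_replicates` times (adjacent spots in the same block), which
#' feeds the replicate-CV quality score.
#'
#' @param config A [sim_config()] object.
#' @param n_printtips Number of print-tip groups (blocks) per array.
#' @param bias_amplitude Amplitude of the injected dye-bias curve, in log2
#'   units (0 disables the bias).
#' @param bias_period Period of the sinusoidal bias along the A axis, in
#'   log2-intensity units; large relative to the A range, so each curve is a
#'   gentle drift.
#' @param a_mean,a_sd Mean and SD of per-probe base log2 intensity A.
#' @param a_jitter Per-spot SD of A around the probe's base intensity.
#' @param spot_replicates Spots printed per probe.
#'
#' @return A list with `arrays` (list of `two_channel_array` objects, one
#'   per sample), `sample_sheet`, and `truth`. In addition to the labelled
#'   matrix truth, `truth$bias_curves` maps `"<array>.<tip>"` to the curve
#'   parameters (evaluate with [bias_curve_fun()]), and `truth$spot_truth`
#'   stores each array's true and biased M per spot.
#' @export
simulate_two_channel_arrays <- function(config,
                                        n_printtips = 16L,
                                        bias_amplitude = 0.8,
                                        bias_period = 20,
                                        a_mean = 10,
                                        a_sd = 1.5,
                                        a_jitter = 0.3,
                                        spot_replicates = 2L) {
  stopifnot(inherits(config, "sim_config"))
  if (length(n_printtips) != 1L || is.na(n_printtips) || n_printtips < 1)
    stop("n_printtips must be a positive count", call. = FALSE)
  if (spot_replicates < 1)
    stop("spot_replicates must be a positive count", call. = FALSE)

  with_seed(config$seed, {
    sim <- simulate_labeled_core(config)
    G <- config$n_genes
    probe_ids <- rownames(sim$matrix)
    abase <- rnorm(G, a_mean, a_sd)

    # fixed grid layout shared by all arrays: replicates adjacent, blocks
    # filled contiguously, 1-based row/column indices within each block
    probe_of_spot <- rep(seq_len(G), each = spot_replicates)
    S <- length(probe_of_spot)
    per_tip <- ceiling(S / n_printtips)
    block <- rep(seq_len(n_printtips), each = per_tip)[seq_len(S)]
    within <- (seq_len(S) - 1L) %% per_tip + 1L
    ncol_grid <- ceiling(sqrt(per_tip))
    grid_row <- (within - 1L) %/% ncol_grid + 1L
    grid_col <- (within - 1L) %% ncol_grid + 1L

    bias_curves <- list()
    spot_truth <- list()
    arrays <- vector("list", ncol(sim$matrix))
    names(arrays) <- colnames(sim$matrix)

    for (j in seq_len(ncol(sim$matrix))) {
      id <- colnames(sim$matrix)[j]
      A <- abase[probe_of_spot] + rnorm(S, 0, a_jitter)
      m_true <- sim$matrix[probe_of_spot, j]
      phase <- runif(n_printtips, 0, 2 * pi)
      bias <- numeric(S)
      for (b in seq_len(n_printtips)) {
        pars <- list(amplitude = bias_amplitude, period = bias_period,
                     center = a_mean, phase = phase[b])
        bias_curves[[paste(id, b, sep = ".")]] <- pars
        sel <- block == b
        bias[sel] <- bias_curve_fun(pars)(A[sel])
      }
      m_biased <- m_true + bias
      log_r <- A + m_biased / 2
      log_g <- A - m_biased / 2
      b_red <- runif(S, 20, 60)
      b_green <- runif(S, 20, 60)
      flag <- ifelse(runif(S) < config$flag_frac, -100L, 0L)
      spots <- data.frame(
        block = block, row = grid_row, column = grid_col,
        probe_id = probe_ids[probe_of_spot],
        f_red = b_red + 2^log_r, b_red = b_red,
        f_green = b_green + 2^log_g, b_green = b_green,
        flag = flag,
        stringsAsFactors = FALSE
      )
      arrays[[j]] <- new_two_channel_array(id, spots)
      spot_truth[[id]] <- data.frame(
        block = block, row = grid_row, column = grid_col,
        probe_id = probe_ids[probe_of_spot],
        m_true = m_true, m_biased = m_biased, a_true = A,
        flag = flag, stringsAsFactors = FALSE
      )
    }

    truth <- sim$truth
    truth$bias_curves <- bias_curves
    truth$spot_truth <- spot_truth
    list(arrays = arrays, sample_sheet = sim$sample_sheet, truth = truth)
  })
}

#' Evaluate a stored dye-bias curve
#'
#' Turns the parameter record stored in `truth$bias_curves` into the smooth
#' function of A that was added to the true M values of one print-tip group.
#'
#' @param pars List with `amplitude`, `period`, `center`, `phase`.
#' @return A function of the mean log2 intensity A.
#' @export
bias_curve_fun <- function(pars) {
  force(pars)
  function(A) {
    pars$amplitude * sin(2 * pi * (A - pars$center) / pars$period + pars$phase)
  }
}
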