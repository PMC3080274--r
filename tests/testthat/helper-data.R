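# Small reusable fixture builders (all data generated in code).

small_config <- function(seed = 1, n_genes = 100L, per_class = 10L,
                         n_classes = 2L, m = 10L, effect = 3,
                         noise_sd = 1, ...) {
  cls <- stats::setNames(rep(per_class, n_classes),
                         paste0("C", seq_len(n_classes)))
  sim_config(n_genes = n_genes, class_spec = cls,
             n_informative_per_class = m, effect_size = effect,
             noise_sd = noise_sd, n_batches = 1L,
             batch_sizes = sum(cls), seed = seed, ...)
}

# self-self hybridization design: no differential signal, spot noise only;
# the standard benchmark for normalization recovery
selfself_config <- function(seed, n_genes = 19200L, noise_sd = 0.15) {
  sim_config(n_genes = n_genes, class_spec = c(ref1 = 1L, ref2 = 1L),
             n_informative_per_class = 0L, noise_sd = noise_sd,
             baseline_sd = 0, n_batches = 1L, batch_sizes = 2L,
             seed = seed)
}

# hand-built two-channel array from explicit channel values
make_array <- function(f_red, b_red, f_green, b_green,
                       probe_id = sprintf("p%02d", seq_along(f_red)),
                       block = rep(1L, length(f_red)),
                       flag = rep(0L, length(f_red)),
                       array_id = "arr1") {
  n <- length(f_red)
  spots <- data.frame(
    block = block,
    row = rep(1L, n),
    column = seq_len(n),
    probe_id = probe_id,
    f_red = f_red, b_red = b_red, f_green = f_green, b_green = b_green,
    flag = flag,
    stringsAsFactors = FALSE
  )
  dldacv:::new_two_channel_array(array_id, spots)
}

# hand-built ma_values object
make_ma <- function(probe_id, M, A = rep(10, length(M)),
                    block = rep(1L, length(M)), array_id = "arr1") {
  ma <- data.frame(block = block, row = rep(1L, length(M)),
                   column = seq_along(M), probe_id = probe_id,
                   M = M, A = A, stringsAsFactors = FALSE)
  attr(ma, "array_id") <- array_id
  class(ma) <- c("ma_values", "data.frame")
  ma
}

# GPR-like spot file text for the standard 9 columns
gpr_text <- function(rows, header = TRUE, comments = character(0)) {
  hdr <- paste(c("Block", "Row", "Column", "ID", "F635 Median",
                 "B635 Median", "F532 Median", "B532 Median", "Flags"),
               collapse = "\t")
  c(comments, if (header) hdr, rows)
}
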