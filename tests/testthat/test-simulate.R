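test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(batch_sizes = c(80L, 35L)), "batch_sizes")
  expect_error(sim_config(n_informative_per_class = 1000,
                          n_genes = 100), "n_informative_per_class")
  expect_error(sim_config(class_spec = c(10, 10)), "class_spec")
  expect_error(
    sim_config(class_spec = c(A = 4L, B = 4L), n_batches = 2L,
               batch_sizes = c(4L, 4L),
               batch_alloc = rbind(A = c(3L, 1L), B = c(2L, 2L))),
    "batch_alloc")
})

test_that("the default configuration reproduces the two-batch study layout", {
  cfg <- sim_config()
  expect_identical(sum(cfg$class_spec), 116L)
  expect_identical(cfg$batch_sizes, c(81L, 35L))
  expect_identical(unname(cfg$batch_alloc[, 1]), c(16L, 12L, 8L, 25L, 20L))
  expect_identical(unname(cfg$batch_alloc[, 2]), c(7L, 7L, 11L, 10L, 0L))
  sim <- simulate_labeled_matrix(cfg)
  sheet <- sim$sample_sheet
  expect_identical(nrow(sheet), 116L)
  expect_identical(sum(sheet$batch == 1), 81L)
  expect_identical(sum(sheet$class == "FL" & sheet$batch == 1), 25L)
  expect_identical(sum(sheet$class == "otherNHL" & sheet$batch == 2), 0L)
})

test_that("matrix simulation has the requested shape and is bit-reproducible", {
  cfg <- small_config(seed = 42, n_genes = 100, per_class = 10,
                      n_classes = 4, effect = 3)
  sim1 <- simulate_labeled_matrix(cfg)
  sim2 <- simulate_labeled_matrix(cfg)
  expect_identical(dim(sim1$matrix), c(100L, 40L))
  expect_identical(sim1$matrix, sim2$matrix)
  expect_identical(sim1$truth$informative_genes,
                   sim2$truth$informative_genes)
  expect_true(all(is.finite(sim1$matrix)))
  # informative sets are disjoint between classes
  inf <- sim1$truth$informative_genes
  expect_identical(anyDuplicated(unlist(inf)), 0L)
  # the generator does not clobber the session RNG stream
  set.seed(7); before <- rnorm(3)
  set.seed(7); invisible(simulate_labeled_matrix(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("zero effect size leaves informative genes at the null", {
  cfg <- small_config(seed = 3, n_genes = 200, per_class = 30, m = 40,
                      effect = 0)
  sim <- simulate_labeled_matrix(cfg)
  lab <- sim$sample_sheet$class
  inf <- sim$truth$informative_genes[["C1"]]
  tstats <- apply(sim$matrix[inf, ], 1, function(v)
    t.test(v[lab == "C1"], v[lab != "C1"])$statistic)
  # t statistics behave like null draws: centred, unit-ish spread
  expect_lt(abs(mean(tstats)), 0.5)
  expect_gt(sd(tstats), 0.6)
  expect_lt(sd(tstats), 1.6)
})

test_that("the generating effect size is recovered from sample means", {
  # effect 3, noise_sd 1 => class-vs-rest mean difference on informative
  # genes approaches 3.0 as n grows (Monte-Carlo check at n = 1000)
  cfg <- sim_config(n_genes = 100, class_spec = c(A = 500L, B = 500L),
                    n_informative_per_class = 20, effect_size = 3,
                    noise_sd = 1, baseline_sd = 1, n_batches = 1,
                    batch_sizes = 1000L, seed = 9)
  sim <- simulate_labeled_matrix(cfg)
  lab <- sim$sample_sheet$class
  inf <- sim$truth$informative_genes[["A"]]
  diffs <- rowMeans(sim$matrix[inf, lab == "A"]) -
    rowMeans(sim$matrix[inf, lab != "A"])
  expect_equal(mean(diffs), 3.0, tolerance = 0.05)
})

test_that("two-channel simulation round-trips through compute_ma", {
  cfg <- small_config(seed = 5, n_genes = 300, per_class = 2)
  tc <- simulate_two_channel_arrays(cfg, n_printtips = 4,
                                    bias_amplitude = 0.8)
  expect_length(tc$arrays, 4L)
  a <- tc$arrays[[1]]
  st <- tc$truth$spot_truth[[a$array_id]]
  ma <- compute_ma(a)
  keep <- st$flag >= 0
  expect_equal(ma$M, st$m_biased[keep], tolerance = 1e-9)
  expect_equal(ma$A, st$a_true[keep], tolerance = 1e-9)
  # foregrounds exceed backgrounds on every spot
  expect_true(all(a$spots$f_red > a$spots$b_red))
  expect_true(all(a$spots$f_green > a$spots$b_green))
  # reruns are bit-identical
  tc2 <- simulate_two_channel_arrays(cfg, n_printtips = 4,
                                     bias_amplitude = 0.8)
  expect_identical(tc$arrays[[2]]$spots, tc2$arrays[[2]]$spots)
})

test_that("zero bias amplitude leaves true M untouched and flags are drawn", {
  cfg <- small_config(seed = 6, n_genes = 200, per_class = 2,
                      flag_frac = 0.05)
  tc <- simulate_two_channel_arrays(cfg, n_printtips = 2,
                                    bias_amplitude = 0)
  st <- tc$truth$spot_truth[[1]]
  expect_equal(st$m_biased, st$m_true, tolerance = 1e-12)
  flags <- unlist(lapply(tc$arrays, function(a) a$spots$flag))
  expect_gt(sum(flags < 0), 0)
  expect_error(simulate_two_channel_arrays(cfg, n_printtips = -1),
               "n_printtips")
})

test_that("stored bias curves reproduce the injected perturbation", {
  cfg <- small_config(seed = 8, n_genes = 250, per_class = 2)
  tc <- simulate_two_channel_arrays(cfg, n_printtips = 5,
                                    bias_amplitude = 0.6)
  st <- tc$truth$spot_truth[[1]]
  id <- names(tc$arrays)[1]
  for (b in unique(st$block)) {
    sel <- st$block == b
    pars <- tc$truth$bias_curves[[paste(id, b, sep = ".")]]
    expect_equal(st$m_biased[sel] - st$m_true[sel],
                 bias_curve_fun(pars)(st$a_true[sel]), tolerance = 1e-12)
  }
})
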