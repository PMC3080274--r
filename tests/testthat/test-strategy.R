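study_train_labels <- function() {
  sheet <- simulate_labeled_matrix(
    sim_config(n_genes = 10, n_informative_per_class = 1))$sample_sheet
  sheet$class[sheet$batch == 1]
}

test_that("one-vs-rest relabelling pools every non-target sample", {
  lab <- study_train_labels()  # the 81-sample training batch
  spec <- strategy_spec("FL v rest", "global_binary", positive_class = "FL")
  rl <- relabel(lab, spec)
  expect_true(all(rl$keep))
  expect_identical(sum(rl$labels == "FL"), 25L)
  expect_identical(sum(rl$labels == "rest"), 56L)
  expect_error(relabel(c("A", "A", "B"),
                       strategy_spec("x", "global_binary",
                                     positive_class = "FL")),
               "not present")
})

test_that("local binary comparisons exclude unmapped classes", {
  lab <- study_train_labels()
  spec <- strategy_spec("cHL v NHL", "local_binary",
                        relabel_map = c(cHL = "cHL", DLBCL = "NHL",
                                        FL = "NHL", otherNHL = "NHL"))
  rl <- relabel(lab, spec)
  expect_false(any(lab[rl$keep] == "RL"))   # RL samples excluded
  expect_identical(sum(rl$labels == "cHL"), 12L)
  expect_identical(sum(rl$labels == "NHL"), 53L)  # DLBCL + FL + otherNHL

  # mapping every sample to one analysis label is rejected
  one <- strategy_spec("bad", "local_binary",
                       relabel_map = c(cHL = "x", DLBCL = "x",
                                       FL = "y"))
  expect_error(relabel(c("cHL", "DLBCL", "cHL"), one), "single class")
})

test_that("multiclass relabelling keeps the listed classes only", {
  lab <- study_train_labels()
  spec <- strategy_spec("4-class", "multiclass",
                        classes_included = c("RL", "cHL", "FL", "DLBCL"))
  rl <- relabel(lab, spec)
  expect_identical(sum(rl$keep), 61L)  # 81 minus the 20 otherNHL
  expect_setequal(unique(rl$labels), c("cHL", "DLBCL", "FL", "RL"))
  expect_error(relabel(lab, strategy_spec("u", "multiclass",
                                          classes_included = c("RL", "cHL", "XX"))),
               "XX")
})

test_that("a strategy tested on its own training data is perfect when separable", {
  cfg <- small_config(seed = 50, n_genes = 150, per_class = 10,
                      n_classes = 3, m = 10, effect = 5)
  sim <- simulate_labeled_matrix(cfg)
  lab <- sim$sample_sheet$class
  spec <- strategy_spec("all", "multiclass")
  res <- run_strategy(sim$matrix, lab, sim$matrix, lab, spec,
                      grid = c(10L, 30L))
  expect_equal(res$test_accuracy, 100)
  expect_equal(res$training_accuracy,
               100 - res$cv_profile$optimal_error)
  expect_identical(res$n_test, 30L)
})

test_that("independent draws from the same model are classified accurately", {
  cfg <- sim_config(n_genes = 300, class_spec = c(A = 30L, B = 60L),
                    n_informative_per_class = 15, effect_size = 4,
                    n_batches = 2, batch_sizes = c(60L, 30L),
                    batch_alloc = rbind(A = c(20L, 10L), B = c(40L, 20L)),
                    seed = 51)
  sim <- simulate_labeled_matrix(cfg)
  tr <- sim$sample_sheet$batch == 1
  spec <- strategy_spec("A v rest", "global_binary", positive_class = "A")
  res <- run_strategy(sim$matrix[, tr], sim$sample_sheet$class[tr],
                      sim$matrix[, !tr], sim$sample_sheet$class[!tr],
                      spec, grid = c(10L, 20L, 30L))
  expect_gte(res$test_accuracy, 90)
})

test_that("with no signal, test accuracy hovers at the majority rate", {
  accs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_genes = 150, class_spec = c(A = 20L, B = 10L),
                      n_informative_per_class = 0, effect_size = 0,
                      n_batches = 2, batch_sizes = c(20L, 10L),
                      batch_alloc = rbind(A = c(13L, 7L), B = c(7L, 3L)),
                      seed = 100 + s)
    sim <- simulate_labeled_matrix(cfg)
    tr <- sim$sample_sheet$batch == 1
    res <- run_strategy(sim$matrix[, tr], sim$sample_sheet$class[tr],
                        sim$matrix[, !tr], sim$sample_sheet$class[!tr],
                        strategy_spec("A v rest", "global_binary",
                                      positive_class = "A"),
                        grid = c(10L, 20L))
    res$test_accuracy
  }, numeric(1))
  # majority class is 70% of the test set; a pure-noise classifier sits
  # between coin-flip (50) and majority (70) accuracy and cannot
  # systematically beat the majority rate
  expect_lt(mean(accs), 78)
  expect_gt(mean(accs), 42)
})

test_that("disjoint probe universes are rejected, partial overlap intersected", {
  x1 <- matrix(rnorm(40), 4, 10,
               dimnames = list(c("a", "b", "c", "d"), NULL))
  x2 <- matrix(rnorm(40), 4, 10,
               dimnames = list(c("e", "f", "g", "h"), NULL))
  lab <- rep(c("A", "B"), each = 5)
  spec <- strategy_spec("x", "global_binary", positive_class = "A")
  expect_error(run_strategy(x1, lab, x2, lab, spec, grid = 2L),
               "no probes")
  x3 <- x2; rownames(x3) <- c("a", "b", "c", "z")
  expect_message(res <- run_strategy(x1, lab, x3, lab, spec, grid = 2L),
                 "3 probes")
  expect_identical(res$final_model$genes %in% c("a", "b", "c"),
                   rep(TRUE, length(res$final_model$genes)))
})
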