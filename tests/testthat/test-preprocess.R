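test_that("M and A match hand-computed log ratios", {
  a <- make_array(f_red = c(1000, 640), b_red = c(0, 0),
                  f_green = c(250, 640), b_green = c(0, 0))
  ma <- compute_ma(a)
  expect_equal(ma$M[1], 2.0, tolerance = 1e-12)
  expect_equal(ma$A[1], (log2(1000) + log2(250)) / 2, tolerance = 1e-12)
  expect_equal(ma$M[2], 0, tolerance = 1e-12)  # R = G
})

test_that("background exceeding foreground is floored, logs stay finite", {
  a <- make_array(f_red = 100, b_red = 150, f_green = 400, b_green = 100)
  ma <- compute_ma(a)
  expect_true(is.finite(ma$M))
  expect_equal(ma$M, log2(1 / 300), tolerance = 1e-12)
})

test_that("an all-flagged array yields a 'no usable spots' error", {
  a <- make_array(f_red = c(10, 10), b_red = c(0, 0),
                  f_green = c(10, 10), b_green = c(0, 0),
                  flag = c(-100L, -50L))
  expect_error(compute_ma(a), "no usable spots")
})

test_that("a constant M offset is removed exactly per print-tip group", {
  set.seed(1)
  ma <- make_ma(sprintf("p%03d", 1:60), M = rep(c(0.7, -0.3), each = 30),
                A = runif(60, 6, 14), block = rep(c(1L, 2L), each = 30))
  norm <- printtip_lowess_normalize(ma)
  expect_equal(norm$M, rep(0, 60), tolerance = 1e-9)
  expect_identical(norm$A, ma$A)
  expect_error(printtip_lowess_normalize(ma, span = 1.5), "span")
})

test_that("tiny print-tip groups fall back to the whole-array fit", {
  set.seed(2)
  ma <- make_ma(sprintf("p%03d", 1:55), M = rnorm(55, 1, 0.01),
                A = runif(55, 6, 14),
                block = c(rep(1L, 50), rep(2L, 5)))
  expect_message(norm <- printtip_lowess_normalize(ma), "whole-array")
  expect_lt(max(abs(norm$M)), 0.1)
})

test_that("injected sinusoidal dye bias is removed on self-self arrays", {
  tc <- simulate_two_channel_arrays(selfself_config(31, n_genes = 4800),
                                    n_printtips = 8, bias_amplitude = 0.8,
                                    spot_replicates = 1)
  ma <- compute_ma(tc$arrays[[1]])
  norm <- printtip_lowess_normalize(ma)
  id <- names(tc$arrays)[1]
  for (b in unique(norm$block)) {
    sel <- norm$block == b
    expect_lt(abs(median(norm$M[sel])), 0.05)
    pars <- tc$truth$bias_curves[[paste(id, b, sep = ".")]]
    truth <- bias_curve_fun(pars)(norm$A[sel])
    q <- quantile(norm$A[sel], c(0.05, 0.95))
    central <- norm$A[sel] >= q[1] & norm$A[sel] <= q[2]
    expect_lt(max(abs(norm$fit[sel][central] - truth[central])), 0.1)
  }
})

test_that("a bias-free array is already centred after normalization", {
  tc <- simulate_two_channel_arrays(selfself_config(32, n_genes = 9600),
                                    n_printtips = 8, bias_amplitude = 0,
                                    spot_replicates = 1)
  st <- tc$truth$spot_truth[[1]]
  ma <- compute_ma(tc$arrays[[1]])
  norm <- printtip_lowess_normalize(ma)
  m_centred <- st$m_true[st$flag >= 0] -
    ave(st$m_true[st$flag >= 0], st$block[st$flag >= 0])
  # evaluated over the central 90% of the intensity range per tip, where
  # the local smoother is well determined (edges carry its usual inflation)
  central <- ave(norm$A, norm$block, FUN = function(a)
    a >= quantile(a, 0.05) & a <= quantile(a, 0.95)) == 1
  expect_lt(max(abs(norm$M - m_centred)[central]), 0.05)
})

test_that("normalization is idempotent within smoother tolerance", {
  tc <- simulate_two_channel_arrays(selfself_config(33, n_genes = 4800),
                                    n_printtips = 8, bias_amplitude = 0.8,
                                    spot_replicates = 1)
  n1 <- printtip_lowess_normalize(compute_ma(tc$arrays[[1]]))
  n2 <- printtip_lowess_normalize(n1)
  med1 <- tapply(n1$M, n1$block, median)
  med2 <- tapply(n2$M, n2$block, median)
  expect_lt(max(abs(med1 - med2)), 0.01)
})

test_that("replicate-CV quality score matches hand computation", {
  # identical replicates: score 0, retained
  a0 <- make_array(f_red = c(100, 100, 40, 40), b_red = rep(0, 4),
                   f_green = c(80, 80, 30, 30), b_green = rep(0, 4),
                   probe_id = c("p1", "p1", "p2", "p2"))
  q0 <- array_qc_score(a0)
  expect_equal(q0$qc_cv_score, 0, tolerance = 1e-12)
  expect_true(q0$retained)

  # replicates {100, 300}: CV = sd/mean = sqrt(2)*100/200
  a1 <- make_array(f_red = c(100, 300, 100, 300), b_red = rep(0, 4),
                   f_green = c(100, 300, 100, 300), b_green = rep(0, 4),
                   probe_id = c("p1", "p1", "p2", "p2"))
  q1 <- array_qc_score(a1)
  expect_equal(q1$qc_cv_score, sqrt(2) * 100 / 200, tolerance = 1e-12)
  expect_true(q1$retained)

  # near-maximal replicate disagreement: CV ~ 1.41 > 1 => removed
  a2 <- make_array(f_red = c(1, 1000, 1, 1000), b_red = rep(0, 4),
                   f_green = c(1, 1000, 1, 1000), b_green = rep(0, 4),
                   probe_id = c("p1", "p1", "p2", "p2"))
  q2 <- array_qc_score(a2)
  expect_gt(q2$qc_cv_score, 1)
  expect_false(q2$retained)
})

test_that("arrays without replicated probes fall back to tip dispersion", {
  a <- make_array(f_red = c(100, 120, 140, 160), b_red = rep(0, 4),
                  f_green = c(100, 100, 100, 100), b_green = rep(0, 4))
  expect_message(q <- array_qc_score(a), "no replicated probes")
  expect_identical(q$method, "tip_dispersion")
})

test_that("assembly averages duplicates, drops sparse probes and imputes", {
  sheet <- data.frame(sample_id = c("s1", "s2", "s3"),
                      class = c("A", "A", "B"), batch = 1L,
                      stringsAsFactors = FALSE)
  m1 <- make_ma(c("pA", "pA", "pB", "pC"), M = c(1, 3, 5, 1),
                array_id = "s1")
  m2 <- make_ma(c("pA", "pB"), M = c(2, 6), array_id = "s2")
  m3 <- make_ma(c("pA", "pB"), M = c(4, 8), array_id = "s3")
  expect_message(
    em <- assemble_matrix(list(s1 = m1, s2 = m2, s3 = m3), sheet,
                          max_missing_frac = 0.5),
    "dropped")
  # duplicate spots averaged
  expect_equal(em$values["pA", "s1"], 2)
  # pC missing in 2/3 > 0.5 of samples: dropped
  expect_false("pC" %in% rownames(em$values))
  expect_false(anyNA(em$values))
  expect_identical(rownames(em$values), c("pA", "pB"))

  # a probe missing in a single sample is imputed with its median
  m2b <- make_ma(c("pA", "pB", "pD"), M = c(2, 6, 2), array_id = "s2")
  m3b <- make_ma(c("pA", "pB", "pD"), M = c(4, 8, 4), array_id = "s3")
  em2 <- suppressMessages(
    assemble_matrix(list(s1 = m1, s2 = m2b, s3 = m3b), sheet))
  expect_equal(em2$values["pD", "s2"], 2)
  expect_equal(em2$values["pD", "s1"], 3)  # median of the observed 2 and 4

  expect_error(assemble_matrix(list(sX = m1), sheet), "sX")
})
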