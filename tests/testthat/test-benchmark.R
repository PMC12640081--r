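test_that("run_grid produces one row per (cell, replicate, arm)", {
  cfg <- experiment_config(model = "inflow-I", arms = "dct", L = 6, S = 1,
                           n_sites = 80, theta = 0.01, replicates = 2,
                           use_true_trees = TRUE)
  m <- run_grid(cfg, seed = 11)
  expect_s3_class(m, "metrics_table")
  expect_equal(nrow(m), 2)
  expect_true(all(m$arm == "dct"))
  expect_true(all(!m$failed))
  expect_true(all(is.finite(m$estimate)))
})

test_that("run_grid is deterministic given its seed", {
  cfg <- experiment_config(model = "null", arms = c("dct", "dstat"), L = 8,
                           S = 1, n_sites = 60, theta = 0.01, replicates = 2,
                           use_true_trees = TRUE)
  m1 <- run_grid(cfg, seed = 7)
  m2 <- run_grid(cfg, seed = 7)
  expect_equal(as.data.frame(m1), as.data.frame(m2))
})

test_that("power_table reports percentages with failure accounting", {
  base <- tibble::tibble(model = "inflow-I", L = 250L, S = 2L, n_sites = 250L,
                         theta = 0.01, replicate = 1:10, arm = "dct",
                         estimate = 0.1, stat = NA_real_, p_or_bf = 0.001,
                         reject = c(rep(TRUE, 7), rep(FALSE, 3)),
                         ci_low = NA_real_, ci_high = NA_real_,
                         failed = FALSE)
  p <- power_table(base)
  expect_equal(p$power, 70)
  base$reject <- TRUE
  expect_equal(power_table(base)$power, 100)
  base$reject <- FALSE
  expect_equal(power_table(base)$power, 0)
  # failures excluded from denominators and counted
  base$failed[1:2] <- TRUE
  base$reject[3:4] <- TRUE
  p2 <- power_table(base)
  expect_equal(p2$n_ok, 8)
  expect_equal(p2$n_failed, 2)
  expect_equal(p2$power, 100 * 2 / 8)
})

test_that("estimation_table computes bias, width and coverage", {
  m <- tibble::tibble(model = "inflow-I", L = 250L, S = 2L, n_sites = 250L,
                      theta = 0.01, replicate = 1:5, arm = "bayes",
                      estimate = rep(0.2, 5), stat = NA_real_,
                      p_or_bf = 200, reject = TRUE,
                      ci_low = 0.1, ci_high = 0.3, failed = FALSE)
  e <- estimation_table(m, truth = 0.2)
  expect_equal(e$bias, 0)
  expect_equal(e$coverage, 100)
  expect_equal(e$mean_ci_width, 0.2)
  # the misspecified-mode expectation for the inflow migration model
  expect_equal(mscflow:::config_truth("inflow-M", 0.01, 0.2, 0.1),
               expected_cumulative_introgression(0.1, 0.01, 0.01))
  expect_equal(mscflow:::config_truth("inflow-M", 0.01, 0.2, 0.1),
               1 - exp(-0.4))
})

test_that("null-model grid has near-nominal size for the summary arms", {
  cfg <- experiment_config(model = "null", arms = c("dct", "blt"), L = 200,
                           S = 1, n_sites = 100, theta = 0.01,
                           replicates = 40, alpha = 0.05,
                           use_true_trees = TRUE)
  m <- run_grid(cfg, seed = 29)
  p <- power_table(m)
  expect_true(all(p$power <= 20)) # 3 binomial SEs above 5% at R = 40
})
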