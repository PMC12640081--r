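test_that("one-component fit recovers a pure exponential", {
  set.seed(71)
  x <- rexp(500, rate = 5)
  f1 <- quibl_fit(x, components = 1)
  expect_equal(f1$lambda, 1 / mean(x), tolerance = 1e-9)
  expect_true(f1$converged)
  expect_equal(f1$bic, -2 * f1$loglik + log(500))
})

test_that("model choice favours one component under the null", {
  set.seed(72)
  wins <- 0; small_pi2 <- 0
  for (r in 1:20) {
    x <- rexp(500, rate = 5)
    f1 <- quibl_fit(x, components = 1)
    f2 <- quibl_fit(x, components = 2)
    if (f1$bic < f2$bic + 10) wins <- wins + 1
    if (f2$pi2 <= 0.1 || f1$bic - f2$bic < 10) small_pi2 <- small_pi2 + 1
  }
  expect_gte(wins, 18)       # >= 90%: no spurious second component
  expect_gte(small_pi2, 18)
})

test_that("two-component fit recovers mixture parameters", {
  set.seed(73)
  ok_pi <- 0; ok_C <- 0
  for (r in 1:10) {
    x <- c(rexp(500, 5), 0.3 + rexp(500, 5))[sample(1000)]
    f2 <- quibl_fit(x, components = 2)
    if (abs(f2$pi2 - 0.5) < 0.1) ok_pi <- ok_pi + 1
    if (abs(f2$C - 0.3) < 0.05) ok_C <- ok_C + 1
  }
  expect_gte(ok_pi, 9)
  expect_gte(ok_C, 9)
})

test_that("degenerate and invalid inputs are handled", {
  z <- rep(0, 10)
  f <- quibl_fit(z, components = 1)
  expect_true(f$degenerate)
  f2 <- quibl_fit(z, components = 2)
  expect_true(f2$degenerate)
  expect_error(quibl_fit(c(-1, rexp(20))), "nonnegative")
  expect_error(quibl_fit(rexp(5)), "at least 10")
})

test_that("triplet-level mixture test behaves at its extremes", {
  set.seed(74)
  l1 <- rexp(100, 5)
  l2 <- c(rexp(60, 5), 0.5 + rexp(60, 5))
  cc <- structure(list(c_con = 300, c_dis1 = 100, c_dis2 = 120,
                       len_con = numeric(0), len_dis1 = l1, len_dis2 = l2,
                       n_excluded = 0L), class = "triplet_counts")
  r <- quibl_test(cc)
  expect_true(r$dis2$significant)
  expect_true(r$significant)
  # an infinite BIC threshold can never be met
  r_inf <- quibl_test(cc, delta_bic_threshold = Inf)
  expect_false(r_inf$significant)
  # classes below the minimum size are insufficient, not errors
  cc2 <- cc; cc2$len_dis2 <- rexp(5, 5)
  r2 <- quibl_test(cc2)
  expect_false(r2$significant)
  expect_true(r2$dis2$insufficient)
})

test_that("resolution-aware likelihood ignores sub-resolution structure", {
  # quantised lengths: zeros plus atoms at the resolution limit, as produced
  # by ML estimation on short loci; the continuous model mistakes the atoms
  # for a shifted component, the binned model must not
  set.seed(75)
  x <- c(rep(0, 150), rep(0.004, 40), rep(0.008, 10))
  f1 <- quibl_fit(x, 1, resolution = 0.004)
  f2 <- quibl_fit(x, 2, resolution = 0.004)
  expect_lt(f1$bic - f2$bic, 10)
  # with a genuinely shifted cloud far above resolution, detection returns
  y <- c(rexp(150, 400), 0.05 + rexp(100, 400))
  g1 <- quibl_fit(y, 1, resolution = 0.004)
  g2 <- quibl_fit(y, 2, resolution = 0.004)
  expect_gte(g1$bic - g2$bic, 10)
  expect_gt(g2$pi2, 0.2)
})

test_that("mixture phi estimate scales pi2 by the dis2 class frequency", {
  set.seed(76)
  l2 <- c(rexp(50, 5), 0.5 + rexp(50, 5))
  cc <- structure(list(c_con = 700, c_dis1 = 100, c_dis2 = 200,
                       len_con = numeric(0), len_dis1 = rexp(100, 5),
                       len_dis2 = l2, n_excluded = 0L),
                  class = "triplet_counts")
  est <- quibl_phi_estimate(cc)
  expect_gt(est, 0.05)
  expect_lt(est, 0.2)
})
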