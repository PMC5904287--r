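# Noise-scale estimation and the minimax threshold.

test_that("sigma estimator has its closed forms and equivariance", {
  expect_equal(estimate_sigma(c(-0.6745, 0.6745, 0.6745)), 1)
  expect_equal(estimate_sigma(rep(0, 16)), 0)
  expect_error(estimate_sigma(numeric(0)), "empty")
  set.seed(2)
  u <- rnorm(64)
  expect_equal(estimate_sigma(3.7 * u), 3.7 * estimate_sigma(u))
})

test_that("sigma estimator is calibrated for Gaussian noise", {
  set.seed(123)
  expect_true(abs(estimate_sigma(rnorm(1e5)) - 1) < 0.02)
})

test_that("minimax threshold follows its formula and monotonicity", {
  u <- rep(c(-0.6745, 0.6745), 512)  # sigma = 1, N = 1024
  est <- minimaxi_threshold(u)
  expect_equal(est$sigma, 1)
  expect_equal(est$N, 1024L)
  expect_equal(est$T, 0.396 + 0.1829 * 10)
  expect_equal(minimaxi_threshold(rep(0, 8))$T, 0)
  expect_error(minimaxi_threshold(1), "at least 2")
  # a 2-s a-priori window tiled by running windows holds 12 node coefficients
  u12 <- rnorm(12)
  est12 <- minimaxi_threshold(u12, span_s = 2)
  expect_equal(est12$T, estimate_sigma(u12) * (0.396 + 0.1829 * log2(12)))
  # T non-decreasing in N at fixed sigma
  Ns <- c(2, 4, 16, 192, 1024, 23040)
  Tn <- vapply(Ns, function(n) minimaxi_threshold(rep(c(-1, 1) * 0.6745,
                                                      n / 2))$T, numeric(1))
  expect_true(all(diff(Tn) > 0))
})
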