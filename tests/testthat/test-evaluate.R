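# Scoring, delays, the fixed baseline, sweeps and clinical correlation.

bs <- function(x, step_s = 8 / 384, warmup = NULL)
  neurostate:::binary_states(x, step_s = step_s, warmup = warmup)

test_that("scoring has its closed forms and equals the confusion oracle", {
  truth <- bs(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(score_detection(truth, truth)$sensitivity, 1)
  expect_equal(score_detection(truth, truth)$specificity, 1)
  comp <- bs(1L - truth$states)
  expect_equal(score_detection(comp, truth)$sensitivity, 0)
  expect_equal(score_detection(comp, truth)$specificity, 0)
  # 3 of 5 true sync steps identified
  id <- bs(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(score_detection(id, truth)$sensitivity, 0.6)
  set.seed(14)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    idv <- rbinom(n, 1, 0.5); trv <- rbinom(n, 1, 0.5)
    wu <- c(rep(TRUE, 2), rep(FALSE, n - 2))
    got <- score_detection(bs(idv, warmup = wu), bs(trv))
    want <- oracle_confusion(idv, trv, 8 / 384, wu)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
    expect_equal(got$ts, want$ts)
    expect_equal(got$Td, want$Td)
  }
})

test_that("label swap exchanges sensitivity and specificity", {
  set.seed(15)
  idv <- rbinom(40, 1, 0.4); trv <- rbinom(40, 1, 0.5)
  a <- score_detection(bs(idv), bs(trv))
  b <- score_detection(bs(1L - idv), bs(1L - trv))
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)
})

test_that("degenerate truth yields NA metrics, not zero", {
  all1 <- bs(rep(1, 8))
  sc <- score_detection(bs(rep(1, 8)), all1)
  expect_true(is.na(sc$specificity))
  expect_equal(sc$sensitivity, 1)
})

test_that("transition delays measure the shift between aligned series", {
  truth <- bs(rep(rep(c(0, 1), 4), each = 24))
  d0 <- transition_delays(truth, truth, lookahead = c(0, 0))
  expect_true(all(c(d0$sync_onset, d0$desync_onset) == 0))
  shifted <- bs(c(rep(0L, 3), truth$states[1:(length(truth$states) - 3)]))
  d3 <- transition_delays(shifted, truth, lookahead = c(0, 0))
  expect_equal(mean(d3$sync_onset), 3 * 8 / 384 * 1000)  # 62.5 ms
  flat <- bs(rep(0, length(truth$states)))
  expect_true(transition_delays(truth, flat)$no_transitions)
})

test_that("fixed baseline is scale invariant and dominated in sensitivity by the adaptive detector", {
  tr <- generate_trial(simulation_spec("theta", snr_db = -9, duration_s = 40,
                                       seed = 5))
  co <- windowed_decompose(tr$signal, "rbio3.7", 2)
  truth <- truth_states(tr, starts = co$starts)
  fb <- fixed_threshold_baseline(co, truth)
  co_scaled <- co; co_scaled$u <- 42 * co$u
  fb2 <- fixed_threshold_baseline(co_scaled, truth)
  expect_identical(fb$states$states, fb2$states$states)
  ad <- score_detection(detect_states(co), truth)
  expect_gt(ad$sensitivity, fb$sensitivity + 0.1)
  expect_gt(fb$specificity, ad$specificity + 0.05)
})

test_that("a single sweep cell equals the direct generate-detect-score composition", {
  sw <- sweep_n1_n2("theta", n1 = 1, n2 = 6, reps = 1, duration_s = 20,
                    seeds = 0)
  tr <- generate_trial(simulation_spec("theta", snr_db = -9, duration_s = 20,
                                       seed = 0))
  co <- windowed_decompose(tr$signal, "rbio3.7", 2)
  p <- score_detection(detect_states(co), truth_states(tr, starts = co$starts))
  expect_equal(sw$sensitivity, p$sensitivity)
  expect_equal(sw$specificity, p$specificity)
})

test_that("pain relief reproduces its closed forms and rejects bad input", {
  expect_equal(pain_relief(9.8, 3), 69.4, tolerance = 0.05)
  expect_equal(pain_relief(5.6, 2), 64.3, tolerance = 0.05)
  expect_equal(pain_relief(c(8, 10), c(6, 8)), c(25, 20))
  expect_error(pain_relief(0, 0), "positive")
  expect_error(pain_relief(11, 2), "0, 10")
})

test_that("Spearman correlation matches the rank oracle, with ties", {
  expect_equal(correlate_states_with_outcome(1:6, (1:6)^2)$rho, 1)
  set.seed(33)
  for (i in 1:8) {
    n <- sample(5:7, 1)
    x <- sample(1:4, n, replace = TRUE)   # ties likely
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    got <- correlate_states_with_outcome(x, y)
    expect_equal(got$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
    expect_equal(got$p, oracle_spearman_p(x, y), tolerance = 1e-12)
  }
  # large-n branch agrees with the t approximation of cor.test
  x <- rnorm(15); y <- x + rnorm(15)
  got <- correlate_states_with_outcome(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-6)
  expect_error(correlate_states_with_outcome(1:2, 1:2), "at least 3")
})
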