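# State discrimination: the confirmation automaton, adaptive thresholds,
# joint encoding and occurrence frequencies.

test_that("confirmation automaton equals the literal rule simulation", {
  # exhaustive over all 3-symbol coefficient sequences of length 6
  syms <- c(0, 0.5, 2)   # against a frozen threshold of 1
  grids <- expand.grid(rep(list(1:3), 6))
  for (counting in c("additional", "total")) {
    for (n1 in 1:3) for (n2 in 1:3) {
      mismatches <- 0L
      for (r in seq_len(nrow(grids))) {
        u <- syms[as.integer(grids[r, ])]
        cond <- u > 1
        got <- neurostate:::.state_automaton(cond, n1, n2, counting)
        if (!identical(got, oracle_automaton(cond, n1, n2, counting)))
          mismatches <- mismatches + 1L
      }
      expect_equal(mismatches, 0L,
                   label = sprintf("mismatches at n1=%d n2=%d (%s)", n1, n2, counting))
    }
  }
})

test_that("automaton matches the oracle on long random sequences", {
  set.seed(31)
  for (i in 1:150) {
    cond <- runif(20) < runif(1)
    n1 <- sample(1:3, 1); n2 <- sample(1:3, 1)
    cnt <- sample(c("additional", "total"), 1)
    expect_identical(neurostate:::.state_automaton(cond, n1, n2, cnt),
                     oracle_automaton(cond, n1, n2, cnt))
  }
})

test_that("automaton boundary behaviour: constant inputs", {
  expect_equal(neurostate:::.state_automaton(rep(TRUE, 10), 1, 6), rep(1L, 10))
  expect_equal(neurostate:::.state_automaton(rep(FALSE, 10), 1, 6), rep(0L, 10))
})

test_that("all-zero coefficients yield no synchronization", {
  cs <- windowed_decompose(numeric(2304), "rbio3.7", 2)
  st <- detect_states(cs)
  expect_true(all(st$states == 0L))
})

test_that("detector is invariant to amplitude scaling of the signal", {
  tr <- generate_trial(simulation_spec("theta", snr_db = -9, duration_s = 20,
                                       seed = 4))
  c1 <- windowed_decompose(tr$signal, "rbio3.7", 2)
  c2 <- windowed_decompose(137.5 * tr$signal, "rbio3.7", 2)
  expect_identical(detect_states(c1)$states, detect_states(c2)$states)
})

test_that("raising n1 shrinks and raising n2 grows synchronization time", {
  tr <- generate_trial(simulation_spec("theta", snr_db = -9, duration_s = 30,
                                       seed = 8))
  cs <- windowed_decompose(tr$signal, "rbio3.7", 2)
  sync_time <- function(n1, n2)
    sum(detect_states(cs, detector_config(n1 = n1, n2 = n2))$states)
  s_n1 <- vapply(1:5, sync_time, numeric(1), n2 = 3)
  expect_true(all(diff(s_n1) <= 0))
  s_n2 <- vapply(1:6, sync_time, numeric(1), n1 = 2)
  expect_true(all(diff(s_n2) >= 0))
})

test_that("detector labels mostly de-synchronization on pure noise", {
  fr <- vapply(1:3, function(s) {
    set.seed(s)
    st <- detect_states(windowed_decompose(rnorm(384 * 60), "rbio3.7", 2))
    mean(st$states[!st$warmup])
  }, numeric(1))
  expect_lt(mean(fr), 0.2)
})

test_that("warmup covers exactly the first a-priori window", {
  cs <- windowed_decompose(rnorm(2304), "rbio3.7", 2)
  st <- detect_states(cs)       # L_priori = 2 s, step 8 -> 96 steps
  expect_equal(sum(st$warmup), 96)
  expect_true(all(which(st$warmup) == 1:96))
})

test_that("short series and inconsistent configs are rejected", {
  cs <- windowed_decompose(rnorm(160), "rbio3.7", 2)
  expect_error(detect_states(cs), "shorter")
  expect_error(detector_config(n1 = 0), "1..6")
  expect_error(detector_config(n2 = 7), "1..6")
})

test_that("joint encoding maps bits to symbols and round-trips", {
  th <- neurostate:::binary_states(c(1, 0, 1, 1), step_s = 1 / 48)
  al <- neurostate:::binary_states(c(0, 0, 1, 0), step_s = 1 / 48)
  j <- encode_joint(th, al)
  expect_equal(as.character(j$states), c("a0t1", "a0t0", "a1t1", "a0t1"))
  set.seed(12)
  th2 <- neurostate:::binary_states(rbinom(50, 1, 0.4), step_s = 1 / 48)
  al2 <- neurostate:::binary_states(rbinom(50, 1, 0.6), step_s = 1 / 48)
  j2 <- encode_joint(th2, al2)
  expect_equal(j2$theta$states, th2$states)
  expect_equal(as.integer(j2$states %in% c("a0t1", "a1t1")), th2$states)
  expect_equal(as.integer(j2$states %in% c("a1t0", "a1t1")), al2$states)
  bad <- neurostate:::binary_states(c(1, 0), step_s = 1 / 48)
  expect_error(encode_joint(th, bad), "not aligned")
})

test_that("occurrence frequencies sum to 100 and satisfy the marginal identities", {
  set.seed(21)
  th <- neurostate:::binary_states(rbinom(200, 1, 0.3), step_s = 0.02)
  al <- neurostate:::binary_states(rbinom(200, 1, 0.5), step_s = 0.02)
  j <- encode_joint(th, al)
  tab <- occurrence_frequency(j)
  expect_equal(sum(tab), 100, tolerance = 1e-9)
  occ <- state_occurrence(j)
  expect_equal(occ[["t1"]], occ[["a0t1"]] + occ[["a1t1"]], tolerance = 1e-9)
  expect_equal(occ[["a1"]], occ[["a1t0"]] + occ[["a1t1"]], tolerance = 1e-9)
  half <- neurostate:::binary_states(rep(c(0, 1), 10), step_s = 0.02)
  expect_equal(occurrence_frequency(half, 1), 50)
  expect_equal(occurrence_frequency(half, 1) + occurrence_frequency(half, 0), 100)
  none <- neurostate:::binary_states(rep(0, 10), step_s = 0.02)
  expect_equal(occurrence_frequency(none, 1), 0)
})

test_that("the neurostate fit runs end to end on a two-band signal", {
  t <- (0:(384 * 20 - 1)) / 384
  x <- sin(2 * pi * 7.5 * t) * trapezoid_envelope(t) + 0.5 * rnorm(length(t))
  fit <- neurostate(x)
  expect_s3_class(fit, "neurostate")
  expect_named(fit$bands, c("theta", "alpha"))
  expect_s3_class(fit$joint, "joint_states")
  expect_equal(length(fit$joint$states), length(fit$bands$theta$states))
  s <- summary(fit)
  expect_true(all(c("a1", "t1", "a0t0") %in% names(s$occurrence)))
  expect_error(neurostate(x, fs = 500), "384")
})
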