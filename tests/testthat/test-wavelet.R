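# Wavelet packet core: reconstruction, band mapping, windowed transform,
# entropy-based basis ranking, and the window-length sweep.

compact_bases <- setdiff(wp_bases(), "dmey")

test_that("forward/inverse transform reconstructs every compactly supported basis", {
  set.seed(11)
  x <- rnorm(768)
  rms <- sqrt(mean(x^2))
  for (b in compact_bases) {
    d <- wp_decompose(x, b, level = 6)
    expect_lt(max(abs(wp_reconstruct(d) - x)), 1e-8 * rms)
  }
  # the discrete Meyer FIR is a truncated approximation; reconstruction is
  # approximate by construction
  d <- wp_decompose(x, "dmey", level = 6)
  err <- sqrt(mean((wp_reconstruct(d) - x)^2)) / rms
  expect_lt(err, 0.05)
})

test_that("unknown basis and bad lengths are rejected", {
  expect_error(wp_decompose(rnorm(128), "nosuchbasis"), "unknown wavelet basis")
  expect_error(wp_decompose(rnorm(100), "db4", level = 6), "multiple of 2\\^level")
  expect_error(wp_decompose(c(rnorm(127), NA), "db4", level = 6), "non-finite")
})

test_that("node bands tile the Nyquist interval and carry the tree labels", {
  fs <- 384; level <- 6
  bands <- lapply(0:63, band_for_node, fs = fs, level = level)
  expect_equal(bands[[1]]$f_low, 0)
  expect_equal(bands[[64]]$f_high, fs / 2)
  for (i in 1:63)
    expect_equal(bands[[i]]$f_high, bands[[i + 1]]$f_low)
  widths <- vapply(bands, function(b) b$f_high - b$f_low, numeric(1))
  expect_true(all(abs(widths - 3) < 1e-12))
  # theta and alpha land on the conventional tree labels
  expect_equal(node_for_band(6, 9, fs)$label, "[6 3]")
  expect_equal(node_for_band(9, 12, fs)$label, "[6 2]")
  expect_error(node_for_band(6.5, 9.5, fs), "not aligned")
})

test_that("a pure in-band tone concentrates its coefficient energy in its node", {
  t <- (0:2303) / 384
  tone <- sin(2 * pi * 7.5 * t)
  for (b in c("rbio3.7", "db4", "sym8")) {
    d <- wp_decompose(tone, b, level = 6)
    en <- colSums(d$coef^2)
    expect_equal(which.max(en) - 1L, 2L)
    expect_gt(en[3] / sum(en), 0.8)
  }
})

test_that("node reconstructions are additive and a zero node gives zero", {
  set.seed(7)
  x <- rnorm(1536)
  d <- wp_decompose(x, "bior3.7", 6)
  total <- Reduce(`+`, lapply(0:63, function(nd) wp_reconstruct_node(d, nd)))
  expect_lt(max(abs(total - x)), 1e-8 * sqrt(mean(x^2)))
  expect_equal(wp_reconstruct_node(d, 5, coef = rep(0, nrow(d$coef))),
               rep(0, 1536))
  # theta-node reconstruction of a theta tone tracks the tone
  tone <- sin(2 * pi * 7.5 * (0:2303) / 384)
  dt <- wp_decompose(tone, "rbio3.7", 6)
  rec <- wp_reconstruct_node(dt, 2)
  expect_gt(cor(rec, tone), 0.9)
})

test_that("windowed transform frames count, localize and match the full transform", {
  set.seed(3)
  x <- rnorm(2304)
  cs <- windowed_decompose(x, "rbio3.7", 2, L_running = 128, step = 8)
  expect_equal(ncol(cs$u), floor((2304 - 128) / 8) + 1)
  expect_equal(nrow(cs$u), 2)
  # frame depends only on its own window
  y <- x; y[200:2304] <- 0
  cs2 <- windowed_decompose(y, "rbio3.7", 2, L_running = 128, step = 8)
  expect_equal(cs$u[, 1], cs2$u[, 1])
  # first frame equals a direct decomposition of the first window
  d1 <- wp_decompose(x[1:128], "rbio3.7", 6)
  expect_equal(unname(cs$u[, 1]), d1$coef[, 3], tolerance = 1e-12)
  # zero signal gives zero frames; short signals are rejected
  expect_true(all(windowed_decompose(numeric(256), "db4", 2)$u == 0))
  expect_error(windowed_decompose(rnorm(100), "db4", 2), "shorter")
})

test_that("coefficient entropy has its closed forms and bounds", {
  expect_equal(basis_entropy(rep(1, 64)), log(64))
  expect_equal(basis_entropy(c(5, 0, 0, 0)), 0)
  expect_error(basis_entropy(numeric(0)), "empty")
  expect_error(basis_entropy(rep(0, 8)), "all-zero")
  set.seed(5)
  for (i in 1:20) {
    u <- rnorm(32)
    H <- basis_entropy(u)
    expect_gte(H, 0)
    expect_lte(H, log(32) + 1e-12)
  }
})

test_that("basis ranking is deterministic over the full candidate list", {
  # the procedure is the contract: which basis wins depends on the
  # oscillation morphology, and the synthetic trapezoid burst is not a
  # real LFP spindle, so no particular winner is asserted here
  x <- theta_burst_fixture(duration_s = 6, snr_db = -3)$signal
  r1 <- select_basis(x, node = 2)
  r2 <- select_basis(x, node = 2)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 11)
  expect_true(all(is.finite(r1$entropy)))
  expect_true(all(diff(r1$entropy) >= 0))
  single <- select_basis(x, "db4", node = 2)
  expect_equal(single$basis, "db4")
  expect_warning(out <- select_basis(x, c("db4", "bogus"), node = 2), "bogus")
  expect_equal(sort(out$basis), "db4")
})

test_that("relative error matches its closed forms and the literal formula", {
  expect_equal(relative_error(rep(1, 10), rep(1, 10)), 0)
  expect_equal(relative_error(rep(1, 50), rep(1.1, 50)), 10, tolerance = 1e-9)
  zm <- rep(c(1, -1), 50)
  expect_error(relative_error(zm, zm + 0.1), "near zero")
  set.seed(9)
  x <- runif(40, 1, 2); y <- x + rnorm(40, 0, 0.2)
  expect_equal(relative_error(x, y, "mean"),
               oracle_relative_error(x, y, mean(x)), tolerance = 1e-12)
  expect_equal(relative_error(x, y, "rms"),
               oracle_relative_error(x, y, sqrt(mean(x^2))), tolerance = 1e-12)
})

test_that("window-length sweep has local error minima at multiples of 64 samples", {
  x <- theta_burst_fixture(duration_s = 6, snr_db = -9)$signal
  sw <- sweep_window_length(x, "rbio3.7", node = 2,
                            lengths = seq(56, 200, by = 8))
  e <- setNames(sw$error, sw$length)
  for (m in c(64, 128, 192)) {
    expect_lt(e[as.character(m)], e[as.character(m - 8)])
    expect_lt(e[as.character(m)], e[as.character(m + 8)])
  }
  one <- sweep_window_length(x, "rbio3.7", node = 2, lengths = 128)
  expect_equal(nrow(one), 1)
  # oracle: recompute the windowed reconstruction at L = 128 directly
  ref <- wp_reconstruct_node(wp_decompose(x, "rbio3.7", 6), 2)
  y <- unlist(lapply(seq(1, 2304 - 127, by = 128), function(s) {
    wp_reconstruct_node(wp_decompose(x[s:(s + 127)], "rbio3.7", 6), 2)
  }))
  expect_equal(one$error, relative_error(ref, y, "rms"), tolerance = 1e-10)
})
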