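# Preprocessing chain and recording I/O.

test_that("recordings round-trip through CSV and binary formats", {
  set.seed(50)
  rec <- lfp_recording(rnorm(1000), fs = 2000, nucleus = "PVAG",
                       contact_pair = "0-1", subject_id = "s01")
  csv <- tempfile(fileext = ".csv")
  write_recording(rec, csv)
  back <- read_recording(csv)
  expect_equal(back$samples, rec$samples)
  expect_equal(back$fs, 2000)
  expect_equal(back$nucleus, "PVAG")
  expect_equal(back$contact_pair, "0-1")
  bin <- tempfile(fileext = ".bin")
  write_recording(rec, bin)
  back2 <- read_recording(bin)
  expect_identical(back2$samples, rec$samples)
  expect_equal(back2$subject_id, "s01")
})

test_that("CSV metadata header is parsed and malformed input rejected", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("# fs=384", "0.5", "-0.25", "1"), f)
  rec <- read_recording(f)
  expect_equal(rec$fs, 384)
  expect_equal(rec$samples, c(0.5, -0.25, 1))
  writeLines(c("0.5", "1"), f)                 # missing fs
  expect_error(read_recording(f), "fs")
  writeLines(c("# fs=384", "abc"), f)
  expect_error(read_recording(f), "non-numeric")
  expect_error(read_recording(tempfile(fileext = ".xyz")), "format")
})

test_that("recording constructor enforces its invariants", {
  expect_error(lfp_recording(numeric(0), 384), "empty")
  expect_error(lfp_recording(c(1, NA), 384), "non-finite")
  expect_error(lfp_recording(1:10, -1), "positive")
})

test_that("the preprocessing chain outputs 384 Hz with the expected length", {
  set.seed(51)
  rec <- lfp_recording(rnorm(20000), fs = 2000)
  out <- preprocess(rec)
  expect_equal(out$fs, 384)
  expect_lt(abs(length(out$samples) - 20000 * 384 / 2000), 3)
  expect_gte(length(out$provenance), 5)
  expect_error(preprocess(lfp_recording(rnorm(100), fs = 100)), "too low")
})

test_that("zero input stays zero through the chain", {
  out <- preprocess(lfp_recording(rep(0, 10000), fs = 2000))
  expect_lt(max(abs(out$samples)), 1e-12)
})

test_that("mains interference is suppressed and the analysis band is preserved", {
  t <- (0:(2000 * 60 - 1)) / 2000
  mains <- sin(2 * pi * 50 * t)
  out <- preprocess(lfp_recording(mains, fs = 2000))
  expect_lt(sqrt(mean(out$samples^2)) / sqrt(mean(mains^2)), 0.05)
  # a 10 Hz tone passes within +/- 10 % (steady-state portion)
  t <- (0:(2000 * 10 - 1)) / 2000
  tone <- sin(2 * pi * 10 * t)
  o <- preprocess(lfp_recording(tone, fs = 2000))
  mid <- o$samples[1000:3000]
  expect_lt(abs(sqrt(mean(mid^2)) / sqrt(0.5) - 1), 0.1)
})

test_that("out-of-band power is attenuated by at least 20 dB", {
  t <- (0:(2000 * 10 - 1)) / 2000
  for (f in c(1, 120)) {
    tone <- sin(2 * pi * f * t)
    o <- preprocess(lfp_recording(tone, fs = 2000))
    mid <- o$samples[1000:3000]
    atten_db <- 20 * log10(sqrt(mean(mid^2)) / sqrt(0.5))
    expect_lt(atten_db, -20)
  }
})

test_that("zero-phase mode is recorded in provenance and preserves the band", {
  t <- (0:(2000 * 6 - 1)) / 2000
  tone <- sin(2 * pi * 10 * t)
  o <- preprocess(lfp_recording(tone, fs = 2000), zero_phase = TRUE)
  expect_true(any(grepl("zero-phase", o$provenance)))
  mid <- o$samples[800:2000]
  expect_lt(abs(sqrt(mean(mid^2)) / sqrt(0.5) - 1), 0.15)
})
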