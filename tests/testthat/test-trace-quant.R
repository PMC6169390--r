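test_that("window areas integrate single peaks correctly", {
  # flat zero channels: all areas zero
  flat <- trace_data(matrix(0, 50, 4, dimnames = list(NULL, c("A","C","G","T"))),
                     peak_positions = 25, called_bases = "A")
  expect_equal(unname(window_areas(flat, 25)), rep(0, 4))
  # unit-height Gaussian (sigma = 2) in a +/-6 window: area close to the
  # full Gaussian mass sqrt(2*pi)*sigma, computed by an independent fine-grid
  # numerical integration oracle
  x <- 1:60
  g <- exp(-(x - 30)^2 / (2 * 2^2))
  ch <- matrix(0, 60, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  ch[, "C"] <- g
  tr <- trace_data(ch, peak_positions = 30, called_bases = "C")
  a <- window_areas(tr, 30, half_width = 6, baseline = FALSE)
  oracle <- stats::integrate(function(u) exp(-(u - 30)^2 / 8), 24, 36)$value
  expect_equal(unname(a["C"]), oracle, tolerance = 1e-2)
  expect_equal(unname(a[c("A", "G", "T")]), rep(0, 3))
  # linearity: two same-shape peaks with heights 7:3 give areas 7:3
  ch2 <- ch
  ch2[, "T"] <- g * 3 / 7
  tr2 <- trace_data(ch2, peak_positions = 30, called_bases = "C")
  a2 <- window_areas(tr2, 30, half_width = 6, baseline = FALSE)
  expect_equal(unname(a2["C"] / a2["T"]), 7 / 3, tolerance = 1e-9)
  # window must fit inside the scan
  expect_error(window_areas(tr, 3, half_width = 6), "out of scan range")
})

test_that("normalized intensities are compositions that sum to one", {
  mt <- mixed_trace(0.5)
  m <- normalized_intensities(mt$trace)
  expect_equal(unname(rowSums(m)), rep(1, nrow(m)), tolerance = 1e-9)
  # pure positions are one-hot; the mixed position splits 50:50
  expect_equal(unname(m[1, "C"]), 1, tolerance = 1e-6)
  expect_equal(unname(m[3, "A"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(m[3, "G"]), 0.5, tolerance = 1e-6)
  # a dead (all-zero) trace region has no defined composition
  flat <- trace_data(matrix(0, 50, 4,
                            dimnames = list(NULL, c("A", "C", "G", "T"))),
                     peak_positions = 25, called_bases = "A")
  expect_warning(m2 <- normalized_intensities(flat, positions = 25),
                 "zero total area")
  expect_true(all(is.na(m2)))
})

test_that("mutant ratio recovers noiseless generating fractions exactly", {
  for (f in c(0, 0.25, 0.5, 0.75, 1)) {
    mt <- mixed_trace(f)
    est <- mutant_ratio(mt$trace, mt$position, "A", "G")
    expect_equal(est$mutant_fraction, f, tolerance = 1e-6)
    expect_equal(unname(sum(est$per_base_fraction)), 1, tolerance = 1e-9)
  }
  expect_error(mutant_ratio(mixed_trace(0.5)$trace, 60, "A", "A"), "differ")
  # both interrogated bases absent: undefined
  mt <- mixed_trace(0)
  expect_error(mutant_ratio(mt$trace, mt$position, "G", "T"), "zero area")
})

test_that("estimates are invariant to uniform intensity rescaling", {
  mt <- mixed_trace(0.3)
  scaled <- trace_data(mt$trace$channels * 37.5,
                       peak_positions = mt$trace$peak_positions,
                       called_bases = mt$trace$called_bases)
  e1 <- mutant_ratio(mt$trace, mt$position, "A", "G")
  e2 <- mutant_ratio(scaled, mt$position, "A", "G")
  expect_equal(e1$mutant_fraction, e2$mutant_fraction, tolerance = 1e-12)
  expect_equal(e1$per_base_fraction, e2$per_base_fraction,
               tolerance = 1e-12)
})

test_that("5% additive white noise keeps estimates near the truth", {
  # tolerance study: with additive noise at 5% of the peak amplitude, the
  # per-seed estimate has SD ~0.02 around the truth (area noise of a
  # +/-4-scan window over two channels); a 4-SD envelope bounds the worst
  # of 50 seeds, and the mean is unbiased
  errs <- vapply(1:50, function(seed) {
    mt <- mixed_trace(0.3, noise_sd = 50, seed = seed)
    mutant_ratio(mt$trace, mt$position, "A", "G")$mutant_fraction - 0.3
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.08)
  expect_lt(abs(mean(errs)), 0.01)
})

test_that("estimator error shrinks as the signal-to-noise ratio grows", {
  mean_err <- vapply(c(150, 50, 10), function(sd) {
    mean(vapply(1:30, function(seed) {
      mt <- mixed_trace(0.3, noise_sd = sd, seed = 100 + seed)
      abs(mutant_ratio(mt$trace, mt$position, "A", "G")$mutant_fraction -
            0.3)
    }, numeric(1)))
  }, numeric(1))
  expect_false(is.unsorted(rev(mean_err)))
})

test_that("titration calibration summarizes slope, deviation and bias", {
  truth <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  perfect <- titration_calibration(truth, truth)
  expect_equal(perfect$slope, 1, tolerance = 1e-12)
  expect_equal(perfect$intercept, 0, tolerance = 1e-12)
  expect_true(perfect$monotone)
  expect_false(perfect$underestimation)
  shrunk <- titration_calibration(truth, truth * 0.9)
  expect_equal(shrunk$slope, 0.9, tolerance = 1e-12)
  expect_true(shrunk$underestimation)
  expect_equal(shrunk$max_deviation, 0.09, tolerance = 1e-12)
  expect_error(titration_calibration(c(0.5, 0.5, 0.5), c(0.4, 0.5, 0.6)),
               "span")
  expect_error(titration_calibration(c(0.2, 0.8), c(0.2, 0.8)), "length")
})

test_that("synthetic titration series calibrates close to the identity", {
  truth <- c(0.25, 0.5, 0.75)
  est <- vapply(seq_along(truth), function(i) {
    mt <- mixed_trace(truth[i], noise_sd = 20, seed = 200 + i)
    mutant_ratio(mt$trace, mt$position, "A", "G")$mutant_fraction
  }, numeric(1))
  cal <- titration_calibration(truth, est)
  expect_true(cal$monotone)
  expect_gt(cal$slope_ci[2], 1 - 1e-9)
  expect_lt(cal$slope_ci[1], 1 + 1e-9)
})

test_that("plain-text trace dialect round-trips", {
  mt <- mixed_trace(0.3, noise_sd = 15, seed = 42)
  path <- withr::local_tempfile(fileext = ".txt")
  write_trace_text(mt$trace, path)
  back <- read_trace(path)
  expect_equal(back$channels, mt$trace$channels, tolerance = 1e-10)
  expect_identical(back$peak_positions, mt$trace$peak_positions)
  expect_identical(back$called_bases, mt$trace$called_bases)
  # quantification is unchanged by the round trip
  expect_equal(mutant_ratio(back, mt$position, "A", "G")$mutant_fraction,
               mutant_ratio(mt$trace, mt$position, "A", "G")$mutant_fraction,
               tolerance = 1e-9)
})

test_that("ABIF traces written by the package parse back identically", {
  mt <- mixed_trace(0.3, noise_sd = 15, seed = 43)
  path <- withr::local_tempfile(fileext = ".ab1")
  write_abif(mt$trace, path)
  back <- read_trace(path)
  # intensities are stored as int16: exact after rounding
  expect_equal(back$channels, round(mt$trace$channels))
  expect_identical(back$peak_positions, mt$trace$peak_positions)
  expect_identical(back$called_bases, mt$trace$called_bases)
  expect_equal(mutant_ratio(back, mt$position, "A", "G")$mutant_fraction,
               0.3, tolerance = 0.02)
})

test_that("malformed traces are rejected", {
  # non-monotone peak index violates the container invariant
  ch <- matrix(1, 50, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_error(trace_data(ch, peak_positions = c(10, 5),
                          called_bases = c("A", "C")), "increasing")
  expect_error(trace_data(ch, peak_positions = 60, called_bases = "A"),
               "scan range")
  expect_error(trace_data(ch[, 1:3], peak_positions = 10,
                          called_bases = "A"), "four columns")
  # truncated/garbled text file
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("[channels]", "A\tC\tG\tT", "1\t2\t3\t4"), path)
  expect_error(read_trace(path), "malformed")
  # not an ABIF file
  path2 <- withr::local_tempfile(fileext = ".ab1")
  writeBin(charToRaw("NOPE"), path2)
  expect_error(read_abif(path2), "not an ABIF")
})
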