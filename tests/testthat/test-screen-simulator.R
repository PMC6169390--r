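test_that("sampled count tables have the model's expectations", {
  d <- paper_design()
  out <- edit_outcome(0.2, 0.05)
  m <- sample_counts(d, out, n = 1e5, seed = 11)
  expect_equal(mean(m$target_start), 100, tolerance = 0.01)
  expect_equal(mean(m$control_start), 80000, tolerance = 0.001)
  expect_equal(mean(m$control_end), 80000, tolerance = 0.001)
  # E[target_end] = depth / barcode_ratio = 100 / 1.1727 ~ 85.27
  expect_equal(mean(m$target_end), 100 / barcode_ratio(out, 26),
               tolerance = 0.01)
  # a single draw is a count_table, reproducible under a seed
  t1 <- sample_counts(d, out, seed = 3)
  t2 <- sample_counts(d, out, seed = 3)
  expect_s3_class(t1, "count_table")
  expect_identical(unclass(t1), unclass(t2))
})

test_that("chi-square test matches the reference implementation", {
  tabs <- random_tables(200, seed = 5)
  for (i in seq_len(nrow(tabs))) {
    tb <- count_table(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    for (corr in c(FALSE, TRUE)) {
      got <- chi_square_proportions(tb, correct = corr)
      ref <- reference_chisq(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i],
                             correct = corr)
      expect_equal(got$statistic, ref$statistic, tolerance = 1e-8)
      expect_equal(got$p_value, ref$p_value, tolerance = 1e-8)
    }
  }
})

test_that("chi-square test is symmetric and handles degenerate tables", {
  expect_equal(chi_square_proportions(
    count_table(100, 100, 80000, 80000))$statistic, 0)
  expect_equal(chi_square_proportions(
    count_table(100, 100, 80000, 80000))$p_value, 1)
  # swapping rows or columns leaves the statistic unchanged
  s1 <- chi_square_proportions(count_table(120, 80, 70000, 81000))$statistic
  s2 <- chi_square_proportions(count_table(70000, 81000, 120, 80))$statistic
  s3 <- chi_square_proportions(count_table(80, 120, 81000, 70000))$statistic
  expect_equal(s1, s2)
  expect_equal(s1, s3)
  # zero margin: untestable signal, not a crash
  res <- chi_square_proportions(count_table(0, 0, 80000, 80000))
  expect_false(res$testable)
  expect_true(is.na(res$statistic))
  expect_error(count_table(-1, 0, 10, 10), "non-negative")
})

test_that("type-I error is calibrated at the nominal alpha", {
  d <- paper_design()
  rate <- estimate_power(d, edit_outcome(0.5, 0), iterations = 10000,
                         alpha = 0.05, seed = 21)
  expect_lt(abs(rate - 0.05), binom_ci99(0.05, 10000))
})

test_that("power estimates are seeded-reproducible and seed-consistent", {
  d <- paper_design()
  out <- edit_outcome(0.4, 0.05)
  p1 <- estimate_power(d, out, iterations = 2000, seed = 9)
  p2 <- estimate_power(d, out, iterations = 2000, seed = 9)
  p3 <- estimate_power(d, out, iterations = 2000, seed = 10)
  expect_identical(p1, p2)
  # different seeds agree within binomial sampling error
  expect_lt(abs(p1 - p3), 2 * binom_ci99(p1, 2000))
})

test_that("untestable tables count as non-detections", {
  # lethal, fully edited: target_end is always 0 but tables stay testable
  # through the start counts; the extreme case of an all-zero margin is
  # exercised directly through the kernel with a tiny pool
  d <- screen_design(n_targets = 1, n_controls = 1, guides_per_target = 1,
                     depth = 1, generations = 26)
  rate <- estimate_power(d, edit_outcome(1, 1), iterations = 500, seed = 2)
  expect_gte(rate, 0)
  expect_lte(rate, 1)
})

test_that("power grid is deterministic and matches pointwise estimates", {
  d <- paper_design()
  g1 <- power_grid(d, mu_values = c(0.2, 0.6), s_values = c(0, 0.05),
                   iterations = 300, seed = 4)
  g2 <- power_grid(d, mu_values = c(0.2, 0.6), s_values = c(0, 0.05),
                   iterations = 300, seed = 4)
  expect_identical(g1$power, g2$power)
  expect_true(all(g1$power >= 0 & g1$power <= 1))
  expect_equal(dim(g1$power), c(2L, 2L))
  # the s = 0 row estimates the nominal alpha
  expect_lt(max(abs(g1$power[1, ] - 0.05)), binom_ci99(0.05, 300))
  df <- as.data.frame(g1)
  expect_equal(nrow(df), 4L)
  expect_equal(df$power[df$mu == 0.6 & df$s == 0.05],
               g1$power["0.05", "0.6"])
})

test_that("power increases with mu, s and depth (CI-overlap criterion)", {
  it <- 2000
  no_sig_decrease <- function(p) {
    all(diff(p) > -(binom_ci99(pmax(p[-length(p)], 0.01), it) +
                      binom_ci99(pmax(p[-1], 0.01), it)))
  }
  d <- paper_design()
  p_mu <- vapply(c(0.1, 0.3, 0.6, 0.9), function(mu) {
    estimate_power(d, edit_outcome(mu, 0.05), iterations = it,
                   seed = 31 + round(100 * mu))
  }, numeric(1))
  expect_true(no_sig_decrease(p_mu))
  expect_gt(p_mu[4], p_mu[1])  # strict gain over the whole range
  p_s <- vapply(c(0.02, 0.05, 0.1, 0.3), function(s) {
    estimate_power(d, edit_outcome(0.3, s), iterations = it,
                   seed = 57 + round(100 * s))
  }, numeric(1))
  expect_true(no_sig_decrease(p_s))
  expect_gt(p_s[4], p_s[1])
  p_d <- vapply(c(50, 100, 200), function(dep) {
    estimate_power(paper_design(depth = dep), edit_outcome(0.3, 0.05),
                   iterations = it, seed = 71 + dep)
  }, numeric(1))
  expect_true(no_sig_decrease(p_d))
  expect_gt(p_d[3], p_d[1])
})

test_that("diploid power at mu equals haploid power at mu squared", {
  d1 <- paper_design(ploidy = 1)
  d2 <- paper_design(ploidy = 2)
  p_dip <- estimate_power(d2, edit_outcome(0.6, 0.1), iterations = 3000,
                          seed = 13)
  p_hap <- estimate_power(d1, edit_outcome(0.36, 0.1), iterations = 3000,
                          seed = 13)
  expect_identical(p_dip, p_hap)
})

test_that("gene-recovery curves behave at the limits and across thresholds", {
  d <- paper_design()
  # neutral genes: essentially never recovered above chance-level thresholds
  rc0 <- gene_recovery_curve(d, effects = rep(0, 5),
                             mu_values = c(0.3, 0.9), thresholds = c(0.5),
                             iterations = 200, seed = 6)
  expect_true(all(rc0$detected_fraction == 0))
  # lethal genes at full editing are always recovered
  rc1 <- gene_recovery_curve(d, effects = rep(1, 4), mu_values = c(1),
                             thresholds = c(0.95), iterations = 200,
                             seed = 7)
  expect_equal(unname(rc1$detected_fraction[1, 1]), 1)
  # detected fraction is non-increasing in the threshold at fixed mu
  rc <- gene_recovery_curve(d, effects = c(0, 0.03, 0.05, 0.1, 0.3, 1),
                            mu_values = c(0.2, 0.6),
                            thresholds = c(0.25, 0.5, 0.8, 0.95),
                            iterations = 300, seed = 8)
  for (j in seq_along(rc$mu_values)) {
    expect_false(is.unsorted(rev(rc$detected_fraction[, j])))
  }
  expect_true(all(rc$success_rate >= 0 & rc$success_rate <= 1))
})

test_that("guide-level aggregation recovers more genes than a single guide", {
  d <- paper_design()
  rc_one <- gene_recovery_curve(d, effects = 0.05, mu_values = 0.3,
                                thresholds = 0.5, iterations = 400,
                                seed = 15)
  rc_any <- gene_recovery_curve(d, effects = 0.05, mu_values = 0.3,
                                thresholds = 0.5, iterations = 400,
                                seed = 15, guide_aggregation = TRUE,
                                guides_required = 1)
  expect_gte(rc_any$success_rate[1, 1], rc_one$success_rate[1, 1])
})
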