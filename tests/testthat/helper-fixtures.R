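# Shared fixtures and independent oracles.

paper_design <- function(...) {
  args <- list(n_targets = 4800, n_controls = 800, guides_per_target = 8,
               depth = 100, generations = 26)
  args[names(list(...))] <- list(...)
  do.call(screen_design, args)
}

# Small pool used where the full genome-scale design would be wasteful.
small_design <- function(...) {
  args <- list(n_targets = 50, n_controls = 20, guides_per_target = 2,
               depth = 100, generations = 26)
  args[names(list(...))] <- list(...)
  do.call(screen_design, args)
}

# Independent oracle for the barcode abundance ratio: explicit discrete
# two-subpopulation growth. The barcode population starts as a fraction `mu`
# of mutants and `1 - mu` wild-type-fitness cells; each generation the mutant
# subpopulation is scaled by (1 - s) relative to wild type. Returns the final
# control-to-barcode count ratio.
oracle_barcode_ratio <- function(mu, s, generations) {
  n_mut <- mu
  n_wt_like <- 1 - mu
  n_ctrl <- 1
  for (g in seq_len(generations)) {
    n_mut <- n_mut * (1 - s)  # relative to the neutral growth of the others
  }
  bc <- n_mut + n_wt_like
  if (bc <= 0) Inf else n_ctrl / bc
}

# A synthetic trace with well-separated peaks (spacing 10 sigma) so that
# neighbouring peaks contribute negligibly to each other's windows, plus one
# mixed position. Returns list(trace, mixed_position).
mixed_trace <- function(fraction, noise_sd = 0, seed = NULL,
                        wt_base = "A", mutant_base = "G") {
  sp <- trace_spec(positions = c(20, 40, 60, 80, 100),
                   base_calls = c("C", "T", wt_base, "C", "T"),
                   mutant_fraction = c(0, 0, fraction, 0, 0),
                   mutant_base = c(NA, NA, mutant_base, NA, NA),
                   peak_width = 2, noise_sd = noise_sd)
  list(trace = generate_trace(sp, seed = seed), position = 60)
}

# Random testable 2x2 count tables for chi-square oracle comparisons.
random_tables <- function(n, seed) {
  set.seed(seed)
  data.frame(
    a = sample(1:1000, n, replace = TRUE),
    b = sample(1:1000, n, replace = TRUE),
    c = sample(1:100000, n, replace = TRUE),
    d = sample(1:100000, n, replace = TRUE)
  )
}

# Reference chi-square via stats::chisq.test on one 2x2 table.
reference_chisq <- function(a, b, c, d, correct = FALSE) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

# 99% binomial CI half-width for a detection-rate estimate.
binom_ci99 <- function(p, n) 2.576 * sqrt(p * (1 - p) / n)
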