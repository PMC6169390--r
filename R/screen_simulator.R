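#' Read-count table for one target guide versus the pooled controls
#'
#' The 2x2 table feeding the detection test: reads for the target guide and
#' the pooled control category, at the start and end of the competition.
#'
#' @param target_start,target_end,control_start,control_end Non-negative
#'   integer read counts.
#' @return An object of class `count_table`.
#' @export
count_table <- function(target_start, target_end, control_start, control_end) {
  vals <- c(target_start = target_start, target_end = target_end,
            control_start = control_start, control_end = control_end)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(stats::setNames(as.numeric(vals), names(vals))),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  m <- matrix(c(x$target_start, x$target_end, x$control_start, x$control_end),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("target", "control"), c("start", "end")))
  print(m)
  invisible(x)
}

#' Sample read-count tables from the screen model
#'
#' Draws four independent binomial read counts (target and pooled control, at
#' start and end) with `size = kp * depth` and success probabilities from
#' [read_probability()]. Expectations: `target_start` is about `depth`,
#' both control counts about `n_controls * depth`, and `target_end` about
#' `depth / barcode_ratio`.
#'
#' @param design A [screen_design()].
#' @param outcome An [edit_outcome()].
#' @param n Number of independent tables to draw.
#' @param seed Optional integer seed (the draw otherwise consumes the current
#'   RNG stream).
#' @return For `n = 1`, a [count_table()]; for `n > 1`, a data frame with one
#'   row per table and columns `target_start`, `target_end`, `control_start`,
#'   `control_end`.
#' @examples
#' sample_counts(screen_design(), edit_outcome(0.2, 0.05), seed = 1)
#' @export
sample_counts <- function(design, outcome, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- sample_count_mat(design, outcome, n)
  if (n == 1L) {
    count_table(m[1, "target_start"], m[1, "target_end"],
                m[1, "control_start"], m[1, "control_end"])
  } else {
    as.data.frame(m)
  }
}

# Vectorised sampling kernel shared by sample_counts() and estimate_power().
# Counts are returned as doubles: margins of the 2x2 table overflow 32-bit
# integers at genome-scale designs.
sample_count_mat <- function(design, outcome, n) {
  size <- kp(design) * design$depth
  p_t0 <- read_probability(design, outcome, "start", "target")
  p_t1 <- read_probability(design, outcome, "end", "target")
  p_c <- read_probability(design, outcome, "start", "control")
  cbind(
    target_start = as.numeric(stats::rbinom(n, size, p_t0)),
    target_end = as.numeric(stats::rbinom(n, size, p_t1)),
    control_start = as.numeric(stats::rbinom(n, size, p_c)),
    control_end = as.numeric(stats::rbinom(n, size, p_c))
  )
}

# Pearson chi-square on 2x2 tables, vectorised over tables.
# a,b / c,d are the two rows. With `correct = TRUE` applies the Yates
# continuity correction exactly as stats::chisq.test does (|O-E| reduced by
# min(0.5, |O-E|)). Tables with a zero margin are flagged untestable.
chisq2x2 <- function(a, b, c, d, correct = FALSE) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  c2 <- b + d
  n <- r1 + r2
  testable <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  delta <- abs(a * d - b * c)
  if (correct) delta <- pmax(delta - pmin(n / 2, delta), 0)
  stat <- rep(NA_real_, length(a))
  stat[testable] <- (n * delta^2 / (r1 * r2 * c1 * c2))[testable]
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       testable = testable)
}

#' Chi-square test of equal proportions on a read-count table
#'
#' Pearson chi-square test (1 degree of freedom) that the target guide's share
#' of reads, relative to the pooled controls, is the same at the start and end
#' of the competition. This is the screen's per-guide detection criterion.
#' The statistic is symmetric under swapping rows or columns of the table.
#'
#' Tables with a zero margin (e.g. a guide with no reads at either timepoint)
#' are not testable; they are returned with `testable = FALSE` and an `NA`
#' statistic and p-value, and are treated as non-detections by
#' [estimate_power()].
#'
#' @param table A [count_table()].
#' @param correct Apply the Yates continuity correction (default `FALSE`; the
#'   correction noticeably depresses power at screen-typical counts).
#' @return A list with `statistic`, `p_value`, `df` (always 1) and `testable`.
#' @examples
#' tb <- count_table(100, 85, 80000, 80000)
#' chi_square_proportions(tb)
#' @export
chi_square_proportions <- function(table, correct = FALSE) {
  stopifnot(inherits(table, "count_table"))
  res <- chisq2x2(table$target_start, table$target_end,
                  table$control_start, table$control_end, correct = correct)
  structure(
    list(statistic = res$statistic, p_value = res$p_value, df = 1L,
         testable = res$testable, correct = correct),
    class = "chisq_proportions"
  )
}

#' @export
print.chisq_proportions <- function(x, ...) {
  if (!x$testable) {
    cat("Chi-square test of equal proportions: untestable (zero margin)\n")
  } else {
    cat(sprintf(
      "Chi-square test of equal proportions: X^2 = %.4f, df = 1, p = %.4g%s\n",
      x$statistic, x$p_value,
      if (x$correct) " (Yates-corrected)" else ""))
  }
  invisible(x)
}

# Deterministic per-stream seeds derived from one root seed, so that grid
# cells are order-independent and reproducible. Linear congruential mixing in
# double precision (exact below 2^53), reduced mod 2^31 - 1.
stream_seed <- function(root, index) {
  s <- (as.numeric(root) %% 2147483647) * 48271 + as.numeric(index) * 16807 + 1
  as.integer(s %% 2147483647)
}

#' Monte-Carlo detection power at one (mu, s) point
#'
#' Repeatedly samples read-count tables from the screen model and applies the
#' chi-square detection test; the detection rate is the fraction of iterations
#' with `p < alpha`. Untestable tables (zero margins) count as non-detections:
#' a screen cannot call a gene from zero reads.
#'
#' At `s_mut = 0` the rate estimates the type-I error and is calibrated at the
#' nominal `alpha`.
#'
#' @param design A [screen_design()].
#' @param outcome An [edit_outcome()].
#' @param iterations Number of Monte-Carlo iterations (>= 1).
#' @param alpha Significance level in (0, 1).
#' @param seed Optional integer seed for reproducibility.
#' @param correct Yates continuity correction (see
#'   [chi_square_proportions()]).
#' @return The detection rate in \[0, 1\].
#' @examples
#' estimate_power(screen_design(), edit_outcome(0.6, 0.05),
#'                iterations = 1000, seed = 1)
#' @export
estimate_power <- function(design, outcome, iterations = 10000, alpha = 0.05,
                           seed = NULL, correct = FALSE) {
  stopifnot(iterations >= 1)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  m <- sample_count_mat(design, outcome, iterations)
  res <- chisq2x2(m[, "target_start"], m[, "target_end"],
                  m[, "control_start"], m[, "control_end"], correct = correct)
  detected <- res$testable & !is.na(res$p_value) & res$p_value < alpha
  mean(detected)
}

#' Detection-power grid over mutagenesis rate and selection coefficient
#'
#' Evaluates [estimate_power()] on the Cartesian grid `mu_values` x
#' `s_values`. Each cell uses its own RNG stream derived deterministically
#' from the root `seed`, so results do not depend on evaluation order.
#'
#' @param design A [screen_design()].
#' @param mu_values,s_values Ascending grids in \[0, 1\].
#' @param iterations Monte-Carlo iterations per cell.
#' @param alpha Significance level.
#' @param seed Root integer seed.
#' @param correct Yates continuity correction.
#' @return An object of class `power_grid`: a list with `mu_values`,
#'   `s_values`, a `power` matrix (rows = `s_values`, columns = `mu_values`),
#'   `iterations` and `alpha`. Coerce with `as.data.frame()` for a tidy
#'   (mu, s, power) layout.
#' @examples
#' g <- power_grid(screen_design(), mu_values = c(0.2, 0.6),
#'                 s_values = c(0, 0.05), iterations = 200, seed = 1)
#' as.data.frame(g)
#' @export
power_grid <- function(design, mu_values, s_values, iterations = 1000,
                       alpha = 0.05, seed = 1, correct = FALSE) {
  stopifnot(all(mu_values >= 0 & mu_values <= 1),
            all(s_values >= 0 & s_values <= 1),
            !is.unsorted(mu_values), !is.unsorted(s_values))
  pw <- matrix(NA_real_, nrow = length(s_values), ncol = length(mu_values),
               dimnames = list(s = format(s_values), mu = format(mu_values)))
  idx <- 0L
  for (i in seq_along(s_values)) {
    for (j in seq_along(mu_values)) {
      idx <- idx + 1L
      pw[i, j] <- estimate_power(
        design, edit_outcome(mu_values[j], s_values[i]),
        iterations = iterations, alpha = alpha,
        seed = stream_seed(seed, idx), correct = correct)
    }
  }
  structure(
    list(mu_values = mu_values, s_values = s_values, power = pw,
         iterations = iterations, alpha = alpha, design = design),
    class = "power_grid"
  )
}

#' @export
as.data.frame.power_grid <- function(x, ...) {
  data.frame(
    mu = rep(x$mu_values, each = length(x$s_values)),
    s = rep(x$s_values, times = length(x$mu_values)),
    power = as.vector(x$power)
  )
}

#' @export
print.power_grid <- function(x, ...) {
  cat(sprintf(
    "Detection-power grid: %d mu x %d s values, %d iterations, alpha = %g\n",
    length(x$mu_values), length(x$s_values), x$iterations, x$alpha))
  print(round(x$power, 3))
  invisible(x)
}

#' Gene-recovery curves over mutagenesis rate
#'
#' For a set of genes with known fitness effects (selection coefficients of
#' their LOF), computes for each mutagenesis rate the fraction of genes whose
#' per-gene detection success rate meets or exceeds each threshold. The
#' success rate of a gene is [estimate_power()] at the gene's selection
#' coefficient, with the mutagenesis rate adjusted for the design's ploidy
#' (see [effective_edit_fraction()]).
#'
#' By default each gene is evaluated once at the (mu, s) point (one
#' representative guide). With `guide_aggregation = TRUE`, each iteration
#' instead simulates all `guides_per_target` guides of the gene and calls the
#' gene detected when at least `guides_required` of them are individually
#' significant.
#'
#' @param design A [screen_design()].
#' @param effects Numeric vector of selection coefficients in \[0, 1\], one
#'   per gene.
#' @param mu_values Ascending grid of mutagenesis rates in \[0, 1\].
#' @param thresholds Minimal per-gene success rates in (0, 1\] used to call a
#'   gene detected.
#' @param iterations Monte-Carlo iterations per gene and mutagenesis rate.
#' @param alpha Significance level of the per-guide test.
#' @param seed Root integer seed.
#' @param correct Yates continuity correction.
#' @param guide_aggregation Aggregate over the gene's guides (default
#'   `FALSE`).
#' @param guides_required Minimum number of significant guides to call the
#'   gene detected when aggregating.
#' @return An object of class `recovery_curve`: `mu_values`, `thresholds`, a
#'   `detected_fraction` matrix (rows = thresholds, columns = mu values), and
#'   the per-gene `success_rate` matrix (genes x mu).
#' @examples
#' rc <- gene_recovery_curve(screen_design(), effects = c(0, 0.05, 0.2),
#'                           mu_values = c(0.2, 0.8), thresholds = 0.5,
#'                           iterations = 100, seed = 1)
#' rc$detected_fraction
#' @export
gene_recovery_curve <- function(design, effects, mu_values,
                                thresholds = c(0.5, 0.8, 0.95),
                                iterations = 1000, alpha = 0.05, seed = 1,
                                correct = FALSE, guide_aggregation = FALSE,
                                guides_required = 1) {
  stopifnot(length(effects) >= 1, all(effects >= 0 & effects <= 1),
            all(mu_values >= 0 & mu_values <= 1),
            all(thresholds > 0 & thresholds <= 1))
  success <- matrix(NA_real_, nrow = length(effects),
                    ncol = length(mu_values))
  idx <- 0L
  for (gi in seq_along(effects)) {
    for (mi in seq_along(mu_values)) {
      idx <- idx + 1L
      cell_seed <- stream_seed(seed, idx)
      outcome <- edit_outcome(mu_values[mi], effects[gi])
      if (!guide_aggregation) {
        success[gi, mi] <- estimate_power(
          design, outcome, iterations = iterations, alpha = alpha,
          seed = cell_seed, correct = correct)
      } else {
        success[gi, mi] <- gene_success_aggregated(
          design, outcome, iterations, alpha, cell_seed, correct,
          guides_required)
      }
    }
  }
  frac <- matrix(NA_real_, nrow = length(thresholds),
                 ncol = length(mu_values),
                 dimnames = list(threshold = format(thresholds),
                                 mu = format(mu_values)))
  for (ti in seq_along(thresholds)) {
    frac[ti, ] <- colMeans(success >= thresholds[ti])
  }
  structure(
    list(mu_values = mu_values, thresholds = thresholds,
         detected_fraction = frac, success_rate = success,
         effects = effects, iterations = iterations, alpha = alpha,
         design = design),
    class = "recovery_curve"
  )
}

# Per-iteration aggregation across a gene's guides: the gene is detected in an
# iteration when >= guides_required of its guides_per_target guides are
# individually significant.
gene_success_aggregated <- function(design, outcome, iterations, alpha, seed,
                                    correct, guides_required) {
  g <- design$guides_per_target
  set.seed(seed)
  hits <- matrix(FALSE, nrow = iterations, ncol = g)
  for (k in seq_len(g)) {
    m <- sample_count_mat(design, outcome, iterations)
    res <- chisq2x2(m[, "target_start"], m[, "target_end"],
                    m[, "control_start"], m[, "control_end"],
                    correct = correct)
    hits[, k] <- res$testable & !is.na(res$p_value) & res$p_value < alpha
  }
  mean(rowSums(hits) >= guides_required)
}

#' @export
as.data.frame.recovery_curve <- function(x, ...) {
  data.frame(
    threshold = rep(x$thresholds, times = length(x$mu_values)),
    mu = rep(x$mu_values, each = length(x$thresholds)),
    detected_fraction = as.vector(x$detected_fraction)
  )
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf(
    "Gene-recovery curve: %d genes, %d mu values, thresholds %s\n",
    length(x$effects), length(x$mu_values),
    paste(x$thresholds, collapse = ", ")))
  print(round(x$detected_fraction, 3))
  invisible(x)
}
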