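#' Parametric mixture of gene-deletion fitness effects
#'
#' A configurable stand-in for the genome-wide distribution of deletion
#' fitness effects measured in pooled Bar-seq competition assays of the yeast
#' knockout (YKO) collection. Empirically, most non-essential deletions have
#' small fitness costs: a sizeable point mass at (or indistinguishable from)
#' zero, the bulk of non-neutral effects below s = 0.25, a small tail of
#' larger effects, and a few effectively lethal loci.
#'
#' The mixture has four components: a point mass at 0 (`neutral_fraction`), a
#' right-skewed Beta density scaled onto (0, `bulk_max`\] (the remainder of
#' the mass), a uniform tail on (`bulk_max`, 1\] (`tail_fraction`), and a
#' point mass at 1 (`lethal_fraction`).
#'
#' @param neutral_fraction Proportion of genes with s = 0 (default 0.35).
#' @param tail_fraction Proportion with s in (`bulk_max`, 1\] (default 0.08).
#' @param lethal_fraction Proportion with s = 1 (default 0.02).
#' @param bulk_shape Length-2 shape parameters of the Beta density of the
#'   bulk component before scaling (default `c(1.2, 3)`, right-skewed).
#' @param bulk_max Upper edge of the bulk component (default 0.25).
#' @return An object of class `fitness_effect_distribution`.
#' @seealso [sample_effects()]
#' @export
fitness_effect_distribution <- function(neutral_fraction = 0.35,
                                        tail_fraction = 0.08,
                                        lethal_fraction = 0.02,
                                        bulk_shape = c(1.2, 3),
                                        bulk_max = 0.25) {
  fr <- c(neutral_fraction, tail_fraction, lethal_fraction)
  if (any(fr < 0) || sum(fr) > 1) {
    stop("component fractions must be >= 0 and sum to <= 1", call. = FALSE)
  }
  if (length(bulk_shape) != 2L || any(bulk_shape <= 0)) {
    stop("`bulk_shape` must be two positive Beta shape parameters",
         call. = FALSE)
  }
  if (bulk_max <= 0 || bulk_max > 1) {
    stop("`bulk_max` must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(neutral_fraction = neutral_fraction,
         bulk_fraction = 1 - sum(fr),
         tail_fraction = tail_fraction,
         lethal_fraction = lethal_fraction,
         bulk_shape = bulk_shape,
         bulk_max = bulk_max),
    class = "fitness_effect_distribution"
  )
}

#' @export
print.fitness_effect_distribution <- function(x, ...) {
  cat("Fitness-effect mixture:\n")
  cat(sprintf("  neutral (s = 0): %.3f\n", x$neutral_fraction))
  cat(sprintf("  bulk (0, %g], Beta(%g, %g): %.3f\n", x$bulk_max,
              x$bulk_shape[1], x$bulk_shape[2], x$bulk_fraction))
  cat(sprintf("  tail (%g, 1]: %.3f\n", x$bulk_max, x$tail_fraction))
  cat(sprintf("  lethal (s = 1): %.3f\n", x$lethal_fraction))
  invisible(x)
}

#' Sample selection coefficients from a fitness-effect mixture
#'
#' @param dist A [fitness_effect_distribution()].
#' @param n Number of genes to sample (>= 1).
#' @param seed Optional integer seed.
#' @return A numeric vector of `n` selection coefficients in \[0, 1\].
#' @examples
#' s <- sample_effects(fitness_effect_distribution(), 1000, seed = 1)
#' mean(s <= 0.25)  # most effects are small
#' @export
sample_effects <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "fitness_effect_distribution"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(4L, n, replace = TRUE,
                     prob = c(dist$neutral_fraction, dist$bulk_fraction,
                              dist$tail_fraction, dist$lethal_fraction))
  out <- numeric(n)
  nb <- sum(comp == 2L)
  nt <- sum(comp == 3L)
  out[comp == 2L] <- dist$bulk_max *
    stats::rbeta(nb, dist$bulk_shape[1], dist$bulk_shape[2])
  out[comp == 3L] <- stats::runif(nt, dist$bulk_max, 1)
  out[comp == 4L] <- 1
  out
}

#' Simulate a full per-guide screen count table
#'
#' Draws start and end read counts for every guide in the pool (all target
#' guides plus the individual control guides), each as an independent
#' binomial out of `kp * depth` reads. Target guides of gene `i` use the
#' gene's selection coefficient `effects[i]` and the shared mutagenesis rate
#' `mu` (ploidy-adjusted); control guides keep probability `1 / kp` at both
#' timepoints.
#'
#' @param design A [screen_design()].
#' @param effects Selection coefficients, one per target locus
#'   (`design$n_targets` values).
#' @param mu Mutagenesis rate shared by all guides.
#' @param seed Optional integer seed.
#' @return A data frame with one row per guide: `guide`, `category`
#'   (`"target"`/`"control"`), `gene` (locus index, `NA` for controls), `s`
#'   (selection coefficient, `NA` for controls), `start` and `end` counts.
#' @examples
#' d <- screen_design(n_targets = 20, n_controls = 10, guides_per_target = 2)
#' counts <- generate_screen_counts(d, effects = rep(0, 20), mu = 0.5,
#'                                  seed = 1)
#' head(counts)
#' @export
generate_screen_counts <- function(design, effects, mu, seed = NULL) {
  stopifnot(inherits(design, "screen_design"))
  if (length(effects) != design$n_targets) {
    stop("`effects` must supply one selection coefficient per target locus",
         call. = FALSE)
  }
  check_proportion(mu, "mu")
  if (!is.null(seed)) set.seed(seed)
  k <- kp(design)
  size <- k * design$depth
  mu_eff <- effective_edit_fraction(mu, design$ploidy)
  n_target_guides <- design$n_targets * design$guides_per_target
  gene <- rep(seq_len(design$n_targets), each = design$guides_per_target)
  s <- effects[gene]
  # end-time success probability per target guide: (1/kp) * nBC(t)/nWT(t)
  p_end <- (1 / k) *
    (mu_eff * (1 - s)^design$generations + (1 - mu_eff))
  start <- as.numeric(stats::rbinom(n_target_guides + design$n_controls,
                                    size, 1 / k))
  end_t <- as.numeric(stats::rbinom(n_target_guides, size, p_end))
  end_c <- as.numeric(stats::rbinom(design$n_controls, size, 1 / k))
  data.frame(
    guide = seq_len(n_target_guides + design$n_controls),
    category = rep(c("target", "control"),
                   c(n_target_guides, design$n_controls)),
    gene = c(gene, rep(NA_integer_, design$n_controls)),
    s = c(s, rep(NA_real_, design$n_controls)),
    start = start,
    end = c(end_t, end_c)
  )
}

#' Per-guide detection tests on a simulated screen table
#'
#' Pools all control guides into one category and tests each target guide's
#' start/end counts against the pooled controls with
#' [chi_square_proportions()].
#'
#' @param counts Output of [generate_screen_counts()].
#' @param alpha Significance level.
#' @param correct Yates continuity correction.
#' @return The target rows of `counts` with added columns `statistic`,
#'   `p_value` and `significant` (untestable guides are not significant).
#' @export
analyze_screen_counts <- function(counts, alpha = 0.05, correct = FALSE) {
  stopifnot(is.data.frame(counts),
            all(c("category", "start", "end") %in% names(counts)))
  ctrl <- counts[counts$category == "control", , drop = FALSE]
  tgt <- counts[counts$category == "target", , drop = FALSE]
  c0 <- sum(ctrl$start)
  c1 <- sum(ctrl$end)
  res <- chisq2x2(tgt$start, tgt$end, rep(c0, nrow(tgt)), rep(c1, nrow(tgt)),
                  correct = correct)
  tgt$statistic <- res$statistic
  tgt$p_value <- res$p_value
  tgt$significant <- res$testable & !is.na(res$p_value) & res$p_value < alpha
  tgt
}

#' Specification of a synthetic Sanger chromatogram
#'
#' Describes a synthetic four-channel trace: Gaussian peaks of width
#' `peak_width` (sigma, in scan units) centred at `positions`, one called
#' base per position, and optionally a second-allele (mutant) peak mixed in
#' at a given fraction. Adjacent positions closer than `3 * peak_width` are
#' rejected: such peaks overlap too strongly for windowed-area quantification.
#'
#' @param positions Strictly increasing peak centres, in scan units. Each
#'   must be at least `3 * peak_width` from the scan start.
#' @param base_calls Called (wild-type) base per position, from
#'   `c("A","C","G","T")`.
#' @param mutant_fraction Per-position fraction of the mutant allele in
#'   \[0, 1\] (recycled; default 0).
#' @param mutant_base Per-position mutant base (recycled); required wherever
#'   `mutant_fraction > 0`, must differ from the called base there.
#' @param peak_width Gaussian sigma in scan units (default 2).
#' @param noise_sd Additive Gaussian baseline noise, in intensity units
#'   (default 0).
#' @param amplitude Total peak height at an unmixed position (default 1000).
#' @return An object of class `trace_spec`.
#' @seealso [generate_trace()]
#' @export
trace_spec <- function(positions, base_calls, mutant_fraction = 0,
                       mutant_base = NA_character_, peak_width = 2,
                       noise_sd = 0, amplitude = 1000) {
  bases <- c("A", "C", "G", "T")
  n <- length(positions)
  stopifnot(n >= 1, length(base_calls) == n)
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("`positions` must be strictly increasing", call. = FALSE)
  }
  if (!all(base_calls %in% bases)) {
    stop("`base_calls` must be A, C, G or T", call. = FALSE)
  }
  mutant_fraction <- rep_len(mutant_fraction, n)
  mutant_base <- rep_len(mutant_base, n)
  if (any(mutant_fraction < 0 | mutant_fraction > 1)) {
    stop("`mutant_fraction` must be in [0, 1]", call. = FALSE)
  }
  mixed <- mutant_fraction > 0
  if (any(mixed & (is.na(mutant_base) | !(mutant_base %in% bases)))) {
    stop("`mutant_base` must be given (A/C/G/T) wherever mutant_fraction > 0",
         call. = FALSE)
  }
  if (any(mixed & mutant_base == base_calls)) {
    stop("`mutant_base` must differ from the called base", call. = FALSE)
  }
  if (n > 1 && any(diff(positions) < 3 * peak_width)) {
    stop("overlapping peaks: adjacent positions must be >= 3 * peak_width apart",
         call. = FALSE)
  }
  if (positions[1] < 3 * peak_width) {
    stop("first position too close to the scan start", call. = FALSE)
  }
  stopifnot(peak_width > 0, noise_sd >= 0, amplitude > 0)
  structure(
    list(positions = as.numeric(positions), base_calls = base_calls,
         mutant_fraction = mutant_fraction, mutant_base = mutant_base,
         peak_width = peak_width, noise_sd = noise_sd,
         amplitude = amplitude),
    class = "trace_spec"
  )
}

#' Generate a synthetic four-channel chromatogram
#'
#' Renders the peaks described by a [trace_spec()] into four intensity
#' channels (A, C, G, T) over an integer scan axis. At a mixed position the
#' called-base and mutant-base peaks share the same centre and width, with
#' heights `amplitude * (1 - f)` and `amplitude * f`, so channel areas are
#' proportional to allele fractions by construction. Additive Gaussian noise
#' (`noise_sd`) is applied afterwards and intensities floored at zero.
#'
#' @param spec A [trace_spec()].
#' @param seed Optional integer seed (only noise is stochastic).
#' @return A [trace_data()] object.
#' @examples
#' sp <- trace_spec(positions = c(20, 40), base_calls = c("A", "C"),
#'                  mutant_fraction = c(0, 0.3), mutant_base = c(NA, "G"))
#' tr <- generate_trace(sp)
#' @export
generate_trace <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "trace_spec"))
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  len <- ceiling(max(spec$positions) + 5 * spec$peak_width)
  x <- seq_len(len)
  ch <- matrix(0, nrow = len, ncol = 4, dimnames = list(NULL, bases))
  for (i in seq_along(spec$positions)) {
    g <- exp(-(x - spec$positions[i])^2 / (2 * spec$peak_width^2))
    f <- spec$mutant_fraction[i]
    wt <- spec$base_calls[i]
    ch[, wt] <- ch[, wt] + spec$amplitude * (1 - f) * g
    if (f > 0) {
      mb <- spec$mutant_base[i]
      ch[, mb] <- ch[, mb] + spec$amplitude * f * g
    }
  }
  if (spec$noise_sd > 0) {
    ch <- ch + matrix(stats::rnorm(length(ch), sd = spec$noise_sd),
                      nrow = len)
    ch[ch < 0] <- 0
  }
  trace_data(ch, peak_positions = round(spec$positions),
             called_bases = spec$base_calls)
}
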