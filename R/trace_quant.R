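#' Chromatogram trace container
#'
#' Four-channel Sanger trace intensities over the scan index, together with
#' the called-peak positions and base calls taken from the base caller. Peak
#' positions are 1-based scan indices into the channel matrix.
#'
#' @param channels Numeric matrix with one row per scan point and four
#'   columns named `A`, `C`, `G`, `T`; intensities must be non-negative.
#' @param peak_positions Strictly increasing integer scan indices of the
#'   called bases, all within the scan range.
#' @param called_bases Character vector of base calls (one per position).
#' @return An object of class `trace_data`.
#' @export
trace_data <- function(channels, peak_positions, called_bases) {
  bases <- c("A", "C", "G", "T")
  channels <- as.matrix(channels)
  if (ncol(channels) != 4L || !all(bases %in% colnames(channels))) {
    stop("`channels` must have four columns named A, C, G, T", call. = FALSE)
  }
  channels <- channels[, bases, drop = FALSE]
  if (any(!is.finite(channels)) || any(channels < 0)) {
    stop("channel intensities must be finite and non-negative",
         call. = FALSE)
  }
  peak_positions <- as.integer(peak_positions)
  if (length(peak_positions) >= 2 &&
      is.unsorted(peak_positions, strictly = TRUE)) {
    stop("`peak_positions` must be strictly increasing", call. = FALSE)
  }
  if (any(peak_positions < 1L) || any(peak_positions > nrow(channels))) {
    stop("`peak_positions` must lie within the scan range", call. = FALSE)
  }
  if (length(called_bases) != length(peak_positions)) {
    stop("`called_bases` must match `peak_positions` in length",
         call. = FALSE)
  }
  structure(
    list(channels = channels, peak_positions = peak_positions,
         called_bases = as.character(called_bases)),
    class = "trace_data"
  )
}

#' @export
print.trace_data <- function(x, ...) {
  cat(sprintf("Chromatogram trace: %d scan points, %d called peaks\n",
              nrow(x$channels), length(x$peak_positions)))
  if (length(x$called_bases)) {
    cat("  calls: ", paste(x$called_bases, collapse = ""), "\n", sep = "")
  }
  invisible(x)
}

#' Per-channel area under the curve in a window around a peak
#'
#' Integrates each of the four channels over
#' `[position - half_width, position + half_width]` by the trapezoidal rule,
#' after an optional baseline correction (subtracted per channel, floored at
#' zero):
#'
#' * `"median"` (default): the channel's median over the whole trace. In a
#'   trace where called peaks are sparse relative to the scan this is a
#'   robust estimate of the channel's baseline level; it removes a constant
#'   offset exactly, leaves ratios of same-shaped peaks unchanged, and —
#'   being estimated from many scan points — adds essentially no noise of
#'   its own.
#' * `"window_min"`: the channel's minimum within the window. Also removes a
#'   constant offset and preserves same-shape peak ratios, but on noisy
#'   traces the minimum is an extreme order statistic: it sits about 1.5
#'   noise SDs below the true baseline, which biases both channel areas
#'   upward (pushing two-base ratios toward 0.5) and inflates their
#'   variance.
#' * `"none"`: no correction.
#'
#' @param trace A [trace_data()].
#' @param position Scan index at the window centre (need not be a called
#'   peak).
#' @param half_width Window half-width in scan units (default 4).
#' @param baseline `"median"`, `"window_min"` or `"none"`; `TRUE`/`FALSE`
#'   are accepted as aliases for `"window_min"`/`"none"`.
#' @return Named numeric vector of four areas (`A`, `C`, `G`, `T`).
#' @export
window_areas <- function(trace, position, half_width = 4,
                         baseline = c("median", "window_min", "none")) {
  stopifnot(inherits(trace, "trace_data"), half_width > 0)
  if (is.logical(baseline)) baseline <- if (baseline) "window_min" else "none"
  baseline <- match.arg(baseline)
  lo <- position - half_width
  hi <- position + half_width
  if (lo < 1 || hi > nrow(trace$channels)) {
    stop("window out of scan range", call. = FALSE)
  }
  idx <- seq(ceiling(lo), floor(hi))
  x <- as.numeric(idx)
  vapply(c("A", "C", "G", "T"), function(b) {
    y <- trace$channels[idx, b]
    y <- switch(baseline,
                median = pmax(y - stats::median(trace$channels[, b]), 0),
                window_min = y - min(y),
                none = y)
    pracma::trapz(x, y)
  }, numeric(1))
}

#' Normalized per-base intensity fractions at a set of positions
#'
#' For each position, computes the four windowed channel areas
#' ([window_areas()]) and normalizes them by their total, giving the fraction
#' of signal attributable to each base. This per-position composition is the
#' quantity displayed as a mutation heat map across a sequenced region.
#'
#' Positions where all four areas are zero have no defined composition; their
#' row is returned as `NA` with a warning.
#'
#' @param trace A [trace_data()].
#' @param positions Scan indices to quantify (defaults to the trace's called
#'   peak positions).
#' @param half_width Window half-width in scan units.
#' @param baseline Baseline rule, see [window_areas()].
#' @return Numeric matrix (positions x 4 bases); each defined row sums to 1.
#' @export
normalized_intensities <- function(trace, positions = trace$peak_positions,
                                   half_width = 4, baseline = "median") {
  stopifnot(length(positions) >= 1)
  out <- t(vapply(positions, function(p) {
    a <- window_areas(trace, p, half_width = half_width, baseline = baseline)
    tot <- sum(a)
    if (tot <= 0) rep(NA_real_, 4) else a / tot
  }, numeric(4)))
  dimnames(out) <- list(format(positions), c("A", "C", "G", "T"))
  if (anyNA(out)) {
    warning("zero total area at some positions; rows set to NA",
            call. = FALSE)
  }
  out
}

#' Mutant allele fraction from peak areas at one position
#'
#' Restricts the normalized window composition at `position` to the wild-type
#' and mutant bases and reports the fraction of their combined signal carried
#' by the mutant base — the chromatogram's semi-quantitative estimate of the
#' mutant allele frequency in the sequenced pool.
#'
#' @param trace A [trace_data()].
#' @param position Scan index of the interrogated base.
#' @param wt_base,mutant_base The two bases to compare (must differ).
#' @param half_width Window half-width in scan units.
#' @param baseline Baseline rule, see [window_areas()].
#' @return An object of class `allele_ratio_estimate`: `position`,
#'   `per_base_fraction` (all four bases, summing to 1) and
#'   `mutant_fraction` (two-base restricted).
#' @examples
#' sp <- trace_spec(20, "A", mutant_fraction = 0.3, mutant_base = "G")
#' est <- mutant_ratio(generate_trace(sp), 20, "A", "G")
#' est$mutant_fraction  # 0.3
#' @export
mutant_ratio <- function(trace, position, wt_base, mutant_base,
                         half_width = 4, baseline = "median") {
  bases <- c("A", "C", "G", "T")
  stopifnot(wt_base %in% bases, mutant_base %in% bases)
  if (wt_base == mutant_base) {
    stop("`wt_base` and `mutant_base` must differ", call. = FALSE)
  }
  a <- window_areas(trace, position, half_width = half_width,
                    baseline = baseline)
  tot <- sum(a)
  if (tot <= 0) {
    stop("zero total area at this position; allele ratio undefined",
         call. = FALSE)
  }
  pair <- a[wt_base] + a[mutant_base]
  if (pair <= 0) {
    stop("both interrogated bases have zero area; allele ratio undefined",
         call. = FALSE)
  }
  structure(
    list(position = position,
         per_base_fraction = a / tot,
         mutant_fraction = unname(a[mutant_base] / pair)),
    class = "allele_ratio_estimate"
  )
}

#' @export
print.allele_ratio_estimate <- function(x, ...) {
  cat(sprintf("Allele-ratio estimate at scan %s: mutant fraction %.4f\n",
              format(x$position), x$mutant_fraction))
  print(round(x$per_base_fraction, 4))
  invisible(x)
}

#' Titration calibration of trace-based allele-fraction estimates
#'
#' Regresses estimated mutant fractions on the known mixing fractions of a
#' titration series (e.g. defined mixtures of mutant and wild-type cells) and
#' summarizes the calibration: least-squares slope and intercept, the largest
#' absolute deviation from the known values, whether the estimates are
#' monotone in the truth, and an underestimation flag raised when the fitted
#' line lies below the identity (slope < 1 or intercept < 0) — the typical
#' behaviour of peak-area quantification.
#'
#' @param true_fraction Known mixture fractions (at least 3 points, not all
#'   identical).
#' @param estimated_fraction Matching estimates from [mutant_ratio()].
#' @return An object of class `titration_calibration`: `slope`, `intercept`,
#'   `slope_ci` (95% confidence interval), `max_deviation`, `monotone`,
#'   `underestimation`, and the fitted `lm` object as `fit`.
#' @export
titration_calibration <- function(true_fraction, estimated_fraction) {
  stopifnot(length(true_fraction) == length(estimated_fraction),
            length(true_fraction) >= 3)
  if (length(unique(true_fraction)) < 2) {
    stop("titration points must span more than one true fraction",
         call. = FALSE)
  }
  fit <- stats::lm(estimated_fraction ~ true_fraction)
  co <- stats::coef(fit)
  # confint warns on numerically perfect fits; the CI itself is still valid
  ci <- tryCatch(suppressWarnings(stats::confint(fit)["true_fraction", ]),
                 error = function(e) c(NA_real_, NA_real_))
  ord <- order(true_fraction)
  structure(
    list(slope = unname(co["true_fraction"]),
         intercept = unname(co["(Intercept)"]),
         slope_ci = unname(ci),
         max_deviation = max(abs(estimated_fraction - true_fraction)),
         monotone = !is.unsorted(estimated_fraction[ord]),
         underestimation = unname(co["true_fraction"] < 1 - 1e-9 ||
                                    co["(Intercept)"] < -1e-9),
         fit = fit),
    class = "titration_calibration"
  )
}

#' @export
print.titration_calibration <- function(x, ...) {
  cat(sprintf(
    "Titration calibration: slope %.4f (95%% CI %.4f-%.4f), intercept %.4f\n",
    x$slope, x$slope_ci[1], x$slope_ci[2], x$intercept))
  cat(sprintf("  max deviation %.4f; monotone: %s; underestimation flag: %s\n",
              x$max_deviation, x$monotone, x$underestimation))
  invisible(x)
}
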