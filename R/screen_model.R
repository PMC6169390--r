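#' Relative fitness of the mutant after a number of generations
#'
#' Under constant per-generation growth rates, the mutant-to-wild-type fitness
#' ratio after `generations` generations is `(1 - s_mut)^generations`.
#'
#' @param s_mut Selection coefficient in \[0, 1\].
#' @param generations Non-negative integer number of generations.
#' @return `(1 - s_mut)^generations`; 1 when `generations == 0`, 0 when
#'   `s_mut == 1` and `generations > 0`.
#' @examples
#' relative_fitness(0.05, 26)  # ~0.2636
#' @export
relative_fitness <- function(s_mut, generations) {
  check_proportion(s_mut, "s_mut")
  if (!is.numeric(generations) || length(generations) != 1L ||
      is.na(generations) || generations < 0) {
    stop("`generations` must be a single non-negative number", call. = FALSE)
  }
  (1 - s_mut)^generations
}

#' Expected control-to-mutant barcode abundance ratio
#'
#' The model's central closed form. A guide's barcode marks a mixed
#' sub-population: a fraction `mu` of its cells carry the LOF (fitness
#' `1 - s_mut` per generation) and `1 - mu` remain effectively wild type.
#' Starting from equal abundance of the control and target barcodes, after
#' `t` generations the control-to-target abundance ratio is
#' \deqn{\frac{n_{WT}(t)}{n_{BC}(t)} =
#'   \frac{1}{\mu\,((1 - S_{mut})^t - 1) + 1}.}
#'
#' The ratio is 1 when `mu = 0`, `s_mut = 0`, or `generations = 0`, and grows
#' as any of the three increases. In the fully edited, lethal limit
#' (`mu = 1`, `s_mut = 1`) the mutant barcode disappears entirely and the
#' ratio is infinite; this is returned as `Inf` rather than an error, and
#' maps to a zero read-sampling probability downstream.
#'
#' @param outcome An [edit_outcome()].
#' @param generations Non-negative integer number of generations.
#' @param initial_ratio Control-to-target abundance ratio at the start of the
#'   competition (default 1: all barcodes present in equal proportion).
#' @return The expected abundance ratio, `>= initial_ratio`; `Inf` in the
#'   degenerate lethal fully-edited case.
#' @examples
#' barcode_ratio(edit_outcome(0.2, 0.05), 26)  # ~1.1727
#' @export
barcode_ratio <- function(outcome, generations, initial_ratio = 1) {
  stopifnot(inherits(outcome, "edit_outcome"))
  if (!is.numeric(initial_ratio) || length(initial_ratio) != 1L ||
      is.na(initial_ratio) || initial_ratio <= 0) {
    stop("`initial_ratio` must be a single positive number", call. = FALSE)
  }
  w <- relative_fitness(outcome$s_mut, generations)
  # mu*(w - 1) + 1, written as mu*w + (1 - mu) to avoid cancellation when
  # w underflows toward 0 at mu near 1
  denom <- outcome$mu * w + (1 - outcome$mu)
  if (denom <= 0) {
    return(Inf)
  }
  initial_ratio / denom
}

#' Binomial success probability for a barcode's read count
#'
#' Read counts are modelled as binomial draws out of `kp * depth` total reads.
#' At the start of the competition every guide is equally abundant, so a
#' single target guide has success probability `1 / kp` and the pooled control
#' category `n_controls / kp` (controls are assumed unaffected throughout, so
#' their probability is identical at both timepoints). At the end of the
#' competition a target guide's probability is scaled down by the barcode
#' abundance ratio: `(1 / kp) / barcode_ratio(...)`.
#'
#' In a diploid design the mutagenesis rate is first converted to the
#' effective fraction of cells with both alleles edited
#' (see [effective_edit_fraction()]).
#'
#' @param design A [screen_design()].
#' @param outcome An [edit_outcome()].
#' @param timepoint `"start"` or `"end"` of the competition.
#' @param category `"target"` (a single target guide) or `"control"` (the
#'   pooled control category).
#' @return A probability in \[0, 1\].
#' @examples
#' d <- screen_design()
#' read_probability(d, edit_outcome(0.2, 0.05), "start", "target")  # 1/39200
#' read_probability(d, edit_outcome(0.2, 0.05), "end", "target")
#' @export
read_probability <- function(design, outcome,
                             timepoint = c("start", "end"),
                             category = c("target", "control")) {
  stopifnot(inherits(design, "screen_design"),
            inherits(outcome, "edit_outcome"))
  timepoint <- match.arg(timepoint)
  category <- match.arg(category)
  k <- kp(design)
  if (category == "control") {
    return(design$n_controls / k)
  }
  if (timepoint == "start") {
    return(1 / k)
  }
  mu_eff <- effective_edit_fraction(outcome$mu, design$ploidy)
  ratio <- barcode_ratio(edit_outcome(mu_eff, outcome$s_mut),
                         design$generations)
  (1 / k) / ratio
}

#' Effective fraction of cells with a full LOF, by ploidy
#'
#' In a haploid a single edit suffices, so the effective LOF fraction equals
#' the mutagenesis rate `mu`. In a diploid both alleles must be edited; under
#' independent editing of the two alleles (heterozygotes assumed to have
#' wild-type fitness) the effective fraction is `mu^2`.
#'
#' @param mu Mutagenesis rate in \[0, 1\].
#' @param ploidy 1 or 2.
#' @return The effective edited fraction, fed as `mu` into [barcode_ratio()].
#' @examples
#' effective_edit_fraction(0.6, 2)  # 0.36
#' @export
effective_edit_fraction <- function(mu, ploidy) {
  check_proportion(mu, "mu")
  if (!ploidy %in% c(1, 2)) {
    stop("`ploidy` must be 1 or 2", call. = FALSE)
  }
  if (ploidy == 1) mu else mu^2
}
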