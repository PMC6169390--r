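#' Screen design: pool layout and sequencing parameters
#'
#' Describes the layout of a pooled CRISPR loss-of-function (LOF) Bar-seq
#' screen: how many loci are targeted, how many control guides are carried
#' along, how many guides target each locus, the expected sequencing depth per
#' guide, the length of the growth competition, and the ploidy of the strain
#' background.
#'
#' The total number of guides in the pool is
#' \eqn{k_p = g \cdot t + c}{kp = g * t + c} (guides per target times targets,
#' plus controls); every read count in the model is a binomial draw out of
#' \eqn{k_p \cdot d} total reads.
#'
#' @param n_targets Number of LOF target loci (default 4800, a yeast
#'   genome-scale screen over non-essential ORFs).
#' @param n_controls Number of control guides, pooled into a single control
#'   category for testing (default 800).
#' @param guides_per_target Guides targeting each locus (default 8).
#' @param depth Expected average sequencing reads per guide (default 100).
#' @param generations Length of the growth competition, in generations
#'   (default 26).
#' @param ploidy 1 (haploid) or 2 (diploid). In a diploid, both alleles must
#'   be edited for the LOF phenotype; see [effective_edit_fraction()].
#' @return An object of class `screen_design`.
#' @seealso [kp()], [edit_outcome()], [sample_counts()]
#' @examples
#' d <- screen_design()
#' kp(d)  # 8 * 4800 + 800 = 39200
#' @export
screen_design <- function(n_targets = 4800, n_controls = 800,
                          guides_per_target = 8, depth = 100,
                          generations = 26, ploidy = 1) {
  check_count(n_targets, "n_targets")
  check_count(n_controls, "n_controls")
  check_count(guides_per_target, "guides_per_target")
  check_count(depth, "depth")
  if (!is.numeric(generations) || length(generations) != 1L ||
      is.na(generations) || generations < 0 ||
      generations != round(generations)) {
    stop("`generations` must be a single non-negative integer", call. = FALSE)
  }
  if (!ploidy %in% c(1, 2)) {
    stop("`ploidy` must be 1 or 2", call. = FALSE)
  }
  structure(
    list(
      n_targets = as.integer(n_targets),
      n_controls = as.integer(n_controls),
      guides_per_target = as.integer(guides_per_target),
      depth = as.integer(depth),
      generations = as.integer(generations),
      ploidy = as.integer(ploidy)
    ),
    class = "screen_design"
  )
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single positive integer", name),
         call. = FALSE)
  }
  invisible(x)
}

#' Total number of guides in the pool
#'
#' @param design A [screen_design()].
#' @return `guides_per_target * n_targets + n_controls`, as a double (the
#'   product can exceed the 32-bit integer range for large designs).
#' @export
kp <- function(design) {
  stopifnot(inherits(design, "screen_design"))
  as.numeric(design$guides_per_target) * design$n_targets + design$n_controls
}

#' @export
print.screen_design <- function(x, ...) {
  cat("Pooled LOF screen design\n")
  cat(sprintf("  targets: %d loci x %d guides; controls: %d (pooled)\n",
              x$n_targets, x$guides_per_target, x$n_controls))
  cat(sprintf("  pool size kp = %s guides; depth = %d reads/guide\n",
              format(kp(x), big.mark = ","), x$depth))
  cat(sprintf("  competition: %d generations; ploidy %d\n",
              x$generations, x$ploidy))
  invisible(x)
}

#' Editing outcome at one locus
#'
#' Pairs the per-cell mutagenesis rate `mu` (the fraction of cells carrying
#' the guide that actually acquired the LOF after editing and recovery) with
#' the selection coefficient `s_mut` of the LOF (per-generation relative
#' fitness deficit of the mutant; relative fitness after `t` generations is
#' `(1 - s_mut)^t`).
#'
#' @param mu Mutagenesis rate in \[0, 1\].
#' @param s_mut Selection coefficient in \[0, 1\].
#' @return An object of class `edit_outcome`.
#' @examples
#' edit_outcome(mu = 0.2, s_mut = 0.05)
#' @export
edit_outcome <- function(mu, s_mut) {
  check_proportion(mu, "mu")
  check_proportion(s_mut, "s_mut")
  structure(list(mu = as.numeric(mu), s_mut = as.numeric(s_mut)),
            class = "edit_outcome")
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.edit_outcome <- function(x, ...) {
  cat(sprintf("Edit outcome: mu = %g, s_mut = %g\n", x$mu, x$s_mut))
  invisible(x)
}
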