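---
title: "Modelling detection power in pooled CRISPR loss-of-function Bar-seq screens"
author: "barseqpower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling detection power in pooled CRISPR loss-of-function Bar-seq screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barseqpower)
```

## The experiment being modelled

In a pooled CRISPR loss-of-function (LOF) screen, a population of cells is
transformed with a guide-RNA library and grown in competition; each guide's
sequence doubles as a strain barcode whose abundance is read out by deep
sequencing before and after growth (Bar-seq). A guide targeting a gene whose
loss costs fitness depletes from the pool; depletion relative to control
guides is the detection signal.

The complication this package exists to quantify is *incomplete editing*: a
cell can carry a guide without having acquired the LOF. If only a fraction
$\mu$ of the cells under a barcode are actually mutant, the depletion signal
is diluted by the $1 - \mu$ wild-type-fitness cells sharing the barcode.
Screens performed with low-efficiency editors therefore need either very
deep sequencing or prohibitively large libraries; screens with efficient
editing (e.g. after co-selection for editing at a second locus) recover far
more of the genome. The package provides the forward model, the detection
test, and the Monte-Carlo machinery to make those statements quantitative.

## The competition model

Two sub-populations share a target guide's barcode: mutants, with
per-generation relative fitness $1 - S$ (selection coefficient $S$), and
non-edited cells with wild-type fitness. With constant growth rates, the
mutant-to-wild-type fitness ratio after $t$ generations is $(1-S)^t$
(`relative_fitness()`). Starting from equal barcode abundances, the expected
control-to-target abundance ratio after $t$ generations is

$$\frac{n_{WT}(t)}{n_{BC}(t)} \;=\; \frac{1}{\mu\!\left((1-S)^t - 1\right) + 1},$$

implemented by `barcode_ratio()`. Numerically we evaluate the denominator as
$\mu (1-S)^t + (1-\mu)$: the two forms are algebraically identical, but the
first suffers catastrophic cancellation when $(1-S)^t$ underflows (large $S$,
$\mu \to 1$), while the second matches a generation-by-generation growth
simulation to better than $10^{-10}$ relative error everywhere. At
$\mu = 1, S = 1$ the barcode goes extinct and the ratio is reported as
`Inf`; downstream it simply becomes a zero sampling probability.

```{r}
barcode_ratio(edit_outcome(mu = 0.2, s_mut = 0.05), generations = 26)
```

## Read sampling and the detection test

With $k_p = g\,t_{\text{loci}} + c$ guides sequenced to an average depth $d$,
read counts are modelled as independent binomial draws out of $k_p d$ reads:
probability $1/k_p$ for any single guide at the start, $c/k_p$ for the
pooled control category at both timepoints, and
$(1/k_p)\, n_{BC}(t)/n_{WT}(t)$ for a target guide at the end
(`read_probability()`, `sample_counts()`). Probabilities are deliberately
*not* renormalized across the pool after selection — each barcode's count is
treated as a marginal binomial rather than one coordinate of a multinomial.
For a 2×2 proportion test this is inconsequential (shares renormalize
identically in both categories) and it keeps every (μ, S) cell independent.

Detection uses Pearson's chi-square test of equal proportions (1 df) on the
table (target, pooled control) × (start, end), at $P <$ `alpha` (default
0.05). We use no continuity correction by default: at screen-typical counts
the Yates correction systematically depresses power; it remains available
via `correct = TRUE`. The test kernel is vectorised over Monte-Carlo
iterations for throughput and is verified against `stats::chisq.test()` to
$10^{-8}$ in the test suite. Tables with a zero margin are "untestable" and
counted as non-detections — a screen cannot call a gene from zero reads.

`estimate_power()` repeats draw-and-test over `iterations` iterations;
`power_grid()` maps it over a (μ, S) grid, and `gene_recovery_curve()` turns
a set of per-gene selection coefficients into the fraction of genes whose
per-gene detection success rate clears a threshold, as a function of μ.

### Default design and scale choices

The default `screen_design()` is a genome-scale yeast screen: 4,800 target
loci × 8 guides, 800 pooled control guides ($k_p = 39{,}200$), depth 100
reads/guide, 26 generations of competition, haploid. Reporting helpers
default to a 20×20 grid at 1,000 iterations, which runs in seconds at a
desk; the printed-figure scale (101×101 grid, 10,000 iterations; recovery
curves over 0.01-steps of μ at 1,000 iterations per gene) is available by
passing those grids explicitly. The test suite uses 10,000 iterations for
calibration checks at single points and reduced grids elsewhere; these sizes
were chosen as the smallest that make the Monte-Carlo error negligible
relative to the tolerances being asserted.

A note on reproducing the headline numbers quoted for this class of design:
with this model and any calibrated chi-square variant (with or without
continuity correction), the detection rate at (μ = 0.2, S = 0.05) is ≈19%
and at (μ = 0.6, S = 0.05) ≈94.5% — both confirmed analytically with
`power.prop.test()` on the induced proportions, not just by simulation.
Published figures of ≈25% and >99% for this design correspond, under the
same model, to a per-guide depth of roughly 150 rather than 100; test
variants that do reach those numbers at depth 100 (e.g. goodness-of-fit of
end counts against start counts taken as expected values) have a type-I
error far above the nominal 5% and are not tests of equal proportions. We
report what the model computes.

### Random-number strategy

Every stochastic function takes a `seed`; grids and recovery curves derive
one sub-stream seed per cell from the root seed by fixed integer mixing, so
cell results do not depend on evaluation order and any cell can be
recomputed in isolation.

## Diploid screens

In a diploid, a LOF phenotype requires both alleles edited. The package
models biallelic editing as independent per allele with heterozygotes at
wild-type fitness, so the effective mutant fraction is $\mu^2$
(`effective_edit_fraction()`), fed into the same haploid machinery. This is
the simplest model consistent with "both alleles must be mutated"; if
editing of the two alleles is positively correlated (e.g. shared chromatin
state) it is conservative. `run_recovery_analysis()` therefore also runs
the diploid variant at twice the configured depth by default, reflecting
how such a screen would actually be provisioned.

## Synthetic fitness effects

Genome-wide recovery curves need a distribution of per-gene selection
coefficients. `fitness_effect_distribution()` provides a four-component
stand-in for the deletion-fitness spectrum measured in yeast knockout
Bar-seq assays: a point mass at $s = 0$ (default 0.35), the bulk of
non-neutral effects as $0.25 \times \mathrm{Beta}(1.2, 3)$ on $(0, 0.25]$
(right-skewed, mode near zero; the remainder of the mass, 0.55 by default),
a uniform tail on $(0.25, 1]$ (0.05–0.08), and a point mass of effectively
lethal loci at $s = 1$ (0.02). The defaults put ~90% of genes at
$s \le 0.25$, matching the qualitative shape of the empirical spectrum in
rich medium: mostly small costs, few large ones. The generator makes no
attempt to reproduce any particular published histogram — condition,
replicate and normalization all shift the empirical shape — so conclusions
drawn from it are about the *method's* behaviour across a realistic range
of effect sizes, not about any specific dataset.

## Chromatogram allele quantification

The second, independent tool quantifies mutant allele fractions from Sanger
chromatograms of pooled or mixed templates — the standard quick check of
editing efficiency. For each interrogated base-call position the four
channel intensities are integrated over a window of ±4 scan units
(trapezoidal rule), baseline-corrected, and normalized by the window total
(`window_areas()`, `normalized_intensities()`); the mutant fraction is the
mutant base's share of the wild-type + mutant areas (`mutant_ratio()`).

Numerical choices, and why:

* **Window half-width 4** scan units around the called peak (~2 peak sigmas
  for typical traces): wide enough to capture ~95% of the peak mass, narrow
  enough to keep neighbouring peaks out. Configurable.
* **Baseline**: the default subtracts each channel's *trace-wide median*,
  which removes a constant offset exactly, leaves ratios of same-shaped
  peaks unchanged, and — being estimated from the full scan — adds
  essentially no noise. The per-window minimum is also available
  (`baseline = "window_min"`), but on noisy traces the window minimum is an
  extreme order statistic sitting ~1.5 noise-SDs below the true baseline;
  subtracting it inflates both channel areas equally, biasing two-base
  fractions toward 0.5 and roughly doubling their spread in our tolerance
  study. We measured both and made the median the default.
* **Trapezoidal integration** on the integer scan grid; peak-shape details
  cancel in ratios of same-shaped peaks, which is what makes windowed AUC
  robust for this semi-quantitative purpose.
* **Degenerate inputs**: windows must lie inside the scan; positions whose
  four areas are all zero yield an `NA` row (heat map) or an error (ratio);
  base-call quality is used only through the peak positions, never as a
  weight.

`titration_calibration()` regresses estimates on known mixing fractions and
flags slopes below 1 or negative intercepts — the characteristic
underestimation of peak-area quantification.

### What the synthetic traces do and do not emulate

`generate_trace()` renders Gaussian peaks of equal width at specified
positions, mixes a mutant base at a given fraction by splitting peak height,
adds white noise, and floors at zero. Peaks closer than 3σ are rejected.
This validates the estimator's arithmetic exactly: with no noise the
generating fraction is recovered to $10^{-6}$, and estimates are invariant
to uniform rescaling. What it does *not* emulate: variable peak widths and
shapes along a real trace, dye blobs, mobility shifts between channels,
baseline drift that varies within a window, and miscalled peak positions.
With additive white noise at 5% of the peak amplitude the per-seed error SD
is ≈0.02 (so occasional single-seed errors up to ≈0.07 are expected across
a hundred traces); real traces sit well below that noise level after
standard processing, but the systematic effects above mean trace-based
fractions should be read as semi-quantitative, typically underestimating
strong minorities — which is exactly what the titration summary is for.

## File formats

Traces are read from binary ABIF (`.ab1`) files via a minimal built-in
parser (processed channels `DATA` 9–12 mapped through the `FWO_` channel
order, peak index `PLOC`, base calls `PBAS`; positions are 0-based on disk,
1-based in R), or from a plain-text dialect (`[channels]` /`[peaks]`
sections) that `write_trace_text()` emits; `write_abif()` writes minimal
`.ab1` files, used by the test suite to exercise the binary path without
shipping binary fixtures. Screen configurations are flat YAML; analysis
runners write tidy CSVs with a provenance comment line and a JSON manifest
with MD5 checksums of every output.

## Known limitations

* Forward model only: no estimation of μ or S from observed screen counts.
* Guide-synthesis errors (guides that cannot edit their target) are not
  modelled; they act like a further reduction of μ in practice.
* No multiplicity control across genes — each guide is tested marginally at
  `alpha`, reproducing standard screen-power accounting rather than an FDR
  pipeline.
* Per-gene recovery uses one (μ, S) evaluation per gene by default; the
  optional guide-level aggregation (`guide_aggregation = TRUE`, gene called
  when ≥ m of g guides are significant) is provided because real screens
  aggregate, but no published aggregation rule is assumed.
* The chromatogram estimator handles two-base substitution ratios at given
  positions; indels, multi-allelic mixtures and base-calling itself are out
  of scope.
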