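---
title: "Estimating generational dispersal distance from individual-based isolation by distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating generational dispersal distance from individual-based isolation by distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdsigma)
```

## The estimation problem

Sessile marine invertebrates such as brooding corals disperse through
planktonic propagules that cannot be tracked directly. `ibdsigma` estimates
the generational dispersal distance σ — the root mean squared *axial*
parent–offspring displacement — indirectly, from the spatial decay of
genetic similarity among individually mapped, individually genotyped
colonies.

Under limited dispersal in a two-dimensional habitat, Wright's genetic
neighbourhood size is NS = 4πDσ², where D is the density of individuals per
m². Rousset's pairwise genetic distance *â* increases linearly with
ln(distance) with slope b = 1/NS; Loiselle's kinship F decreases with slope
−(1 − F(1))/NS, where F(1) is the mean kinship among neighbouring pairs.
Fitting either regression and supplying an independent density therefore
yields σ = sqrt(NS/(4πD)). Under a Gaussian dispersal kernel σ equals 1.25
times the mean Euclidean parent–offspring distance; σ summarises the kernel
scale but carries no information about its tail shape.

Two density flavours are supported and deliberately kept distinct:
*census* density (distinct multilocus genotypes counted in mapped plots,
per m²) and *effective* density (a contemporary, externally estimated N_e —
e.g. from a sibship method — divided by the area its sample covers).
Census density generally bounds effective density from above, so the two σ
estimates bracket the plausible range.

## Assumptions

* Migration–drift equilibrium across the analysed distance window. Theory
  and simulation place this window at roughly σ to 10σ–50σ; the package
  therefore re-fits the regression iteratively, resetting the window to
  [σ̂, k·σ̂] (k defaults to 20, settable in 10–50) until σ̂ changes by less
  than 5% or 20 iterations pass. A window that cannot hold three pairs, or
  a slope with the anti-IbD sign, stops the loop and flags the result
  `"scale-unresolved"` instead of producing a number — when the sampled
  distance range does not span the equilibrium window this refusal *is* the
  correct answer.
* Demographic independence of the analysed taxon: the pipeline runs one
  taxon at a time and never pools cryptic taxa, whose mixture would fake
  spatial structure.
* A 2D habitat. Pairwise distances are Euclidean in the plane after each
  plot is projected onto its best-fit plane (total least squares) and the
  normal component is dropped; depth is treated as uninformative for
  within-taxon structure. Cross-location pairs are excluded — locations
  kilometres apart are not within one continuous neighbourhood system.
* For Loiselle's F, inbreeding is permitted (this is the reason to prefer F
  when per-location Weir–Cockerham F_IS is significantly positive, which
  `run_pipeline(metric = "auto")` checks via a delete-one-locus jackknife);
  for Rousset's *â*, inbreeding can produce spurious positive slopes, which
  is why the metric choice matters.

## Statistical design choices

**Ratio of sums everywhere.** Both pairwise metrics are multilocus
ratio-of-sums estimators, consistent with Weir–Cockerham practice: per-pair
and per-locus numerator and denominator contributions are cached, so any
locus resample reconstitutes exact pair values. The biallelic summations
run over both alleles (doubling the single-allele terms), fixing the
denominator scale.

**Q_w is sample-wide by default.** Rousset's *â* needs the probability that
an individual's two alleles are identical in state; the sample-wide
estimate is the lower-variance plug-in and the default, with a `pair_qw`
switch for the pair-restricted reading. Exact numerical parity with other
implementations of *â* is not promised.

**Confidence intervals resample loci, never pairs.** Pairs share
individuals, so pair-level OLS standard errors are invalid and are not
computed. The percentile bootstrap over loci stands in for
accelerated-bootstrap intervals (whose acceleration constants cannot be
reconstructed from published material); a delete-one-locus jackknife
(`b ± 1.96·SE`) is provided as the second route. The two agree closely on
simulated data. Locus resampling captures marker noise conditional on the
realized genealogy — not the between-realization variance of the slope
itself — so interval coverage of the *theoretical* slope across replicate
populations falls below nominal in regimes with very small neighbourhoods.

**The kinship-slope conversion.** The standard Sp-statistic form
NS = (1 − F(1))/(−b) is the default; a literal division variant
NS = 1/(−b(1 − F(1))) appears behind `literal_eq23` because published
typesettings of the conversion are ambiguous. With small F(1) the two are
numerically close; the standard form is the literature-consistent one.
F(1) defaults to the mean kinship within the current σ̂, re-evaluated each
iteration (initialised at 0, i.e. the first pass uses the plain
reciprocal).

**Monte-Carlo σ propagation.** Published parameter summaries come as a
central value with an asymmetric interval. These are represented by a
two-piece lognormal: one log-scale SD below the median, another above,
matched exactly at the median and both 95% endpoints — positive support and
asymmetry at zero extra assumptions. 2000 (NS, D) pairs are drawn
independently (no joint structure is available for them), each mapped
through σ = sqrt(NS/(4πD)), and the median with the 5th–95th percentile
interval is reported. When the slope's bootstrap draws are available they
are transformed draw-by-draw instead, keeping the slope→NS dependence
exact; draws with the anti-IbD sign give an undefined neighbourhood, are
truncated out and counted, and a result with more than half such draws is
flagged `"slope indistinguishable from 0"`. For census density, per-plot
densities are resampled when more than one plot exists; otherwise the
two-piece lognormal applies.

## Clone handling

Genets are detected with a shared-allele (Prevosti-type) distance on
dosages — robust to missing data and standard in clone calling. The calling
threshold is calibrated on technical replicates: their pairwise distances
estimate the combined sequencing-error and somatic-mutation scale. When
every non-replicate distance exceeds the largest replicate distance, the
threshold is the midpoint of that gap; when the distributions overlap, the
95th percentile of replicate distances is used with a warning. Pairs
co-typed at fewer than 20% of loci are excluded from calibration as
unstable. Genets are single-linkage components (somatic mutations
accumulate along clonal chains), and all downstream analyses keep one
representative per genet — the colony with the least missing data, ties
broken by id order.

## The synthetic-data generator

The forward simulator is the test harness for every stage: a constant-N
population on a rectangular arena, uniform mother choice, fathers drawn
with Gaussian kernel weights exp(−r²/(2m²)), Mendelian segregation at
unlinked biallelic loci, offspring settling at the mother's position plus
Gaussian noise, and reflecting boundaries. Because IbD estimates *gene*
dispersal, the settlement SD σ_g is solved from
σ_g² = σ_true² − (1 − s)·m²/2 (s the selfing rate): a gene inherits the
father-to-mother displacement half the time, so the father kernel
contributes m²/2 to the axial gene-dispersal variance. The mate-choice
radius m defaults to σ_true.

Defaults chosen once and held fixed: founder allele frequencies are
Beta(0.8, 0.8) — a U-shaped, RAD-SNP-like spectrum whose rare tail the
minor-allele-count filter trims; loci are unlinked and mutation-free (runs
are short enough that drift dominates); density regulation is uniform
culling, which keeps true density exactly N/area. Validation runs use
N = 2000 at 0.3 m⁻² (an arena of ~82 × 82 m), 500 loci, 50 generations,
sampled exhaustively in two 25 × 4 m plots — magnitudes matching a dense
RADseq study of a coral stand, and sized so the whole validation suite runs
on one CPU in minutes.

Clonality has two pathways. The generational pathway copies the maternal
genotype with probability `clonal_rate` and displaces the clone by a
Gaussian; with non-overlapping generations, clone mates then sit at
Rayleigh(sd·√2) distances or farther (two or more displacement steps).
Fission — the dominant mechanism behind metre-scale clonal clusters in
plating corals, where the original colony survives the split — is modelled
by `plant_clones()`: the source ramet stays, the new ramet lands one
Rayleigh(sd) step away. Technical replicates, per-allele genotyping error
and missingness are layered on by `add_genotyping_noise()`.

What the generator does *not* emulate: overlapping generations and age
structure, larval transport by currents (kernels are isotropic Gaussians,
real kernels are likely fat-tailed), selection, linkage, and habitat
heterogeneity. Passing tests therefore certify the estimator chain under
its own model assumptions — they do not certify Gaussian kernels in real
reefs, and σ from a fat-tailed kernel underestimates the tail.

## Numerical conventions and degenerate inputs

* Distances below 0.01 m (coincident centroids) are floored at 0.01 m, the
  smallest distance treated as resolvable, keeping ln(d) finite.
* Natural logarithms throughout; significance is two-sided at 95%
  (CI excluding zero).
* Monomorphic loci contribute nothing to either metric; pairs with no
  co-typed polymorphic locus are dropped with a count. Fully monomorphic
  (or fully homozygous) tables raise errors rather than return 0/0.
* Bootstrap resamples whose denominator collapses to zero are discarded and
  counted; a single-locus table yields a zero-width interval.
* Undefined neighbourhoods (slope of the wrong sign) propagate as `Inf`
  sentinels, never silently dropped.
* All stochastic steps take explicit seeds and restore the caller's RNG
  state; a pipeline rerun with the same seed is numerically identical.

## Known limitations

* Locus-bootstrap intervals understate between-realization slope variance
  (see above); they are the appropriate *within-dataset* uncertainty, which
  is what feeds the σ distribution.
* With very small neighbourhoods (NS of a few individuals) the linear
  ln(d) approximation itself degrades and slopes run slightly steep.
* When the sampled extent is below ~10σ the method refuses a point estimate
  by design; only a broader sampling design can fix that.
* Memory: per-locus caches are O(pairs × loci); several hundred individuals
  by a few thousand loci fits comfortably, but tens of thousands of
  individuals would not.
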