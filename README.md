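# ibdsigma

Estimating how far sessile benthic organisms — corals in particular — send
their offspring each generation is notoriously hard: larvae are microscopic
and the ocean is large. `ibdsigma` implements the indirect, individual-based
route: when dispersal is limited, relatives cluster in space, genetic
distance between colonies increases with the log of geographic distance
(isolation by distance, IbD), and the slope of that increase carries the
generational dispersal distance.

## The model

For a population distributed in two dimensions, Wright's genetic
neighbourhood — the effective number of individuals within a circle of
radius 2σ — is

    NS = 4 π D σ²

where D is the density of individuals (per m²) and σ² the mean squared
*axial* parent–offspring displacement per generation. Rousset showed that
regressing the pairwise genetic distance *â* between individuals on ln(d)
gives a slope b with

    NS = 1 / b,

and for Loiselle's kinship coefficient F (preferred under inbreeding or
selfing), with F(1) the mean kinship among neighbours,

    NS = (1 − F(1)) / (−b).

Given an independent density estimate — census counts of distinct
multilocus genotypes, or an effective density from an externally estimated
contemporary N_e — σ follows as

    σ = sqrt(NS / (4 π D)),

and under a Gaussian kernel the mean Euclidean parent–offspring distance is
σ / 1.25. The regression is only informative at spatial scales near
migration–drift equilibrium (roughly σ to 10σ–50σ), so the distance window
is adjusted iteratively from the current σ estimate. Uncertainty in the
slope (locus bootstrap) and in density is propagated by Monte-Carlo
resampling into a probability distribution of σ.

The package covers the full workflow:

* **Data model** — VCF/TSV genotype input, colony coordinate maps with
  per-plot affine transforms and best-fit-plane 2D projection, RADseq-style
  filtering (individual missingness, minor-allele count, per-SNP
  missingness, optional depth masks), one-SNP-per-contig thinning.
* **Clones** — shared-allele distances, a clone-calling threshold calibrated
  on technical replicates, single-linkage genet assignment, clonal spatial
  summaries.
* **Metrics** — Rousset's *â* and Loiselle's *F* with cached per-locus
  contributions, Weir–Cockerham F_IS / F_ST.
* **IbD regression** — OLS on ln(distance) with locus-bootstrap and
  delete-one-locus jackknife confidence intervals (pair-level standard
  errors are deliberately not offered: pairs share individuals).
* **Dispersal** — neighbourhood-size conversion, census/effective densities,
  iterative window adjustment, Monte-Carlo σ distributions.
* **Simulator** — a continuous-space forward-time population with Gaussian
  mate choice and settlement, selfing, clonality (generational and fission
  dyads), genotyping error and technical replicates, with σ known exactly.

## A worked example

Simulate a brooding-coral-like population with σ = 3 m at density
0.3 colonies/m², sample two 25 × 4 m photogrammetry plots exhaustively, and
run the pipeline end to end:

```r
library(ibdsigma)

cfg <- sim_config(n_ind = 2000, sigma_true = 3, density = 0.3,
                  n_loci = 500, generations = 50, seed = 42)
out <- simulate_population(cfg)
sm  <- sample_plots(out, data.frame(plot = c("p1", "p2"),
                                    xmin = c(5, 45), xmax = c(30, 70),
                                    ymin = c(10, 40), ymax = c(14, 44)))

rep <- run_pipeline(list(
  genotypes   = sm$genotypes, colony_map = sm$map,
  metric      = "rousset_a",  clone_threshold = 0.02,
  plot_areas  = c(p1 = 100, p2 = 100),
  n_boot = 1000, n_draws = 2000, seed = 42))
rep$summary
```

```
  taxon    metric density      slope       NS sigma_median      pi5     pi95 flag
1   sim rousset_a  census 0.02407459 41.53757     3.421032 2.942792 3.967845
```

The fitted IbD slope b = 0.0241 sits close to the theoretical
1/(4π·0.3·3²) = 0.0295; its reciprocal is a neighbourhood of ≈ 42 effective
individuals, and combining it with the census density of the sampled plots
gives a Monte-Carlo σ median of 3.4 m (90% PI 2.9–4.0 m) against the true
3 m. A non-significant slope, or a distance range that cannot span σ to
k·σ, is reported as a flagged sentinel row rather than a number.

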