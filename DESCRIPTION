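Package: ibdsigma
Title: Generational Dispersal Distance from Individual-Based Isolation by
    Distance
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the generational dispersal distance (sigma) of
    sessile benthic organisms from co-registered SNP genotypes and mapped
    colony coordinates using individual-based isolation-by-distance
    regressions. Provides genotype filtering, clone (genet) detection
    calibrated on technical replicates, Rousset's a-hat and Loiselle's F
    pairwise statistics with locus-resampling confidence intervals,
    Wright neighbourhood-size conversion with iterative spatial-scale
    adjustment, Monte-Carlo propagation of neighbourhood and density
    uncertainty to a sigma distribution, and a continuous-space
    forward-time simulator for validation with known sigma.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
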