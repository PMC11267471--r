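#' Configuration for the continuous-space forward simulator
#'
#' The simulator emulates a sessile benthic population: individuals live on a
#' 2D arena at constant density, mothers are chosen uniformly, fathers by a
#' Gaussian mate-choice kernel, and offspring settle at the mother's position
#' plus Gaussian noise.  The estimand of IbD dispersal analysis is *gene*
#' dispersal, so the offspring-position SD `sigma_g` is solved such that the
#' effective axial gene-dispersal SD equals `sigma_true`: a gene moves
#' `sigma_g` when inherited from the mother and gains the father-to-mother
#' displacement (axial variance `mating_radius^2`) half the time, giving
#' `sigma_g^2 = sigma_true^2 - (1 - selfing_rate) * mating_radius^2 / 2`.
#'
#' @param n_ind number of individuals (constant across generations, >= 10).
#' @param sigma_true target axial gene-dispersal SD in metres (0 allowed for
#'   the degenerate no-dispersal case, which requires `mating_radius = 0` and
#'   `selfing_rate = 1`).
#' @param density individuals per m^2; with `arena = NULL` the arena is a
#'   square of area `n_ind / density`.
#' @param arena optional `c(width, height)` in metres (overrides `density`).
#' @param mating_radius axial SD of the Gaussian mate-choice kernel
#'   (default `sigma_true`).
#' @param selfing_rate probability a non-clonal offspring is selfed.
#' @param clonal_rate probability an offspring is an asexual copy of its
#'   mother.
#' @param clonal_displacement_sd axial SD (m) of the clone displacement.
#' @param n_loci number of unlinked biallelic loci.
#' @param allele_freq_beta `c(alpha, beta)` of the founder allele-frequency
#'   Beta distribution.
#' @param generations number of non-overlapping generations.
#' @param error_rate,missing_rate,n_replicate_samples genotyping-noise
#'   settings applied by [add_genotyping_noise()] when
#'   [simulate_population()] is asked to.
#' @param seed integer RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_ind = 500L, sigma_true = 3, density = 0.3,
                       arena = NULL, mating_radius = NULL, selfing_rate = 0,
                       clonal_rate = 0, clonal_displacement_sd = 0.5,
                       n_loci = 200L, allele_freq_beta = c(0.8, 0.8),
                       generations = 50L, error_rate = 0, missing_rate = 0,
                       n_replicate_samples = 0L, seed = 1L) {
  if (is.null(mating_radius)) mating_radius <- sigma_true
  if (is.null(arena)) {
    side <- sqrt(n_ind / density)
    arena <- c(side, side)
  }
  stopifnot(n_ind >= 10, sigma_true >= 0, all(arena > 0), n_loci >= 1,
            generations >= 0, mating_radius >= 0,
            selfing_rate >= 0, selfing_rate <= 1,
            clonal_rate >= 0, clonal_rate <= 1,
            clonal_displacement_sd >= 0,
                        error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (mating_radius == 0 && selfing_rate < 1 && clonal_rate < 1)
    stop("mating_radius = 0 requires selfing_rate = 1 (no outcross mates)")
  sigma_g2 <- sigma_true^2 - (1 - selfing_rate) * mating_radius^2 / 2
  if (sigma_g2 < 0)
    stop("mating_radius too large: (1 - selfing) * mating_radius^2 / 2 ",
         "exceeds sigma_true^2")
  structure(list(n_ind = as.integer(n_ind), sigma_true = sigma_true,
                 arena = arena, mating_radius = mating_radius,
                 selfing_rate = selfing_rate, clonal_rate = clonal_rate,
                 clonal_displacement_sd = clonal_displacement_sd,
                 n_loci = as.integer(n_loci),
                 allele_freq_beta = allele_freq_beta,
                 generations = as.integer(generations),
                 error_rate = error_rate, missing_rate = missing_rate,
                 n_replicate_samples = as.integer(n_replicate_samples),
                 seed = as.integer(seed), sigma_g = sqrt(sigma_g2)),
            class = "sim_config")
}

#' Run the forward simulation
#'
#' Founders are placed uniformly on the arena with Hardy-Weinberg genotypes
#' at Beta-distributed allele frequencies; each generation every one of the
#' `n_ind` offspring picks a uniform mother and is either an asexual copy
#' (probability `clonal_rate`, displaced by the clone kernel) or a sexual
#' offspring (selfed with probability `selfing_rate`, otherwise the father is
#' drawn proportional to `exp(-r^2 / (2 * mating_radius^2))`), with Mendelian
#' segregation at unlinked loci, settlement at the mother's position plus
#' Gaussian noise, and reflecting arena boundaries.
#'
#' @param cfg a [sim_config()].
#' @param noise also apply [add_genotyping_noise()] using the rates in `cfg`
#'   (default `TRUE` when any of them is non-zero).
#' @return A `sim_output` list: `genotypes` ([genotype_table()]), `map`
#'   ([colony_map()]), and `truth` (`sigma_true`, `D_true`, `genet`,
#'   `pedigree` of the last generation).
#' @export
simulate_population <- function(cfg, noise = NULL) {
  old <- local_seed(cfg$seed)
  on.exit(restore_seed(old))
  N <- cfg$n_ind; L <- cfg$n_loci
  p <- rbeta(L, cfg$allele_freq_beta[1], cfg$allele_freq_beta[2])
  geno0 <- matrix(rbinom(N * L, 2L, rep(p, each = N)), N, L)
  x0 <- runif(N, 0, cfg$arena[1])
  y0 <- runif(N, 0, cfg$arena[2])
  res <- .sim_forward_cpp(geno0, x0, y0, cfg$arena[1], cfg$arena[2],
                          cfg$generations, cfg$sigma_g, cfg$mating_radius,
                          cfg$selfing_rate, cfg$clonal_rate,
                          cfg$clonal_displacement_sd)
  ids <- sprintf("sim%04d", seq_len(N))
  g <- genotype_table(matrix(res$genotypes, N, L,
                             dimnames = list(ids, sprintf("c%04d_snp", seq_len(L)))),
                      contig_id = sprintf("c%04d", seq_len(L)),
                      taxon = rep("sim", N))
  map <- colony_map(data.frame(id = ids, location = "loc1", plot = "plot1",
                               x = res$x, y = res$y, z = 0))
  pedigree <- NULL
  if (cfg$generations > 0) {
    pedigree <- data.frame(
      id = ids,
      mother = ids[res$mother + 1L],
      father = ifelse(res$father < 0, NA, ids[pmax(res$father, 0) + 1L]),
      is_clone = res$is_clone == 1L,
      mother_x = res$mother_x, mother_y = res$mother_y,
      father_x = res$father_x, father_y = res$father_y,
      x = res$x, y = res$y, stringsAsFactors = FALSE)
  }
  out <- structure(list(
    genotypes = g, map = map,
    truth = list(sigma_true = cfg$sigma_true,
                 D_true = N / prod(cfg$arena),
                 genet = setNames(res$genet, ids),
                 pedigree = pedigree),
    config = cfg), class = "sim_output")
  if (is.null(noise))
    noise <- cfg$error_rate > 0 || cfg$missing_rate > 0 ||
      cfg$n_replicate_samples > 0
  if (noise)
    out <- add_genotyping_noise(out, cfg$error_rate, cfg$missing_rate,
                                cfg$n_replicate_samples,
                                seed = cfg$seed + 1L)
  out
}

#' @export
print.sim_output <- function(x, ...) {
  cat("sim_output:", nrow(x$genotypes$genotypes), "individuals,",
      ncol(x$genotypes$genotypes), "loci; sigma_true =",
      x$truth$sigma_true, "m, D_true =", signif(x$truth$D_true, 3), "m^-2\n")
  invisible(x)
}

#' Restrict a simulation to rectangular sampling plots
#'
#' Emulates exhaustive sampling within photogrammetry plots (e.g. 25 m x 4 m
#' belts): only individuals inside a plot rectangle are retained and
#' relabelled with that plot (and optionally location).
#'
#' @param out a `sim_output`.
#' @param plot_specs data.frame with columns `plot`, `xmin`, `xmax`, `ymin`,
#'   `ymax` and optionally `location`.
#' @return The restricted `sim_output`.
#' @export
sample_plots <- function(out, plot_specs) {
  stopifnot(all(c("plot", "xmin", "xmax", "ymin", "ymax") %in%
                  names(plot_specs)))
  arena <- out$config$arena
  if (any(plot_specs$xmin < 0 | plot_specs$xmax > arena[1] |
          plot_specs$ymin < 0 | plot_specs$ymax > arena[2]))
    stop("plot rectangle outside the arena")
  m <- out$map
  plot_lab <- rep(NA_character_, nrow(m))
  loc_lab <- rep(NA_character_, nrow(m))
  for (r in seq_len(nrow(plot_specs))) {
    inside <- is.na(plot_lab) &
      m$x >= plot_specs$xmin[r] & m$x <= plot_specs$xmax[r] &
      m$y >= plot_specs$ymin[r] & m$y <= plot_specs$ymax[r]
    if (!any(inside)) warning("empty plot: ", plot_specs$plot[r])
    plot_lab[inside] <- as.character(plot_specs$plot[r])
    loc_lab[inside] <- if ("location" %in% names(plot_specs))
      as.character(plot_specs$location[r]) else "loc1"
  }
  keep <- which(!is.na(plot_lab))
  if (!length(keep)) stop("no individuals inside any plot")
  m2 <- m[keep, , drop = FALSE]
  m2$plot <- plot_lab[keep]
  m2$location <- loc_lab[keep]
  rownames(m2) <- NULL
  out$map <- colony_map(m2)
  out$genotypes <- subset_genotypes(out$genotypes, ind = keep)
  out$truth$genet <- out$truth$genet[keep]
  if (!is.null(out$truth$pedigree))
    out$truth$pedigree <- out$truth$pedigree[keep, , drop = FALSE]
  out$plot_specs <- plot_specs
  out
}

#' Plant clonal dyads by fission
#'
#' Colony fission leaves the original ramet in place and adds a second ramet
#' of the same genet displaced by a bivariate Gaussian (so dyad distances are
#' Rayleigh-distributed with scale `displacement_sd`).  This emulates the
#' dominant mode of fine-scale clonal spread in plating corals, where clone
#' mates sit within a metre of each other, and complements the generational
#' `clonal_rate` pathway (in which both clone mates are offspring and carry
#' two displacement steps).
#'
#' @param out a `sim_output`.
#' @param n_dyads number of colonies to split.
#' @param displacement_sd axial SD (m) of the new ramet's displacement.
#' @param seed integer RNG seed.
#' @return The `sim_output` with `n_dyads` additional ramets appended.
#' @export
plant_clones <- function(out, n_dyads, displacement_sd = 0.4, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  g <- out$genotypes
  n <- nrow(g$genotypes)
  n_dyads <- min(n_dyads, n)
  src <- sort(sample.int(n, n_dyads))
  ids <- individual_ids(g)
  new_ids <- paste0(ids[src], "_f")
  X <- rbind(g$genotypes, g$genotypes[src, , drop = FALSE])
  rownames(X) <- c(ids, new_ids)
  rg <- g$replicate_group
  if (!is.null(rg)) rg <- c(rg, rg[src])
  out$genotypes <- genotype_table(X, contig_id = g$contig_id,
                                  replicate_group = rg,
                                  taxon = c(g$taxon, g$taxon[src]))
  m <- as.data.frame(out$map)
  rows <- m[match(ids[src], m$id), , drop = FALSE]
  rows$id <- new_ids
  arena <- out$config$arena
  rows$x <- pmin(pmax(rows$x + rnorm(n_dyads, 0, displacement_sd), 0), arena[1])
  rows$y <- pmin(pmax(rows$y + rnorm(n_dyads, 0, displacement_sd), 0), arena[2])
  m2 <- rbind(m, rows)
  rownames(m2) <- NULL
  out$map <- colony_map(m2)
  out$truth$genet <- c(out$truth$genet,
                       setNames(out$truth$genet[src], new_ids))
  out$truth$planted_dyads <- cbind(ids[src], new_ids)
  out
}

#' Add genotyping error, missingness and technical replicates
#'
#' Technical replicate samples are duplicated first (sharing a
#' `replicate_group` label with their source colony and its coordinates);
#' each allele call of every sample is then flipped independently with
#' probability `error_rate`, and calls are masked with probability
#' `missing_rate`.
#'
#' @param out a `sim_output`.
#' @param error_rate per-allele flip probability.
#' @param missing_rate per-call masking probability.
#' @param n_replicate_samples number of individuals to resample as technical
#'   replicates.
#' @param seed integer RNG seed.
#' @return The noised `sim_output`.
#' @export
add_genotyping_noise <- function(out, error_rate, missing_rate,
                                 n_replicate_samples = 0L, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  g <- out$genotypes
  X <- g$genotypes
  ids <- rownames(X)
  taxon <- g$taxon
  rep_group <- rep(NA_character_, nrow(X))
  if (n_replicate_samples > 0) {
    n_replicate_samples <- min(n_replicate_samples, nrow(X))
    src <- sort(sample.int(nrow(X), n_replicate_samples))
    rep_group[src] <- ids[src]
    X <- rbind(X, X[src, , drop = FALSE])
    rep_ids <- paste0(ids[src], "_rep")
    rownames(X) <- c(ids, rep_ids)
    rep_group <- c(rep_group, ids[src])
    extra <- out$map[match(ids[src], out$map$id), , drop = FALSE]
    extra$id <- rep_ids
    m2 <- rbind(as.data.frame(out$map), extra)
    rownames(m2) <- NULL
    out$map <- colony_map(m2)
    out$truth$genet <- c(out$truth$genet,
                         setNames(out$truth$genet[src], rep_ids))
    taxon <- c(taxon, taxon[src])
  }
  if (error_rate > 0) {
    a1 <- (!is.na(X)) & X >= 1L          # alt call on first allele
    a2 <- (!is.na(X)) & X == 2L
    f1 <- matrix(runif(length(X)) < error_rate, nrow(X))
    f2 <- matrix(runif(length(X)) < error_rate, nrow(X))
    Xn <- (a1 != f1) + (a2 != f2)
    Xn[is.na(X)] <- NA_integer_
    dimnames(Xn) <- dimnames(X)
    X <- Xn
  }
  if (missing_rate > 0)
    X[matrix(runif(length(X)) < missing_rate, nrow(X))] <- NA_integer_
  out$genotypes <- genotype_table(X, contig_id = g$contig_id,
                                  replicate_group = rep_group,
                                  taxon = taxon)
  out
}
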