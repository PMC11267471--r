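test_that("config validation enforces the dispersal-composition constraints", {
  expect_error(sim_config(mating_radius = 0, selfing_rate = 0.5),
               "selfing_rate = 1")
  expect_error(sim_config(sigma_true = 1, mating_radius = 5), "too large")
  cfg <- sim_config(sigma_true = 3, mating_radius = 3, selfing_rate = 0)
  expect_equal(cfg$sigma_g, sqrt(9 - 9 / 2))
  # selfing reduces the father-side contribution
  cfg2 <- sim_config(sigma_true = 3, mating_radius = 3, selfing_rate = 1)
  expect_equal(cfg2$sigma_g, 3)
})

test_that("same seed reproduces the simulation draw for draw", {
  cfg <- sim_config(n_ind = 60, n_loci = 30, generations = 5, seed = 12)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$genotypes$genotypes, b$genotypes$genotypes)
  expect_identical(a$map$x, b$map$x)
})

test_that("pure clonality copies genotypes without segregation", {
  cfg <- sim_config(n_ind = 80, n_loci = 40, generations = 6,
                    clonal_rate = 1, seed = 3)
  out <- simulate_population(cfg)
  expect_true(all(out$truth$pedigree$is_clone))
  gid <- out$truth$genet
  X <- out$genotypes$genotypes
  for (g in unique(gid)) {
    rows <- X[gid == g, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(v) length(unique(v)) == 1)))
  }
})

test_that("zero dispersal pins offspring to the maternal position", {
  cfg <- sim_config(n_ind = 50, sigma_true = 0, mating_radius = 0,
                    selfing_rate = 1, n_loci = 10, generations = 3, seed = 4)
  out <- simulate_population(cfg)
  ped <- out$truth$pedigree
  expect_equal(ped$x, ped$mother_x, tolerance = 1e-12)
  expect_equal(ped$y, ped$mother_y, tolerance = 1e-12)
})

test_that("effective axial gene dispersal matches sigma_true within 5%", {
  cfg <- sim_config(n_ind = 12000, sigma_true = 2, density = 0.3, n_loci = 2,
                    generations = 1, seed = 10)
  out <- simulate_population(cfg)
  ped <- out$truth$pedigree
  # a gene comes from the mother or the father with equal probability
  set.seed(1)
  from_father <- runif(nrow(ped)) < 0.5 & !is.na(ped$father_x)
  px <- ifelse(from_father, ped$father_x, ped$mother_x)
  # drop lineages whose settlement crossed a reflecting boundary zone
  inner <- px > 8 & px < cfg$arena[1] - 8
  disp <- (ped$x - px)[inner]
  expect_gt(length(disp), 1e4 * 0.6)
  expect_equal(sd(disp), 2, tolerance = 0.05)
})

test_that("plot sampling is exhaustive, exclusive and density-consistent", {
  cfg <- sim_config(n_ind = 1200, sigma_true = 3, density = 0.3,
                    n_loci = 5, generations = 2, seed = 6)
  out <- simulate_population(cfg)
  full <- sample_plots(out, data.frame(plot = "all", xmin = 0,
                                       xmax = cfg$arena[1], ymin = 0,
                                       ymax = cfg$arena[2]))
  expect_equal(nrow(full$genotypes$genotypes), cfg$n_ind)

  ps <- data.frame(plot = c("a", "b"), xmin = c(0, 30), xmax = c(25, 55),
                   ymin = c(0, 20), ymax = c(4, 24))
  sm <- sample_plots(out, ps)
  expect_true(all(table(sm$map$plot) > 0))
  expect_equal(anyDuplicated(sm$map$id), 0L)
  # expected count per 100 m^2 plot at density 0.3 is 30
  counts <- vapply(1:4, function(k) {
    o <- simulate_population(sim_config(n_ind = 1200, sigma_true = 3,
                                        density = 0.3, n_loci = 5,
                                        generations = 2, seed = 700 + k))
    nrow(sample_plots(o, ps)$map)
  }, numeric(1))
  expect_equal(mean(counts), 60, tolerance = 0.25)
  expect_error(sample_plots(out, data.frame(plot = "x", xmin = -5, xmax = 1,
                                            ymin = 0, ymax = 1)),
               "outside the arena")
})

test_that("genotyping noise flips alleles at the requested rate and masks
           calls", {
  cfg <- sim_config(n_ind = 150, n_loci = 300, generations = 0, seed = 8)
  out <- simulate_population(cfg)
  clean <- out$genotypes$genotypes

  same <- add_genotyping_noise(out, 0, 0, 0, seed = 9)
  expect_identical(same$genotypes$genotypes, clean)

  noisy <- add_genotyping_noise(out, 0.01, 0, 0, seed = 9)
  flips <- sum(abs(noisy$genotypes$genotypes - clean))
  # each call carries 2 alleles: expected allele flips = 2 * n * L * eps
  expect_equal(flips / (2 * length(clean)), 0.01, tolerance = 0.25)

  gone <- add_genotyping_noise(out, 0, 1, 0, seed = 9)
  expect_true(all(is.na(gone$genotypes$genotypes)))
  d_gone <- suppressWarnings(clonal_distance(gone$genotypes))
  expect_true(all(is.na(d_gone[upper.tri(d_gone)])))
})

test_that("replicate-pair clonal distance matches a Monte-Carlo oracle of
           the flip process", {
  eps <- 0.01
  cfg <- sim_config(n_ind = 120, n_loci = 500, generations = 0, seed = 21)
  out <- simulate_population(cfg)
  noised <- add_genotyping_noise(out, eps, 0, n_replicate_samples = 30,
                                 seed = 22)
  d <- suppressWarnings(clonal_distance(noised$genotypes))
  rp <- ibdsigma:::replicate_pairs(noised$genotypes)
  obs <- mean(d[rp])

  # independent oracle: flip alleles of duplicated dosages in plain R
  set.seed(5)
  dos <- as.vector(out$genotypes$genotypes)
  flip <- function(v) {
    a1 <- as.integer(v >= 1); a2 <- as.integer(v == 2)
    f1 <- runif(length(v)) < eps; f2 <- runif(length(v)) < eps
    (a1 != f1) + (a2 != f2)
  }
  mc <- replicate(40, mean(abs(flip(dos) - flip(dos))) / 2)
  expect_equal(obs, mean(mc), tolerance = 0.15)
})

test_that("selfing raises F_IS monotonically and panmixia keeps it near 0", {
  grid <- c(0, 0.4, 0.8)
  fis_vals <- vapply(seq_along(grid), function(k) {
    cfg <- sim_config(n_ind = 300, sigma_true = 3, density = 0.3,
                      n_loci = 150, generations = 12,
                      selfing_rate = grid[k], seed = 40 + k)
    out <- simulate_population(cfg)
    fis(out$genotypes, rep("p", 300), jackknife = FALSE)$fis
  }, numeric(1))
  expect_true(all(diff(fis_vals) > 0))
  expect_gt(fis_vals[3], 0.4)            # strong-selfing regime
  expect_gt(cor(grid, fis_vals, method = "spearman"), 0.9)

  cfg0 <- sim_config(n_ind = 400, sigma_true = 10, density = 0.3,
                     mating_radius = 10, n_loci = 200, generations = 0,
                     seed = 50)
  out0 <- simulate_population(cfg0)
  expect_lt(abs(fis(out0$genotypes, rep("p", 400), jackknife = FALSE)$fis),
            0.05)
})

test_that("allele frequencies drift without directional change", {
  cfg <- sim_config(n_ind = 1000, sigma_true = 3, density = 0.3,
                    n_loci = 300, generations = 5, seed = 17)
  out <- simulate_population(cfg)
  # replay the founder frequency draw made under the same seed
  old <- ibdsigma:::local_seed(cfg$seed)
  p0 <- rbeta(cfg$n_loci, cfg$allele_freq_beta[1], cfg$allele_freq_beta[2])
  ibdsigma:::restore_seed(old)
  p_final <- colMeans(out$genotypes$genotypes) / 2
  expect_lt(abs(mean(p_final - p0)), 0.01)
})

test_that("planted fission dyads sit at Rayleigh-scale distances", {
  cfg <- sim_config(n_ind = 400, sigma_true = 3, density = 0.3, n_loci = 5,
                    generations = 0, seed = 61)
  out <- simulate_population(cfg)
  out <- plant_clones(out, n_dyads = 300, displacement_sd = 0.3, seed = 62)
  m <- out$map
  dy <- out$truth$planted_dyads
  dd <- sqrt((m$x[match(dy[, 1], m$id)] - m$x[match(dy[, 2], m$id)])^2 +
               (m$y[match(dy[, 1], m$id)] - m$y[match(dy[, 2], m$id)])^2)
  expect_equal(median(dd), 0.3 * sqrt(2 * log(2)), tolerance = 0.12)
  expect_equal(out$truth$genet[dy[, 1]], out$truth$genet[dy[, 2]],
               ignore_attr = TRUE)
})
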