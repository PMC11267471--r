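vcf_lines <- function(records, samples = c("s1", "s2")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

test_that("VCF parsing yields the dosage matrix with contigs preserved", {
  tf <- tempfile(fileext = ".vcf")
  writeLines(vcf_lines(c(
    "ctg1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1",
    "ctg1\t20\t.\tG\tC\t.\tPASS\t.\tGT\t1/1\t./.",
    "ctg2\t5\t.\tT\tA\t.\tPASS\t.\tGT\t0|1\t1|1")), tf)
  g <- read_genotypes(tf)
  expect_equal(dim(g), c(2L, 3L))
  expect_equal(unname(g$genotypes["s1", ]), c(0L, 2L, 1L))
  expect_equal(unname(g$genotypes["s2", ]), c(1L, NA_integer_, 2L))
  expect_equal(g$contig_id, c("ctg1", "ctg1", "ctg2"))
})

test_that("multi-allelic VCF records are rejected, naming the record", {
  tf <- tempfile(fileext = ".vcf")
  writeLines(vcf_lines("ctg1\t30\t.\tA\tT,C\t.\tPASS\t.\tGT\t0/1\t0/2"), tf)
  expect_error(read_genotypes(tf), "ctg1:30")
})

test_that("genotype TSV round-trips exactly, and duplicate ids error", {
  g <- genotype_table(random_dosage(5, 8, miss = 0.2, seed = 3),
                      contig_id = rep(c("a", "b"), each = 4))
  tf <- tempfile(fileext = ".tsv")
  write_genotypes_tsv(g, tf)
  g2 <- read_genotypes(tf)
  expect_identical(g$genotypes, g2$genotypes)
  expect_identical(g$contig_id, g2$contig_id)

  X <- random_dosage(2, 3)
  rownames(X) <- c("dup", "dup")
  expect_error(genotype_table(X, contig_id = letters[1:3]), "duplicate")
})

test_that("colony map reading validates columns, ids and coordinates", {
  tf <- tempfile(fileext = ".tsv")
  df <- data.frame(id = c("a", "b", "c"), location = "L1", plot = "P1",
                   x = c(0, 3, 1), y = c(0, 4, 1), z = 5)
  write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  m <- read_colony_map(tf)
  expect_s3_class(m, "colony_map")
  expect_equal(nrow(m), 3L)

  df2 <- df; df2$id <- c("a", "a", "c")
  write.table(df2, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_colony_map(tf), "duplicate")

  write.table(df[, -4], tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_colony_map(tf), "missing column")

  df3 <- df; df3$x <- c("0", "oops", "1")
  write.table(df3, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_colony_map(tf), "row 2")

  write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_warning(read_colony_map(tf, genotype_ids = c("a", "b", "zz")),
                 "lack coordinates")
})

test_that("per-plot affine transforms behave as similarities", {
  m <- colony_map(data.frame(id = paste0("c", 1:6), location = "L1",
                             plot = rep(c("P1", "P2"), each = 3),
                             x = c(0, 3, 1, 0, 1, 2), y = c(0, 4, 1, 0, 2, 0),
                             z = 5))
  idt <- list(P1 = list(), P2 = list())
  expect_equal(transform_coordinates(m, idt)$x, m$x)

  d0 <- pairwise_distance_2d(m, flatten = FALSE)
  sc <- transform_coordinates(m, list(P1 = list(scale = 2), P2 = list()))
  d1 <- pairwise_distance_2d(sc, flatten = FALSE)
  within_p1 <- d0$i %in% paste0("c", 1:3) & d0$j %in% paste0("c", 1:3)
  expect_equal(d1$d[within_p1], 2 * d0$d[within_p1])

  tr <- transform_coordinates(m, list(P1 = list(translation = c(5, -2, 1)),
                                      P2 = list()))
  d2 <- pairwise_distance_2d(tr, flatten = FALSE)
  expect_equal(d2$d[within_p1], d0$d[within_p1])

  expect_error(transform_coordinates(m, list(P1 = list())), "P2")
  expect_error(transform_coordinates(m, list(P1 = list(scale = 0), P2 = list())),
               "scale")
})

test_that("2D distances are Euclidean, within-location only, and floored", {
  m <- colony_map(data.frame(
    id = c("a", "b", "c", "d"), location = c("L1", "L1", "L1", "L2"),
    plot = c("P1", "P1", "P2", "P3"),
    x = c(0, 3, 10, 100), y = c(0, 4, 0, 0), z = 0))
  d <- pairwise_distance_2d(m)
  expect_equal(d$d[d$i == "a" & d$j == "b"], 5)
  # same-location cross-plot pair present, cross-location pair absent
  expect_true(any(d$i == "a" & d$j == "c"))
  expect_false(any(d$i == "d" | d$j == "d"))

  m2 <- colony_map(data.frame(id = c("a", "b", "e"), location = "L1",
                              plot = "P1", x = c(0, 3, 0), y = c(0, 4, 0),
                              z = 0))
  expect_warning(d2 <- pairwise_distance_2d(m2), "floored")
  expect_equal(min(d2$d), 0.01)
})

test_that("distances are symmetric, obey the triangle inequality, and scale", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 12
    m <- colony_map(data.frame(id = paste0("c", 1:n), location = "L1",
                               plot = "P1", x = runif(n, 0, 25),
                               y = runif(n, 0, 4), z = runif(n, 4, 6)))
    d <- pairwise_distance_2d(m)
    dm <- matrix(0, n, n, dimnames = list(m$id, m$id))
    dm[cbind(d$i, d$j)] <- d$d
    dm <- dm + t(dm)
    tri <- replicate(20, sample(n, 3))
    for (k in 1:20) {
      a <- tri[1, k]; b <- tri[2, k]; cc <- tri[3, k]
      expect_lte(dm[a, b], dm[a, cc] + dm[cc, b] + 1e-9)
    }
    expect_true(all(d$d <= sqrt(25^2 + 4^2) + 1e-9))
    sc <- m; sc$x <- 3 * sc$x; sc$y <- 3 * sc$y; sc$z <- 3 * sc$z
    d3 <- pairwise_distance_2d(sc)
    expect_equal(d3$d, 3 * d$d, tolerance = 1e-8)
  }
})

test_that("filtering removes individuals first, then MAC/missing loci", {
  set.seed(5)
  X <- random_dosage(10, 20, seed = 5)
  X[X == 2L] <- 1L                       # keep MAC comfortably high
  X[1, 1:12] <- NA                       # individual 1: 60% missing
  X[, 20] <- c(1L, rep(0L, 9))           # after removing ind 1: MAC 0
  g <- genotype_table(X, contig_id = paste0("ctg", 1:20))
  f <- filter_genotypes(g, filter_config(min_allele_count = 3))
  rep <- attr(f, "filter_report")
  expect_equal(rep$n_ind_removed_missing, 1L)
  expect_false("i1" %in% rownames(f$genotypes))
  expect_false("l20" %in% colnames(f$genotypes))

  # MAC threshold boundary: count of 2 fails at MAC = 3
  X2 <- matrix(1L, 8, 2, dimnames = list(paste0("i", 1:8), c("a", "b")))
  X2[, 2] <- c(1L, 1L, rep(0L, 6))
  g2 <- genotype_table(X2, contig_id = c("c1", "c2"))
  f2 <- filter_genotypes(g2, filter_config(min_allele_count = 3))
  expect_equal(colnames(f2$genotypes), "a")

  # clean table is unchanged, and filtering is idempotent
  X3 <- random_dosage(12, 10, seed = 9)
  g3 <- genotype_table(X3, contig_id = paste0("c", 1:10))
  f3 <- filter_genotypes(g3)
  f4 <- filter_genotypes(f3)
  expect_identical(f3$genotypes, f4$genotypes)
})

test_that("depth masking applies only when depth is present", {
  X <- matrix(1L, 4, 3, dimnames = list(paste0("i", 1:4), paste0("l", 1:3)))
  dp <- matrix(10, 4, 3); dp[1, 1] <- 2; dp[2, 2] <- 1000
  g <- genotype_table(X, contig_id = paste0("c", 1:3), depth = dp)
  f <- filter_genotypes(g, filter_config(min_allele_count = 1))
  expect_equal(attr(f, "filter_report")$n_calls_depth_masked, 2L)
  g2 <- genotype_table(X, contig_id = paste0("c", 1:3))
  f2 <- filter_genotypes(g2, filter_config(min_allele_count = 1))
  expect_true(is.na(attr(f2, "filter_report")$n_calls_depth_masked))
})

test_that("one-SNP-per-contig thinning is exact, seeded and forced", {
  X <- random_dosage(6, 15, seed = 2)
  g <- genotype_table(X, contig_id = rep(c("a", "b", "c"), each = 5))
  t1 <- thin_one_snp_per_contig(g, seed = 7)
  expect_equal(ncol(t1$genotypes), 3L)
  expect_equal(sort(unique(t1$contig_id)), c("a", "b", "c"))
  t2 <- thin_one_snp_per_contig(g, seed = 7)
  expect_identical(colnames(t1$genotypes), colnames(t2$genotypes))

  g3 <- genotype_table(X[, 1:6], contig_id = c(rep("a", 5), "solo"))
  t3 <- thin_one_snp_per_contig(g3, seed = 1)
  expect_true("l6" %in% colnames(t3$genotypes))
})
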