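# Independent brute-force oracles: literal term-by-term enumeration of the
# estimator definitions, kept loop-heavy and free of any package code path.

# Loiselle kinship: explicit loop over pairs, loci and both alleles.
oracle_loiselle <- function(X) {
  n <- nrow(X); L <- ncol(X)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- 0; den <- 0
    for (l in seq_len(L)) {
      typed <- which(!is.na(X[, l]))
      if (length(typed) < 2 || !(i %in% typed) || !(j %in% typed)) next
      nl <- length(typed)
      for (allele in 1:2) {
        p <- if (allele == 1) X[, l] / 2 else 1 - X[, l] / 2
        pbar <- mean(p[typed])
        if (pbar <= 0 || pbar >= 1) next
        num <- num + (p[i] - pbar) * (p[j] - pbar) + pbar * (1 - pbar) / (nl - 1)
        den <- den + pbar * (1 - pbar)
      }
    }
    out[i, j] <- out[j, i] <- num / den
  }
  out
}

# Rousset a-hat: enumerate the four cross-individual allele pairs per locus,
# with the sample-wide within-individual identity Qw.
alleles_of <- function(d) if (d == 0) c(0L, 0L) else if (d == 2) c(1L, 1L) else c(0L, 1L)

oracle_rousset <- function(X) {
  n <- nrow(X); L <- ncol(X)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(X), rownames(X)))
  qw <- numeric(L)
  for (l in seq_len(L)) {
    typed <- which(!is.na(X[, l]))
    ident <- vapply(typed, function(i) {
      a <- alleles_of(X[i, l]); as.numeric(a[1] == a[2])
    }, numeric(1))
    qw[l] <- mean(ident)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- 0; den <- 0
    for (l in seq_len(L)) {
      if (is.na(X[i, l]) || is.na(X[j, l])) next
      if (sum(!is.na(X[, l])) < 2) next
      ai <- alleles_of(X[i, l]); aj <- alleles_of(X[j, l])
      qij <- 0
      for (u in 1:2) for (v in 1:2) qij <- qij + (ai[u] == aj[v]) / 4
      num <- num + qw[l] - qij
      den <- den + 1 - qw[l]
    }
    out[i, j] <- out[j, i] <- num / den
  }
  out
}

# extract the pairwise metric matrix from a pair_metric_table
pair_matrix <- function(t, ids) {
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(t$pairs$i, t$pairs$j)] <- t$pairs$value
  m[cbind(t$pairs$j, t$pairs$i)] <- t$pairs$value
  m
}

# random dosage matrix with controlled missingness
random_dosage <- function(n, L, miss = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(sample(0:2, n * L, replace = TRUE), n, L,
              dimnames = list(paste0("i", seq_len(n)), paste0("l", seq_len(L))))
  if (miss > 0) X[matrix(runif(n * L) < miss, n)] <- NA_integer_
  X
}

# two-deme Wright-Fisher allele-frequency simulation (island model) used as
# an independent oracle for F_ST ~ 1/(1 + 4Nm)
island_model_freqs <- function(L, N, m, G, seed) {
  set.seed(seed)
  p <- matrix(runif(L, 0.2, 0.8), L, 2)
  for (g in seq_len(G)) {
    pm <- cbind((1 - m) * p[, 1] + m * p[, 2], (1 - m) * p[, 2] + m * p[, 1])
    p <- matrix(rbinom(2 * L, 2 * N, pm), L, 2) / (2 * N)
  }
  p
}

hw_genotypes <- function(p, n) {
  L <- length(p)
  matrix(rbinom(n * L, 2L, rep(p, each = n)), n, L)
}
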