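## Pairwise genetic statistics used in individual-based IbD: Loiselle's
## kinship F and Rousset's a-hat.  Both are multilocus ratio-of-sums
## estimators; per-pair, per-locus numerator and denominator contributions are
## cached so confidence intervals can be built by resampling loci.

pair_index <- function(n) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = ut[, 1], j = ut[, 2])
}

## attach within-location 2D distances to pairs; NA where unavailable
pair_distances <- function(ids_i, ids_j, map) {
  if (is.null(map)) return(rep(NA_real_, length(ids_i)))
  pd <- pairwise_distance_2d(map)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pd_key <- key(pd$i, pd$j)
  pd$d[match(key(ids_i, ids_j), pd_key)]
}

new_pair_metric_table <- function(ids, px, metric_name, num, den, d, locus_id) {
  denom <- rowSums(den)
  if (all(denom == 0)) {
    if (metric_name == "loiselle_F")
      stop("zero denominator: no polymorphism")
    stop("zero denominator: all individuals fully homozygous at all loci")
  }
  value <- rowSums(num) / denom
  dropped <- sum(denom == 0)
  if (dropped)
    message(dropped, " pair(s) share no co-typed polymorphic loci; dropped")
  keep <- denom > 0
  structure(list(
    pairs = data.frame(i = ids[px$i][keep], j = ids[px$j][keep],
                       d = d[keep], value = value[keep],
                       stringsAsFactors = FALSE),
    num = num[keep, , drop = FALSE], den = den[keep, , drop = FALSE],
    metric_name = metric_name, locus_id = locus_id,
    n_pairs_dropped = dropped), class = "pair_metric_table")
}

#' @export
print.pair_metric_table <- function(x, ...) {
  cat("pair_metric_table (", x$metric_name, "): ", nrow(x$pairs), " pairs, ",
      ncol(x$num), " loci; ", sum(is.finite(x$pairs$d)),
      " pairs with within-location distance\n", sep = "")
  invisible(x)
}

#' Loiselle's kinship coefficient between individuals
#'
#' For locus l with reference-allele frequency estimate `p_i = dosage/2` per
#' individual and sample mean `pbar` over the `n_l` typed individuals, the
#' per-allele pair numerator is
#' `(p_i - pbar)(p_j - pbar) + pbar(1 - pbar)/(n_l - 1)` (the second term is
#' the finite-sample correction) and the denominator `pbar(1 - pbar)`; both
#' are summed over the two alleles of a biallelic SNP (doubling the
#' single-allele terms) and over loci, and the multilocus kinship is the ratio
#' of sums.  Loci at which either member of a pair is untyped contribute
#' nothing to that pair.
#'
#' @param g a [genotype_table()] with >= 3 individuals and >= 1 polymorphic
#'   locus.
#' @param map optional [colony_map()]; when supplied, within-location 2D
#'   distances are attached to pairs (cross-location pairs get `NA`).
#' @return A `pair_metric_table` with per-locus contributions cached for
#'   locus resampling.
#' @export
loiselle_kinship <- function(g, map = NULL) {
  X <- g$genotypes
  n <- nrow(X); L <- ncol(X)
  if (n < 3L) stop("need >= 3 individuals")
  px <- pair_index(n)
  P <- length(px$i)
  num <- matrix(0, P, L); den <- matrix(0, P, L)
  typed <- !is.na(X)
  for (l in seq_len(L)) {
    tl <- typed[, l]
    nl <- sum(tl)
    if (nl < 2L) next
    p <- X[, l] / 2
    pbar <- mean(p[tl])
    pq <- pbar * (1 - pbar)
    if (pq == 0) next                     # monomorphic: no information
    dev <- p - pbar
    ct <- tl[px$i] & tl[px$j]
    num[ct, l] <- 2 * (dev[px$i][ct] * dev[px$j][ct] + pq / (nl - 1))
    den[ct, l] <- 2 * pq
  }
  d <- pair_distances(rownames(X)[px$i], rownames(X)[px$j], map)
  new_pair_metric_table(rownames(X), px, "loiselle_F", num, den, d,
                        colnames(X))
}

#' Rousset's a-hat genetic distance between individuals
#'
#' Built from probabilities of allele identity in state: `Qw_l` is the
#' sample-average probability that the two alleles of one individual are
#' identical (1 for homozygotes, 0 for heterozygotes), and `Qij_l` the mean
#' identity over the four cross-individual allele pairs,
#' `p_i p_j + (1 - p_i)(1 - p_j)` with `p = dosage/2`.  The multilocus
#' statistic is `sum_l (Qw_l - Qij_l) / sum_l (1 - Qw_l)` over co-typed loci
#' (ratio of sums).  `Qw` is estimated sample-wide for stability; set
#' `pair_qw = TRUE` to restrict it to the pair itself.
#'
#' @inheritParams loiselle_kinship
#' @param pair_qw use only the focal pair when estimating `Qw` (default
#'   `FALSE`: sample-wide).
#' @return A `pair_metric_table`.
#' @export
rousset_a <- function(g, map = NULL, pair_qw = FALSE) {
  X <- g$genotypes
  n <- nrow(X); L <- ncol(X)
  if (n < 3L) stop("need >= 3 individuals")
  px <- pair_index(n)
  P <- length(px$i)
  num <- matrix(0, P, L); den <- matrix(0, P, L)
  typed <- !is.na(X)
  hom <- (X != 1L)                        # within-individual identity in state
  for (l in seq_len(L)) {
    tl <- typed[, l]
    if (sum(tl) < 2L) next
    p <- X[, l] / 2
    qij <- p[px$i] * p[px$j] + (1 - p[px$i]) * (1 - p[px$j])
    ct <- tl[px$i] & tl[px$j]
    if (pair_qw) {
      qw <- (hom[px$i, l] + hom[px$j, l]) / 2
      num[ct, l] <- qw[ct] - qij[ct]
      den[ct, l] <- 1 - qw[ct]
    } else {
      qw <- mean(hom[tl, l])
      num[ct, l] <- qw - qij[ct]
      den[ct, l] <- 1 - qw
    }
  }
  d <- pair_distances(rownames(X)[px$i], rownames(X)[px$j], map)
  new_pair_metric_table(rownames(X), px, "rousset_a", num, den, d,
                        colnames(X))
}

#' Mean kinship in the first distance class
#'
#' `F(1)` is the average kinship among neighbouring pairs, used to rescale a
#' Loiselle-slope into a neighbourhood size.  The neighbour radius
#' conventionally defaults to the current sigma estimate.
#'
#' @param t a `pair_metric_table` with `metric_name = "loiselle_F"`.
#' @param neighbour_radius metres.
#' @return Mean kinship over pairs with `d <= neighbour_radius`.
#' @export
mean_kinship_first_class <- function(t, neighbour_radius) {
  if (t$metric_name != "loiselle_F")
    stop("F(1) is defined for the loiselle_F metric")
  sel <- is.finite(t$pairs$d) & t$pairs$d <= neighbour_radius
  if (!any(sel))
    stop("no pairs within ", neighbour_radius,
         " m; increase the neighbour radius")
  mean(t$pairs$value[sel])
}

## Weir-Cockerham variance components for one locus across r groups.
## Returns c(a, b, c): among-group, among-individual-within-group,
## within-individual.  For r = 1 only b and c are defined (a = 0).
wc_components <- function(dos_by_group) {
  r <- length(dos_by_group)
  n_i <- vapply(dos_by_group, function(d) sum(!is.na(d)), numeric(1))
  if (any(n_i < 1) || sum(n_i) < 2) return(c(0, 0, 0))
  p_i <- vapply(dos_by_group, function(d) mean(d, na.rm = TRUE) / 2, numeric(1))
  h_i <- vapply(dos_by_group, function(d) mean(d == 1, na.rm = TRUE), numeric(1))
  nbar <- mean(n_i)
  pbar <- sum(n_i * p_i) / (r * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  if (r == 1) {
    n <- n_i[1]
    if (n < 2) return(c(0, 0, 0))
    b <- (n / (n - 1)) * (pbar * (1 - pbar) - (2 * n - 1) / (4 * n) * hbar)
    return(c(0, b, hbar / 2))
  }
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a, b, hbar / 2)
}

#' Per-group inbreeding coefficient F_IS (Weir-Cockerham)
#'
#' Multilocus ratio-of-sums of the WC within-group variance components:
#' `F_IS = 1 - sum(c) / sum(b + c)`.  A positive `F_IS` (inbreeding/selfing)
#' is the standard ground for preferring Loiselle's F over Rousset's a-hat in
#' IbD regressions.  With `jackknife = TRUE`, a delete-one-locus 95% CI is
#' attached.
#'
#' @param g a [genotype_table()].
#' @param groups per-individual group labels (e.g. sampling locations).
#' @param jackknife compute delete-one-locus CIs (default `TRUE`).
#' @return data.frame with one row per group: `group`, `n`, `fis`, and with
#'   jackknife also `ci_low`, `ci_high`.  Monomorphic groups get `NA`.
#' @export
fis <- function(g, groups, jackknife = TRUE) {
  groups <- as.character(rep_len(groups, nrow(g$genotypes)))
  out <- lapply(unique(groups), function(grp) {
    sel <- which(groups == grp)
    if (length(sel) < 2L)
      return(data.frame(group = grp, n = length(sel), fis = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    X <- g$genotypes[sel, , drop = FALSE]
    comp <- vapply(seq_len(ncol(X)),
                   function(l) wc_components(list(X[, l])), numeric(3))
    bs <- comp[2, ]; cs <- comp[3, ]
    tot <- bs + cs
    f <- if (sum(tot) > 0) 1 - sum(cs) / sum(tot) else NA_real_
    lo <- hi <- NA_real_
    if (jackknife && is.finite(f) && ncol(X) >= 2) {
      fl <- vapply(seq_along(bs), function(l) {
        denom <- sum(tot) - tot[l]
        if (denom > 0) 1 - (sum(cs) - cs[l]) / denom else NA_real_
      }, numeric(1))
      fl <- fl[is.finite(fl)]
      if (length(fl) >= 2) {
        Lh <- length(fl)
        se <- sqrt((Lh - 1) / Lh * sum((fl - mean(fl))^2))
        lo <- f - 1.96 * se; hi <- f + 1.96 * se
      }
    }
    data.frame(group = grp, n = length(sel), fis = f,
               ci_low = lo, ci_high = hi)
  })
  do.call(rbind, out)
}

#' Pairwise F_ST between groups (Weir-Cockerham theta)
#'
#' Multilocus ratio of sums of the WC84 variance components:
#' `theta = sum(a) / sum(a + b + c)` over loci.
#'
#' @inheritParams fis
#' @return Symmetric matrix of pairwise theta (diagonal 0); `NA` when a group
#'   pair shares no polymorphic locus.
#' @export
fst_wc <- function(g, groups) {
  groups <- as.character(rep_len(groups, nrow(g$genotypes)))
  gl <- unique(groups)
  if (length(gl) < 2L) stop("need >= 2 groups")
  th <- matrix(0, length(gl), length(gl), dimnames = list(gl, gl))
  for (u in seq_along(gl)) for (v in seq_len(u - 1L)) {
    s1 <- which(groups == gl[u]); s2 <- which(groups == gl[v])
    comp <- vapply(seq_len(ncol(g$genotypes)), function(l)
      wc_components(list(g$genotypes[s1, l], g$genotypes[s2, l])),
      numeric(3))
    tot <- colSums(comp)
    th[u, v] <- th[v, u] <-
      if (sum(tot) > 0) sum(comp[1, ]) / sum(tot) else NA_real_
  }
  th
}
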