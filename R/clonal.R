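#' Pairwise shared-allele (clonal) genetic distance
#'
#' Prevosti-type distance on allele dosages: for a pair of individuals the
#' per-locus similarity is `1 - |d_i - d_j| / 2` and the distance is one minus
#' the mean similarity over co-typed loci, i.e. `sum|d_i - d_j| / (2 * L_ij)`.
#' Identical genotypes give 0, opposite homozygotes at every locus give 1.
#' Pairs with no co-typed loci get `NA` with a warning.
#'
#' @param g a [genotype_table()] with at least 2 individuals.
#' @return Symmetric matrix in `[0, 1]` with zero diagonal and an
#'   `"n_cotyped"` attribute (matrix of co-typed locus counts).
#' @export
clonal_distance <- function(g) {
  X <- g$genotypes
  if (nrow(X) < 2L) stop("need >= 2 individuals")
  typed <- !is.na(X)
  I <- lapply(0:2, function(v) {
    m <- (X == v) & typed
    storage.mode(m) <- "double"
    m
  })
  C <- tcrossprod(typed * 1)                     # co-typed locus counts
  S01 <- I[[1]] %*% t(I[[2]]); S12 <- I[[2]] %*% t(I[[3]])
  S02 <- I[[1]] %*% t(I[[3]])
  S <- S01 + t(S01) + S12 + t(S12) + 2 * (S02 + t(S02))  # sum |d_i - d_j|
  D <- S / (2 * C)
  diag(D) <- 0
  if (any(C == 0 & upper.tri(C)))
    warning(sum(C == 0 & upper.tri(C)),
            " pair(s) share no co-typed loci; distance set NA")
  D[C == 0] <- NA
  diag(D) <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  attr(D, "n_cotyped") <- C
  D
}

## id pairs (2-col matrix) of technical replicates from a genotype table
replicate_pairs <- function(g) {
  rg <- g$replicate_group
  if (is.null(rg)) return(matrix(character(), ncol = 2))
  ids <- individual_ids(g)
  grp <- split(ids, rg)
  grp <- grp[lengths(grp) > 1]
  if (!length(grp)) return(matrix(character(), ncol = 2))
  do.call(rbind, lapply(grp, function(v) t(utils::combn(v, 2))))
}

#' Calibrate the clone-calling distance threshold on technical replicates
#'
#' Replicate-pair distances bound the combined sequencing-error plus
#' somatic-mutation scale.  If every non-replicate distance exceeds the
#' largest replicate distance (a clean gap), the threshold is the midpoint
#' between that maximum and the smallest non-replicate distance.  If the two
#' distributions overlap, the 95th percentile of replicate distances is used
#' with a warning.
#'
#' @param dists matrix from [clonal_distance()].
#' @param rep_pairs two-column matrix of technical-replicate id pairs (e.g.
#'   from a genotype table's `replicate_group`).
#' @param min_cotyped_frac pairs co-typed at less than this fraction of loci
#'   are excluded from calibration (unstable distances).
#' @return Numeric threshold with attribute `"rule"` (`"gap"` or
#'   `"quantile"`).
#' @export
calibrate_threshold <- function(dists, rep_pairs, min_cotyped_frac = 0.2) {
  rep_pairs <- as.matrix(rep_pairs)
  if (nrow(rep_pairs) < 1L)
    stop("no technical-replicate pairs: supply a manual threshold to ",
         "call_clones()")
  L <- max(attr(dists, "n_cotyped"), 1)
  ok <- attr(dists, "n_cotyped") >= min_cotyped_frac * L
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  repkey <- key(rep_pairs[, 1], rep_pairs[, 2])
  idx <- which(upper.tri(dists) & ok & !is.na(dists), arr.ind = TRUE)
  allkey <- key(rownames(dists)[idx[, 1]], colnames(dists)[idx[, 2]])
  vals <- dists[idx]
  is_rep <- allkey %in% repkey
  rep_d <- vals[is_rep]
  nonrep_d <- vals[!is_rep]
  if (!length(rep_d)) stop("replicate pairs excluded by co-typing filter")
  m <- max(rep_d)
  if (length(nonrep_d) && min(nonrep_d) > m) {
    thr <- (m + min(nonrep_d)) / 2
    attr(thr, "rule") <- "gap"
  } else {
    warning("replicate and non-replicate distances overlap; using 95th ",
            "percentile of replicate distances")
    thr <- unname(quantile(rep_d, 0.95, type = 7))
    attr(thr, "rule") <- "quantile"
  }
  thr
}

#' Group colonies into genets (clonal lineages)
#'
#' Single-linkage clustering: genets are connected components of the graph
#' linking pairs at or below the distance threshold.  Technical replicates are
#' always co-grouped.  One representative per genet (lowest missing data, ties
#' broken by id order) is flagged for downstream analyses.
#'
#' @param dists matrix from [clonal_distance()].
#' @param threshold distance threshold (from [calibrate_threshold()] or user
#'   supplied).
#' @param map optional [colony_map()]; when given, spatial distances between
#'   within-genet colony pairs are recorded.
#' @param missingness optional named per-individual missing-data fraction
#'   (defaults to 0 for all).
#' @param replicate_group optional named per-individual replicate labels;
#'   replicate samples of one colony are collapsed when counting colonies.
#' @return A `clone_assignment` list: `threshold`, `genet_id` (named integer),
#'   `representative` (named logical), `Ng`, `N`, `Ng_over_N`,
#'   `clone_pair_distances` (metres).
#' @export
call_clones <- function(dists, threshold, map = NULL, missingness = NULL,
                        replicate_group = NULL) {
  ids <- rownames(dists)
  n <- length(ids)
  if (is.null(missingness)) missingness <- setNames(numeric(n), ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  idx <- which(upper.tri(dists) & !is.na(dists) & dists <= threshold,
               arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) union2(idx[k, 1], idx[k, 2])
  if (!is.null(replicate_group)) {
    for (v in split(seq_len(n), replicate_group[ids])) {
      if (length(v) > 1) for (k in v[-1]) union2(v[1], k)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  genet_id <- match(roots, unique(roots))
  names(genet_id) <- ids

  miss <- missingness[ids]
  miss[is.na(miss)] <- 0
  representative <- setNames(logical(n), ids)
  for (gid in unique(genet_id)) {
    members <- which(genet_id == gid)
    representative[members[order(miss[members],
                                 match(ids[members], ids))][1]] <- TRUE
  }

  # colonies: technical replicates of one colony collapse to one ramet
  colony_key <- ids
  if (!is.null(replicate_group)) {
    rg <- replicate_group[ids]
    colony_key <- ifelse(is.na(rg) | rg == "", ids, paste0("rep:", rg))
  }
  N <- length(unique(colony_key))
  Ng <- length(unique(genet_id[!duplicated(colony_key)]))

  clone_pair_distances <- numeric(0)
  if (!is.null(map)) {
    m <- map[match(ids, map$id), , drop = FALSE]
    for (gid in unique(genet_id)) {
      members <- which(genet_id == gid & !is.na(m$x))
      members <- members[!duplicated(colony_key[members])]
      if (length(members) > 1) {
        xy <- cbind(m$x[members], m$y[members])
        clone_pair_distances <- c(clone_pair_distances,
                                  as.numeric(stats::dist(xy)))
      }
    }
  }
  structure(list(threshold = as.numeric(threshold), genet_id = genet_id,
                 representative = representative, Ng = Ng, N = N,
                 Ng_over_N = Ng / N,
                 clone_pair_distances = clone_pair_distances),
            class = "clone_assignment")
}

#' @export
print.clone_assignment <- function(x, ...) {
  cat("clone_assignment: Ng =", x$Ng, "genets among N =", x$N,
      sprintf("colonies (Ng:N = %.2f), threshold %.4g\n",
              x$Ng_over_N, x$threshold))
  invisible(x)
}

#' Summarise the spatial spread of clones
#'
#' @param assign a `clone_assignment` from [call_clones()] built with a
#'   colony map.
#' @return List with the clone-pair distance vector, `median`,
#'   `frac_within_1m` and `n_pairs`; an empty summary (flagged by
#'   `n_pairs = 0`) when no multi-colony genet exists.
#' @export
clonal_spatial_summary <- function(assign) {
  d <- assign$clone_pair_distances
  if (!length(d)) {
    return(list(distances = numeric(0), median = NA_real_,
                frac_within_1m = NA_real_, n_pairs = 0L))
  }
  list(distances = d, median = median(d), frac_within_1m = mean(d <= 1),
       n_pairs = length(d))
}
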