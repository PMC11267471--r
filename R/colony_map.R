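#' Construct or read a colony coordinate map
#'
#' A `colony_map` records, for each genotyped colony, its location (shore
#' site), plot, and metre-scaled coordinates.  Convention: right-handed axes
#' in metres, x increasing along shore between locations, y along the long
#' (25 m) plot axis, z = depth (>= 0).
#'
#' @param df data.frame with columns `id`, `location`, `plot`, `x`, `y`, `z`.
#' @return An object of classes `colony_map` and `data.frame`.
#' @export
colony_map <- function(df) {
  need <- c("id", "location", "plot", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("duplicate colony id: ", df$id[duplicated(df$id)][1])
  for (cc in c("x", "y", "z")) {
    v <- df[[cc]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("non-finite or non-numeric coordinate in column ", cc,
           if (is.numeric(v)) paste0(", row ", which(!is.finite(v))[1]))
  }
  if (any(df$z < 0)) stop("z (depth) must be >= 0, row ",
                          which(df$z < 0)[1])
  class(df) <- c("colony_map", "data.frame")
  df
}

#' @rdname colony_map
#' @param path path to a tab-separated file with a header row naming the six
#'   required columns.
#' @param genotype_ids optional character vector of genotyped individual ids;
#'   a warning lists genotyped ids that lack coordinates.
#' @export
read_colony_map <- function(path, genotype_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  for (cc in intersect(c("x", "y", "z"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v) && !anyNA(df[[cc]]))
      stop("non-numeric coordinate in column ", cc, ", row ",
           which(is.na(v))[1])
    df[[cc]] <- v
  }
  m <- colony_map(df)
  if (!is.null(genotype_ids)) {
    lost <- setdiff(genotype_ids, m$id)
    if (length(lost))
      warning(length(lost), " genotyped individual(s) lack coordinates and ",
              "are excluded from spatial analyses: ",
              paste(utils::head(lost, 5), collapse = ", "),
              if (length(lost) > 5) ", ...")
  }
  m
}

#' Apply per-plot affine transforms to colony coordinates
#'
#' Each plot is reconstructed in its own local frame; this operation scales,
#' rotates (about the z axis, degrees counter-clockwise) and translates each
#' plot into the common metre-scaled frame.
#'
#' @param map a [colony_map()].
#' @param transforms named list (one entry per plot) of lists with elements
#'   `scale` (positive scalar, default 1), `rotation` (degrees, default 0) and
#'   `translation` (length-3 numeric, default `c(0, 0, 0)`).  May also be a
#'   path to a YAML file with the same structure.
#' @return The transformed `colony_map`.
#' @export
transform_coordinates <- function(map, transforms) {
  if (is.character(transforms)) transforms <- yaml::read_yaml(transforms)
  plots <- unique(as.character(map$plot))
  miss <- setdiff(plots, names(transforms))
  if (length(miss)) stop("missing transform for plot(s): ",
                         paste(miss, collapse = ", "))
  for (p in plots) {
    tr <- transforms[[p]]
    s <- if (is.null(tr$scale)) 1 else tr$scale
    if (s <= 0) stop("scale must be > 0 for plot ", p)
    th <- (if (is.null(tr$rotation)) 0 else tr$rotation) * pi / 180
    tl <- if (is.null(tr$translation)) c(0, 0, 0) else as.numeric(tr$translation)
    i <- map$plot == p
    x <- map$x[i] * s; y <- map$y[i] * s; z <- map$z[i] * s
    map$x[i] <- cos(th) * x - sin(th) * y + tl[1]
    map$y[i] <- sin(th) * x + cos(th) * y + tl[2]
    map$z[i] <- z + tl[3]
  }
  map
}

## Orthogonal projection of each plot's points onto its best-fit plane
## (total least squares via PCA), keeping the common frame; degenerate plots
## (< 3 points) are left untouched.
flatten_plot_planes <- function(map) {
  for (p in unique(map$plot)) {
    i <- which(map$plot == p)
    if (length(i) < 3L) next
    xyz <- cbind(map$x[i], map$y[i], map$z[i])
    ctr <- colMeans(xyz)
    pc <- tryCatch(prcomp(xyz, center = TRUE, scale. = FALSE),
                   error = function(e) NULL)
    if (is.null(pc) || ncol(pc$rotation) < 3L) next
    nrml <- pc$rotation[, 3]
    dev <- as.numeric(sweep(xyz, 2, ctr) %*% nrml)
    proj <- xyz - outer(dev, nrml)
    map$x[i] <- proj[, 1]; map$y[i] <- proj[, 2]; map$z[i] <- proj[, 3]
  }
  map
}

#' Pairwise 2D geographic distances within locations
#'
#' Computes Euclidean distances between colony centroids after projecting
#' each plot onto its best-fit plane and dropping the vertical component
#' (the 2D flattening used when depth carries no genetic signal).
#' Cross-location pairs are excluded; same-location, different-plot pairs are
#' retained.  Coincident distinct colonies are floored at `min_distance` with
#' a warning.
#'
#' @param map a [colony_map()] in the common frame.
#' @param min_distance distance floor in metres (default 0.01).
#' @param flatten project plots onto their best-fit planes first (default
#'   `TRUE`).
#' @return data.frame with columns `i`, `j` (ids, i < j lexicographically in
#'   file order), `location`, `d` (metres).
#' @export
pairwise_distance_2d <- function(map, min_distance = 0.01, flatten = TRUE) {
  if (flatten) map <- flatten_plot_planes(map)
  out <- vector("list", 0L)
  for (loc in unique(map$location)) {
    i <- which(map$location == loc)
    if (length(i) < 2L) next
    xy <- cbind(map$x[i], map$y[i])
    dmat <- as.matrix(stats::dist(xy))
    ut <- which(upper.tri(dmat), arr.ind = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      i = map$id[i][ut[, 1]], j = map$id[i][ut[, 2]],
      location = loc, d = dmat[ut], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(i = character(), j = character(),
                      location = character(), d = numeric()))
  res <- do.call(rbind, out)
  low <- res$d < min_distance
  if (any(low)) {
    warning(sum(low), " coincident/near-coincident pair(s) floored at ",
            min_distance, " m")
    res$d[low] <- min_distance
  }
  rownames(res) <- NULL
  res
}
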