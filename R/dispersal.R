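## Neighbourhood-size -> sigma conversion and Monte-Carlo uncertainty
## propagation.  Wright's genetic neighbourhood for a 2D population is
## NS = 4*pi*D*sigma^2, the effective number of individuals within a circle
## of radius 2*sigma; an IbD slope gives NS and an independent density D then
## gives sigma = sqrt(NS / (4*pi*D)).

#' Neighbourhood size from a Rousset a-hat IbD slope
#'
#' `NS = 1/b`.  A non-positive slope is inconsistent with IbD for a genetic
#' distance; the neighbourhood is then undefined and `Inf` is returned as a
#' sentinel (never silently dropped).
#'
#' @param b IbD slope of a-hat on ln(distance).
#' @return Neighbourhood size (individuals), or `Inf` when `b <= 0`.
#' @export
ns_from_rousset <- function(b) {
  ifelse(is.finite(b) & b > 0, 1 / b, Inf)
}

#' Neighbourhood size from a Loiselle kinship IbD slope
#'
#' Kinship decays with ln(distance) under IbD, so `b < 0` is expected and
#' `NS = (1 - F1) / (-b)` (the standard Sp-statistic form).  The
#' literal-printed alternative `NS = 1 / (-b * (1 - F1))` is available behind
#' `literal_eq23`.  A non-negative slope returns the `Inf` sentinel.
#'
#' @param b IbD slope of Loiselle's F on ln(distance).
#' @param F1 mean kinship among neighbours (first distance class), in
#'   `[0, 1)`.
#' @param literal_eq23 use the division form (default `FALSE`).
#' @return Neighbourhood size, or `Inf` when `b >= 0`.
#' @export
ns_from_loiselle <- function(b, F1, literal_eq23 = FALSE) {
  if (any(F1 >= 1)) stop("F1 must be < 1")
  ns <- if (literal_eq23) 1 / (-b * (1 - F1)) else (1 - F1) / (-b)
  ifelse(is.finite(b) & b < 0, ns, Inf)
}

#' Construct a density estimate
#'
#' Wraps a per-area density (individuals per m^2) with its confidence
#' interval.  Usually produced by [census_density()] or
#' [effective_density()]; the direct constructor serves when only published
#' central values and intervals are available.
#'
#' @param kind `"census"` or `"effective"`.
#' @param central point density (> 0), individuals per m^2.
#' @param ci length-2 confidence interval containing `central`.
#' @param area_m2 area the density refers to (optional).
#' @param plot_densities optional named per-plot densities (kept for
#'   resampling).
#' @param source free-text provenance note.
#' @return A `density_estimate`.
#' @export
density_estimate <- function(kind, central, ci, area_m2 = NA_real_,
                             plot_densities = NULL, source = NA_character_) {
  stopifnot(central > 0, ci[1] <= central, central <= ci[2])
  structure(list(kind = kind, central = central, ci_low = ci[1],
                 ci_high = ci[2], area_m2 = area_m2,
                 plot_densities = plot_densities, source = source),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("density_estimate (%s): %.3g (%.3g-%.3g) m^-2\n",
              x$kind, x$central, x$ci_low, x$ci_high))
  invisible(x)
}

#' Census density of genets from plot counts
#'
#' The census density approximates the density of multilocus genotypes:
#' clones are counted once per plot.  The central value pools genets over the
#' total area; the interval is the spread (min-max) of the per-plot
#' densities, which are retained for resampling.
#'
#' @param assign a `clone_assignment` from [call_clones()].
#' @param map a [colony_map()] giving each colony's plot.
#' @param plot_areas named numeric vector of plot areas in m^2.
#' @return A `density_estimate` of kind `"census"`.
#' @export
census_density <- function(assign, map, plot_areas) {
  if (any(plot_areas <= 0)) stop("plot areas must be > 0")
  ids <- names(assign$genet_id)
  plot_of <- map$plot[match(ids, map$id)]
  keep <- !is.na(plot_of)
  tab <- tapply(assign$genet_id[keep], plot_of[keep],
                function(v) length(unique(v)))
  plots <- names(tab)
  miss <- setdiff(plots, names(plot_areas))
  if (length(miss)) stop("no area for plot(s): ", paste(miss, collapse = ", "))
  dens <- as.numeric(tab) / plot_areas[plots]
  central <- sum(tab) / sum(plot_areas[plots])
  ci <- if (length(dens) > 1) range(dens) else c(central, central)
  density_estimate("census", central, ci, area_m2 = sum(plot_areas[plots]),
                   plot_densities = setNames(dens, plots),
                   source = "plot genet counts")
}

#' Effective density from an externally estimated N_e
#'
#' Divides a contemporary effective population size (e.g. a sibship-method
#' estimate) and its CI by the spatial area covered by the individuals.
#'
#' @param Ne_central point estimate of N_e (> 0).
#' @param Ne_CI length-2 CI for N_e.
#' @param area_m2 area in m^2 (> 0).
#' @return A `density_estimate` of kind `"effective"`.
#' @export
effective_density <- function(Ne_central, Ne_CI, area_m2) {
  if (Ne_central <= 0) stop("N_e must be > 0")
  if (area_m2 <= 0) stop("area must be > 0")
  density_estimate("effective", Ne_central / area_m2,
                   sort(Ne_CI / area_m2), area_m2 = area_m2,
                   source = "external N_e")
}

#' Point estimate of sigma from neighbourhood size and density
#'
#' `sigma = sqrt(NS / (4 * pi * D))` metres.  The `Inf` neighbourhood
#' sentinel propagates to an `Inf` sigma.
#'
#' @param NS neighbourhood size.
#' @param D density in individuals per m^2.
#' @return sigma in metres.
#' @export
sigma_point <- function(NS, D) {
  stopifnot(all(D > 0))
  sqrt(NS / (4 * pi * D))
}

#' Mean Euclidean dispersal distance under a Gaussian kernel
#'
#' For a Gaussian dispersal kernel sigma equals 1.25 times the mean Euclidean
#' parent-offspring distance, so the mean distance is `sigma / 1.25`.
#'
#' @param sigma generational dispersal distance (m).
#' @return Mean Euclidean dispersal distance (m).
#' @export
mean_dispersal_distance <- function(sigma) sigma / 1.25

#' Two-piece lognormal sampler matched to a central value and CI
#'
#' Positive, asymmetric-interval parameter distributions (neighbourhood size,
#' density) are represented by a lognormal with different log-scale standard
#' deviations below and above the median, matched exactly at the median and
#' both CI endpoints.
#'
#' @param n number of draws.
#' @param central median (> 0).
#' @param ci length-2 CI (defaults to a 95% interval).
#' @param level CI coverage used for the match (default 0.95).
#' @return `n` draws.
#' @export
rtwo_piece_lognormal <- function(n, central, ci, level = 0.95) {
  stopifnot(central > 0, ci[1] > 0, ci[1] <= central, central <= ci[2])
  z <- qnorm(1 - (1 - level) / 2)
  s_lo <- (log(central) - log(ci[1])) / z
  s_hi <- (log(ci[2]) - log(central)) / z
  zz <- rnorm(n)
  exp(log(central) + ifelse(zz < 0, s_lo, s_hi) * zz)
}

#' Iterative spatial-scale adjustment of the IbD window and sigma
#'
#' IbD slopes reflect recent dispersal only within the migration-drift
#' equilibrium window, roughly sigma to 10-50 sigma.  Starting from the full
#' within-location window, the fit and sigma are recomputed with the window
#' reset to `[sigma, k_max * sigma]` until sigma changes by less than 5%
#' (relative) or 20 iterations.  For the Loiselle metric, `F(1)` is
#' re-evaluated at each iteration as the mean kinship within the current
#' sigma.  A window that collapses below 3 pairs, or a slope inconsistent
#' with IbD, stops the loop with the `"scale-unresolved"` flag.
#'
#' @param t a `pair_metric_table` with distances.
#' @param D a `density_estimate`.
#' @param k_max upper window multiple (default 20, sensible range 10-50).
#' @param max_iter maximum iterations (default 20).
#' @param tol relative sigma convergence tolerance (default 0.05).
#' @param literal_eq23 passed to [ns_from_loiselle()].
#' @return List: `fit` (final `ibd_fit`), `sigma`, `NS`, `F1`, `converged`,
#'   `flag` (`NA` or `"scale-unresolved"`), `history` (one row per
#'   iteration).
#' @export
iterate_sigma <- function(t, D, k_max = 20, max_iter = 20L, tol = 0.05,
                          literal_eq23 = FALSE) {
  if (k_max < 10 || k_max > 50)
    warning("k_max outside the supported 10-50 range")
  d <- t$pairs$d
  full <- range(d[is.finite(d)])
  history <- NULL
  window <- full
  sigma_old <- NA_real_
  last <- NULL
  flag <- NA_character_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fit <- tryCatch(fit_ibd(t, window), error = function(e) NULL)
    if (is.null(fit)) { flag <- "scale-unresolved"; break }
    F1 <- NA_real_
    if (t$metric_name == "rousset_a") {
      NS <- ns_from_rousset(fit$slope)
    } else {
      F1 <- if (is.na(sigma_old)) 0 else
        tryCatch(mean_kinship_first_class(t, sigma_old),
                 error = function(e) 0)
      NS <- ns_from_loiselle(fit$slope, max(F1, 0), literal_eq23)
    }
    if (!is.finite(NS)) { flag <- "scale-unresolved"; break }
    sigma <- sigma_point(NS, D$central)
    history <- rbind(history,
                     data.frame(iter = it, d_min = window[1],
                                d_max = window[2], n_pairs = fit$n_pairs,
                                slope = fit$slope, F1 = F1, NS = NS,
                                sigma = sigma))
    last <- list(fit = fit, sigma = sigma, NS = NS, F1 = F1)
    if (!is.na(sigma_old) && abs(sigma - sigma_old) / sigma_old < tol) {
      converged <- TRUE
      break
    }
    sigma_old <- sigma
    window <- c(sigma, k_max * sigma)
    window[1] <- max(window[1], full[1])
    if (window[2] <= window[1]) { flag <- "scale-unresolved"; break }
  }
  if (is.null(last)) {
    return(list(fit = NULL, sigma = NA_real_, NS = NA_real_, F1 = NA_real_,
                converged = FALSE, flag = "scale-unresolved",
                history = history))
  }
  c(last, list(converged = converged, flag = flag, history = history))
}

#' Monte-Carlo distribution of sigma
#'
#' Propagates uncertainty in the neighbourhood size and in density to a
#' probability distribution of sigma by drawing `n_draws` independent
#' (NS, D) pairs and computing `sigma = sqrt(NS / (4 * pi * D))`.
#'
#' Neighbourhood draws come either from locus-bootstrap slope draws (an
#' `ibd_fit` from [bootstrap_ci_loci()], keeping the slope-to-NS dependence
#' exact) or from a printed `(central, CI)` triple via a two-piece lognormal.
#' Density draws resample per-plot census densities when available, otherwise
#' a two-piece lognormal matched to the density CI.  Draws whose slope is
#' inconsistent with IbD give an undefined (infinite) NS; such draws are
#' truncated out and counted, and the result is flagged when they exceed
#' half.
#'
#' @param ns_source an `ibd_fit` with bootstrap slope draws, or a numeric
#'   `c(central, lo, hi)` triple for NS.
#' @param D a `density_estimate`.
#' @param n_draws number of Monte-Carlo draws (default 2000).
#' @param seed integer RNG seed.
#' @param F1 mean neighbour kinship, required when `ns_source` is a Loiselle
#'   fit.
#' @param literal_eq23 passed to [ns_from_loiselle()].
#' @param use_plot_densities resample per-plot census densities when present
#'   (default `TRUE`).
#' @return A `sigma_estimate`: `draws` (finite sigma draws), `median`,
#'   `pi_90` (5th-95th percentile), `n_draws`, `n_nonfinite`, `seed`,
#'   `density_kind`, `metric`, `flag`.
#' @export
sigma_distribution <- function(ns_source, D, n_draws = 2000L, seed = 1L,
                               F1 = 0, literal_eq23 = FALSE,
                               use_plot_densities = TRUE) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  metric <- NA_character_
  if (inherits(ns_source, "ibd_fit")) {
    slopes <- attr(ns_source, "slope_draws")
    if (is.null(slopes))
      stop("ibd_fit carries no bootstrap slope draws; run bootstrap_ci_loci()")
    metric <- ns_source$metric_name
    b <- sample(slopes, n_draws, replace = TRUE)
    NS <- if (metric == "rousset_a") ns_from_rousset(b)
          else ns_from_loiselle(b, F1, literal_eq23)
  } else {
    stopifnot(is.numeric(ns_source), length(ns_source) == 3)
    NS <- rtwo_piece_lognormal(n_draws, ns_source[1], ns_source[2:3])
  }
  Dd <- if (!is.null(D$plot_densities) && use_plot_densities &&
            length(D$plot_densities) > 1)
    sample(D$plot_densities, n_draws, replace = TRUE)
  else rtwo_piece_lognormal(n_draws, D$central, c(D$ci_low, D$ci_high))
  s <- sigma_point(NS, Dd)
  finite <- is.finite(s)
  flag <- if (mean(!finite) > 0.5) "slope indistinguishable from 0" else NA_character_
  draws <- s[finite]
  structure(list(draws = draws,
                 median = if (length(draws)) median(draws) else NA_real_,
                 pi_90 = if (length(draws))
                   unname(quantile(draws, c(0.05, 0.95), type = 7))
                 else c(NA_real_, NA_real_),
                 n_draws = n_draws, n_nonfinite = sum(!finite), seed = seed,
                 density_kind = D$kind, metric = metric, flag = flag),
            class = "sigma_estimate")
}

#' @export
print.sigma_estimate <- function(x, ...) {
  cat(sprintf("sigma_estimate: median %.3g m (90%% PI %.3g-%.3g), %d/%d finite draws\n",
              x$median, x$pi_90[1], x$pi_90[2],
              x$n_draws - x$n_nonfinite, x$n_draws))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}
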