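#' Fit an isolation-by-distance regression
#'
#' Ordinary least squares of a pairwise genetic metric on the natural log of
#' geographic distance, `metric = a + b * ln(d)`, over pairs inside a distance
#' window.  Under 2D IbD the Rousset a-hat slope is positive and the Loiselle
#' kinship slope negative.  Confidence intervals must come from locus
#' resampling ([bootstrap_ci_loci()], [jackknife_ci_loci()]): pairs share
#' individuals, so pair-level OLS standard errors are invalid and are not
#' reported.
#'
#' @param t a `pair_metric_table` with distances attached.
#' @param window numeric `c(d_min, d_max)` in metres; `NULL` uses all pairs
#'   with a finite distance.
#' @return An `ibd_fit` list: `metric_name`, `slope`, `intercept`, `window`,
#'   `n_pairs`, and CI fields filled by the resampling functions.
#' @export
fit_ibd <- function(t, window = NULL) {
  d <- t$pairs$d
  sel <- is.finite(d) & is.finite(t$pairs$value)
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] < window[2])
    sel <- sel & d >= window[1] & d <= window[2]
  }
  if (sum(sel) < 3L) stop("fewer than 3 pairs in the distance window")
  ld <- log(d[sel])
  if (var(ld) == 0) stop("zero variance in ln(distance)")
  fit <- lm(t$pairs$value[sel] ~ ld)
  structure(list(metric_name = t$metric_name,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 window = if (is.null(window)) range(d[sel]) else window,
                 n_pairs = sum(sel),
                 ci_low = NA_real_, ci_high = NA_real_, ci_method = NA_character_,
                 significant = NA),
            class = "ibd_fit")
}

#' @export
print.ibd_fit <- function(x, ...) {
  cat(sprintf("ibd_fit (%s): b = %.5g, a = %.5g over [%.3g, %.3g] m (%d pairs)\n",
              x$metric_name, x$slope, x$intercept, x$window[1], x$window[2],
              x$n_pairs))
  if (!is.na(x$ci_method))
    cat(sprintf("  95%% CI (%s): [%.5g, %.5g]%s\n", x$ci_method,
                x$ci_low, x$ci_high,
                if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

## slope of metric on ln(d) recomputed from per-locus contributions under
## locus weights W (L x B matrix of resample counts); returns B slopes
slopes_under_weights <- function(t, sel, ld, W) {
  num <- t$num[sel, , drop = FALSE] %*% W
  den <- t$den[sel, , drop = FALSE] %*% W
  V <- num / den
  xc <- ld - mean(ld)
  wx <- xc / sum(xc^2)
  drop(crossprod(wx, V))                  # per-column OLS slope
}

#' Locus-bootstrap confidence interval for the IbD slope
#'
#' Resamples loci with replacement, rebuilds every pair value by
#' ratio-of-sums from the cached per-locus contributions, refits the
#' regression and takes the percentile 95% interval of the bootstrap slopes
#' (the package's stand-in for GENEPOP-style ABC intervals, whose
#' acceleration constants are not reconstructable).  Deterministic for a
#' fixed seed.  Resamples in which some pair's denominator collapses to zero
#' are discarded and counted.
#'
#' @inheritParams fit_ibd
#' @param n_boot number of bootstrap resamples (default 1000; < 100 warns).
#' @param seed integer RNG seed.
#' @return The `ibd_fit` with `ci_low`/`ci_high`, `ci_method =
#'   "bootstrap_loci"`, `significant`, and attributes `"slope_draws"` (kept
#'   draws) and `"n_discarded"`.
#' @export
bootstrap_ci_loci <- function(t, window = NULL, n_boot = 1000L, seed = 1L) {
  if (n_boot < 100L) warning("n_boot < 100: unstable percentile interval")
  fit <- fit_ibd(t, window)
  d <- t$pairs$d
  sel <- is.finite(d) & is.finite(t$pairs$value)
  if (!is.null(window)) sel <- sel & d >= window[1] & d <= window[2]
  sel <- which(sel)
  ld <- log(d[sel])
  L <- ncol(t$num)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  draws <- matrix(sample.int(L, L * n_boot, replace = TRUE), nrow = L)
  W <- matrix(0L, L, n_boot)
  for (b in seq_len(n_boot)) W[, b] <- tabulate(draws[, b], nbins = L)
  slopes <- slopes_under_weights(t, sel, ld, W)
  bad <- !is.finite(slopes)
  if (any(bad))
    message(sum(bad), " degenerate bootstrap draw(s) discarded")
  slopes <- slopes[!bad]
  ci <- unname(quantile(slopes, c(0.025, 0.975), type = 7))
  fit$ci_low <- ci[1]; fit$ci_high <- ci[2]
  fit$ci_method <- "bootstrap_loci"
  fit$significant <- ci[1] * ci[2] > 0
  attr(fit, "slope_draws") <- slopes
  attr(fit, "n_discarded") <- sum(bad)
  fit
}

#' Delete-one-locus jackknife confidence interval for the IbD slope
#'
#' Leave-one-locus-out slopes `b_(-l)` give the jackknife standard error
#' `sqrt(((L - 1) / L) * sum((b_(-l) - mean)^2))` and a normal-theory 95% CI
#' `b +/- 1.96 * SE`.
#'
#' @inheritParams fit_ibd
#' @return The `ibd_fit` with CI fields, `ci_method = "jackknife_loci"` and
#'   attribute `"loo_slopes"`.
#' @export
jackknife_ci_loci <- function(t, window = NULL) {
  L <- ncol(t$num)
  if (L < 2L) stop("jackknife needs >= 2 loci")
  fit <- fit_ibd(t, window)
  d <- t$pairs$d
  sel <- is.finite(d) & is.finite(t$pairs$value)
  if (!is.null(window)) sel <- sel & d >= window[1] & d <= window[2]
  sel <- which(sel)
  ld <- log(d[sel])
  W <- matrix(1L, L, L)
  diag(W) <- 0L                            # column l = leave locus l out
  loo <- slopes_under_weights(t, sel, ld, W)
  loo_ok <- loo[is.finite(loo)]
  se <- sqrt((L - 1) / L * sum((loo_ok - mean(loo_ok))^2))
  fit$ci_low <- fit$slope - 1.96 * se
  fit$ci_high <- fit$slope + 1.96 * se
  fit$ci_method <- "jackknife_loci"
  fit$significant <- fit$ci_low * fit$ci_high > 0
  attr(fit, "loo_slopes") <- loo
  attr(fit, "jackknife_se") <- se
  fit
}
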