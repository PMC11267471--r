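# Shared simulation fixtures, built once per test run.

two_plots <- function() {
  data.frame(plot = c("p1", "p2"),
             xmin = c(5, 45), xmax = c(30, 70),
             ymin = c(10, 40), ymax = c(14, 44))
}

# a mid-size IbD population with known sigma, sampled in two 25 x 4 m plots
sim_ibd_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_ind = 2000, sigma_true = 3, density = 0.3,
                        n_loci = 500, generations = 50, seed = 42)
      out <- simulate_population(cfg)
      cache <<- sample_plots(out, two_plots())
    }
    cache
  }
})

# a small pair_metric_table built directly from chosen per-locus
# contributions (den = 1 per locus unless given), for exact-regression tests
toy_pair_table <- function(d, value_by_locus, metric = "rousset_a",
                           den_by_locus = NULL) {
  P <- length(d)
  L <- ncol(value_by_locus)
  if (is.null(den_by_locus)) den_by_locus <- matrix(1, P, L)
  ids <- paste0("c", seq_len(ceiling((1 + sqrt(1 + 8 * P)) / 2)))
  px <- t(utils::combn(length(ids), 2))[seq_len(P), , drop = FALSE]
  structure(list(
    pairs = data.frame(i = ids[px[, 1]], j = ids[px[, 2]], d = d,
                       value = rowSums(value_by_locus) / rowSums(den_by_locus),
                       stringsAsFactors = FALSE),
    num = value_by_locus, den = den_by_locus, metric_name = metric,
    locus_id = paste0("L", seq_len(L)), n_pairs_dropped = 0L),
    class = "pair_metric_table")
}
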