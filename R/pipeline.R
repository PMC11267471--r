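#' End-to-end taxon-to-sigma pipeline
#'
#' Runs the full analysis for one taxon: read -> filter -> thin to one SNP
#' per contig -> clone detection (threshold calibrated on technical
#' replicates) -> genet representatives -> per-location F_IS -> pairwise
#' metrics -> IbD regression with iterative spatial-scale adjustment ->
#' locus-bootstrap CI -> Monte-Carlo sigma distribution per density kind.
#' Any stage error aborts with the stage name; every stochastic stage derives
#' its seed from `cfg$seed`, so reruns reproduce outputs exactly.
#'
#' @param cfg a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{genotypes}{path to VCF/TSV, or a [genotype_table()].}
#'     \item{colony_map}{path to TSV, or a [colony_map()].}
#'     \item{replicate_map, transforms}{optional paths/objects passed to the
#'       readers.}
#'     \item{taxon}{taxon label to analyse (default: the only one present).}
#'     \item{metric}{`"rousset_a"`, `"loiselle_F"`, `"both"` (default) or
#'       `"auto"` (Loiselle when any location has significantly positive
#'       F_IS, else Rousset).}
#'     \item{window_policy}{`"iterative"` (default) or `"fixed"` with
#'       `window = c(d_min, d_max)`.}
#'     \item{k_max, n_boot, n_draws, seed}{tuning; defaults 20, 1000, 2000, 1.}
#'     \item{clone_threshold}{manual threshold when no replicates exist.}
#'     \item{plot_areas}{named vector of plot areas (m^2) for census density.}
#'     \item{Ne}{optional list `(central, ci, area_m2)` for effective
#'       density.}
#'     \item{output_dir}{optional; when set, report TSV/JSON files are
#'       written there.}
#'   }
#' @return A `pipeline_report` list with the per-stage results and a
#'   Table-style summary data.frame (`$summary`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  defaults <- list(metric = "both", window_policy = "iterative", k_max = 20,
                   n_boot = 1000L, n_draws = 2000L, seed = 1L)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  g <- stage("read_genotypes",
             if (inherits(cfg$genotypes, "genotype_table")) cfg$genotypes
             else read_genotypes(cfg$genotypes, replicate_map = cfg$replicate_map))
  map <- stage("read_colony_map",
               if (inherits(cfg$colony_map, "colony_map")) cfg$colony_map
               else read_colony_map(cfg$colony_map,
                                    genotype_ids = individual_ids(g)))
  if (!is.null(cfg$transforms))
    map <- stage("transform_coordinates",
                 transform_coordinates(map, cfg$transforms))

  taxon <- cfg$taxon
  if (is.null(taxon)) {
    taxon <- unique(g$taxon)
    if (length(taxon) > 1)
      stop("several taxa present; set cfg$taxon (one taxon per run)")
  }
  sel <- which(g$taxon == taxon)
  if (!length(sel)) stop("no individuals of taxon ", taxon)
  g <- subset_genotypes(g, ind = sel)
  message("taxon ", taxon, ": ", nrow(g$genotypes), " individuals in")

  g <- stage("filter_genotypes", filter_genotypes(g, cfg$filter %||% filter_config()))
  filter_report <- attr(g, "filter_report")
  g <- stage("thin_one_snp_per_contig",
             thin_one_snp_per_contig(g, seed = cfg$seed + 101L))
  message("filtered: ", nrow(g$genotypes), " individuals x ",
          ncol(g$genotypes), " loci")

  dists <- stage("clonal_distance", clonal_distance(g))
  rp <- replicate_pairs(g)
  threshold <- if (nrow(rp)) {
    stage("calibrate_threshold", calibrate_threshold(dists, rp))
  } else {
    if (is.null(cfg$clone_threshold))
      stop("no technical replicates: set cfg$clone_threshold")
    cfg$clone_threshold
  }
  miss <- rowMeans(is.na(g$genotypes))
  rg <- if (is.null(g$replicate_group)) NULL
        else setNames(g$replicate_group, individual_ids(g))
  clones <- stage("call_clones",
                  call_clones(dists, threshold, map = map,
                              missingness = miss, replicate_group = rg))
  message("clones: Ng = ", clones$Ng, " genets / N = ", clones$N,
          " colonies (threshold ", signif(clones$threshold, 3), ")")
  reps <- names(clones$representative)[clones$representative]
  g_rep <- subset_genotypes(g, ind = match(reps, individual_ids(g)))

  loc <- map$location[match(individual_ids(g_rep), map$id)]
  fis_tab <- stage("fis", fis(g_rep, ifelse(is.na(loc), "unknown", loc)))
  metric <- cfg$metric
  if (metric == "auto") {
    inbred <- any(fis_tab$fis > 0 & fis_tab$ci_low > 0, na.rm = TRUE)
    metric <- if (inbred) "loiselle_F" else "rousset_a"
    message("metric auto-selected: ", metric,
            if (inbred) " (significantly positive F_IS)" else "")
  }
  metrics <- if (metric == "both") c("rousset_a", "loiselle_F") else metric

  densities <- list()
  if (!is.null(cfg$plot_areas))
    densities$census <- stage("census_density",
                              census_density(clones, map,
                                             unlist(cfg$plot_areas)))
  if (!is.null(cfg$Ne))
    densities$effective <- stage("effective_density",
                                 effective_density(cfg$Ne$central,
                                                   unlist(cfg$Ne$ci),
                                                   cfg$Ne$area_m2))
  if (!length(densities)) stop("no density input: set plot_areas and/or Ne")

  results <- list()
  summary_rows <- list()
  for (mt in metrics) {
    t <- stage(mt, if (mt == "rousset_a") rousset_a(g_rep, map)
               else loiselle_kinship(g_rep, map))
    for (dk in names(densities)) {
      D <- densities[[dk]]
      it <- if (cfg$window_policy == "iterative")
        stage("iterate_sigma", iterate_sigma(t, D, k_max = cfg$k_max))
      else {
        f <- stage("fit_ibd", fit_ibd(t, cfg$window))
        F1 <- if (mt == "loiselle_F")
          mean_kinship_first_class(t, sigma_point(
            ns_from_loiselle(f$slope, 0), D$central)) else NA_real_
        NS <- if (mt == "rousset_a") ns_from_rousset(f$slope)
              else ns_from_loiselle(f$slope, max(F1, 0, na.rm = TRUE))
        list(fit = f, sigma = sigma_point(NS, D$central), NS = NS, F1 = F1,
             converged = TRUE, flag = if (is.finite(NS)) NA_character_
                                      else "scale-unresolved",
             history = NULL)
      }
      key <- paste(mt, dk, sep = ".")
      if (!is.na(it$flag) || is.null(it$fit)) {
        results[[key]] <- list(iteration = it, fit = NULL, sigma = NULL)
        summary_rows[[key]] <- data.frame(
          taxon = taxon, metric = mt, density = dk, slope = NA_real_,
          NS = NA_real_, sigma_median = NA_real_, pi5 = NA_real_,
          pi95 = NA_real_, flag = it$flag)
        next
      }
      boot <- stage("bootstrap_ci_loci",
                    bootstrap_ci_loci(t, window = it$fit$window,
                                      n_boot = cfg$n_boot,
                                      seed = cfg$seed + 7L))
      sig <- stage("sigma_distribution",
                   sigma_distribution(boot, D, n_draws = cfg$n_draws,
                                      seed = cfg$seed + 13L,
                                      F1 = max(it$F1, 0, na.rm = TRUE)))
      flag <- if (!isTRUE(boot$significant)) "slope not significant"
              else sig$flag
      results[[key]] <- list(iteration = it, fit = boot, sigma = sig)
      summary_rows[[key]] <- data.frame(
        taxon = taxon, metric = mt, density = dk, slope = boot$slope,
        NS = it$NS,
        sigma_median = if (is.na(flag)) sig$median else NA_real_,
        pi5 = if (is.na(flag)) sig$pi_90[1] else NA_real_,
        pi95 = if (is.na(flag)) sig$pi_90[2] else NA_real_,
        flag = if (is.na(flag)) "" else flag)
    }
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  report <- structure(list(config = cfg, taxon = taxon, seed = cfg$seed,
                           filter_report = filter_report, clones = clones,
                           fis = fis_tab, densities = densities,
                           results = results, summary = summary),
                      class = "pipeline_report")
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report for taxon", x$taxon, "\n")
  print(x$summary)
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(report$summary, file.path(dir, "summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(data.frame(id = names(report$clones$genet_id),
                         genet_id = report$clones$genet_id,
                         is_representative = report$clones$representative),
              file.path(dir, "genets.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  jsonlite::write_json(
    list(taxon = report$taxon, seed = report$seed,
         filter_report = report$filter_report,
         clone_threshold = report$clones$threshold,
         Ng = report$clones$Ng, N = report$clones$N,
         fis = report$fis, summary = report$summary),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}

#' Generate packaged test datasets
#'
#' Writes simulator-generated fixtures (VCF, genotype TSV, colony-map TSV and
#' a truth JSON) to `dir`.  `"tiny"` gives a seconds-scale dataset; the
#' paper-scale preset matches the magnitude of a filtered empirical RADseq
#' dataset (335 individuals, 1606 loci).  Regeneration from the same seed is
#' byte-identical.
#'
#' @param size `"tiny"` (n = 40, L = 50) or `"paper_scale"` (n = 335,
#'   L = 1606).
#' @param seed integer RNG seed.
#' @param dir output directory.
#' @param n_ind,n_loci override the preset sizes.
#' @return Named list of file paths.
#' @export
make_fixtures <- function(size = c("tiny", "paper_scale"), seed = 1L,
                          dir = tempfile("fixtures"), n_ind = NULL,
                          n_loci = NULL) {
  size <- match.arg(size)
  n <- n_ind %||% switch(size, tiny = 40L, paper_scale = 335L)
  L <- n_loci %||% switch(size, tiny = 50L, paper_scale = 1606L)
  cfg <- sim_config(n_ind = n, sigma_true = 3, density = 0.3, n_loci = L,
                    generations = if (size == "tiny") 20L else 50L,
                    error_rate = 0.005, missing_rate = 0.05,
                    n_replicate_samples = max(2L, n %/% 20L), seed = seed)
  out <- simulate_population(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                tsv = file.path(dir, "genotypes.tsv"),
                colony_map = file.path(dir, "colony_map.tsv"),
                replicate_map = file.path(dir, "replicate_map.tsv"),
                truth = file.path(dir, "truth.json"))
  write_genotypes_vcf(out$genotypes, paths$vcf)
  write_genotypes_tsv(out$genotypes, paths$tsv)
  write.table(as.data.frame(out$map), paths$colony_map, sep = "\t",
              row.names = FALSE, quote = FALSE)
  rg <- out$genotypes$replicate_group
  write.table(data.frame(id = individual_ids(out$genotypes),
                         replicate_group = ifelse(is.na(rg), "", rg)),
              paths$replicate_map, sep = "\t", row.names = FALSE,
              quote = FALSE)
  jsonlite::write_json(list(sigma_true = out$truth$sigma_true,
                            D_true = out$truth$D_true,
                            genet = as.list(out$truth$genet)),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  paths
}
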