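#' Construct a genotype table
#'
#' A `genotype_table` holds diploid biallelic SNP calls as an individuals x
#' loci matrix of allele dosages (0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = missing), together with the RAD contig of
#' each locus, optional technical-replicate labels and taxon labels per
#' individual, and an optional read-depth matrix.
#'
#' @param genotypes integer matrix (individuals x loci) with values in
#'   \{0, 1, 2, NA\}; rownames are individual ids, colnames locus ids.
#' @param contig_id character vector, one contig per locus.
#' @param replicate_group optional character vector per individual; individuals
#'   sharing a non-`NA` value are technical replicates of one colony.
#' @param taxon optional character vector per individual (default `"taxon1"`).
#' @param depth optional numeric matrix of per-call read depths, same
#'   dimensions as `genotypes`.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(genotypes, contig_id, replicate_group = NULL,
                           taxon = NULL, depth = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes); L <- ncol(genotypes)
  if (n < 1L || L < 1L) stop("genotype table needs >= 1 individual and >= 1 locus")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosage values must be 0, 1, 2 or NA")
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- paste0("ind", seq_len(n))
  if (anyDuplicated(rownames(genotypes)))
    stop("duplicate individual ids: ",
         paste(unique(rownames(genotypes)[duplicated(rownames(genotypes))]),
               collapse = ", "))
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("snp", seq_len(L))
  contig_id <- as.character(contig_id)
  if (length(contig_id) != L) stop("contig_id must have one entry per locus")
  if (anyNA(contig_id)) stop("contig_id must be defined for every locus")
  if (!is.null(replicate_group)) {
    replicate_group <- as.character(replicate_group)
    if (length(replicate_group) != n)
      stop("replicate_group must have one entry per individual")
  }
  if (is.null(taxon)) taxon <- rep("taxon1", n)
  taxon <- rep_len(as.character(taxon), n)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!all(dim(depth) == dim(genotypes)))
      stop("depth matrix dimensions must match genotypes")
  }
  structure(list(genotypes = genotypes, contig_id = contig_id,
                 replicate_group = replicate_group, taxon = taxon,
                 depth = depth),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "loci;",
      length(unique(x$contig_id)), "contigs;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$genotypes))))
  if (!is.null(x$replicate_group)) {
    nrep <- sum(table(x$replicate_group[!is.na(x$replicate_group)]) > 1)
    cat("  technical replicate groups:", nrep, "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$genotypes)

individual_ids <- function(g) rownames(g$genotypes)

## subset by individual and/or locus index, keeping metadata in step
subset_genotypes <- function(g, ind = NULL, loci = NULL) {
  if (is.null(ind)) ind <- seq_len(nrow(g$genotypes))
  if (is.null(loci)) loci <- seq_len(ncol(g$genotypes))
  genotype_table(g$genotypes[ind, loci, drop = FALSE],
                 contig_id = g$contig_id[loci],
                 replicate_group = g$replicate_group[ind],
                 taxon = g$taxon[ind],
                 depth = if (!is.null(g$depth)) g$depth[ind, loci, drop = FALSE])
}

#' Read SNP genotypes from a VCF or genotype TSV
#'
#' VCF files must contain biallelic SNPs only (records with more than one ALT
#' allele raise an error naming the record); the GT field is converted to
#' allele dosage and the CHROM field supplies the contig id.  The TSV dialect
#' is tab-separated with individuals as rows, loci as columns, dosage symbols
#' `0/1/2` and `.` for missing; a header row `id<TAB>locus...` and an optional
#' comment line `#contig<TAB>...` carrying per-locus contig ids.
#'
#' @param path path to a `.vcf` (optionally gzipped) or `.tsv` file.
#' @param replicate_map optional path to a two-column TSV (`id`,
#'   `replicate_group`) labelling technical replicates.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, replicate_map = NULL,
                           format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  g <- if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
  if (!is.null(replicate_map)) {
    rm_tab <- read.table(replicate_map, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
    if (!all(c("id", "replicate_group") %in% names(rm_tab)))
      stop("replicate map needs columns id, replicate_group")
    rg <- as.character(rm_tab$replicate_group[match(individual_ids(g),
                                                    rm_tab$id)])
    rg[!is.na(rg) & rg == ""] <- NA_character_
    g$replicate_group <- rg
  }
  g
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record(s) not supported: ",
         paste(fix[multi, "CHROM"], fix[multi, "POS"],
               sep = ":", collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1")] <- 2L
  locus_id <- paste(fix[, "CHROM"], fix[, "POS"], sep = "_")
  rownames(dos) <- locus_id
  dos <- t(dos)  # individuals x loci
  depth <- NULL
  if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    rownames(dp) <- locus_id
    depth <- t(dp)
  }
  genotype_table(dos, contig_id = fix[, "CHROM"], depth = depth)
}

read_genotypes_tsv <- function(path) {
  lines <- readLines(path)
  contig_line <- grep("^#contig\t", lines)
  header_at <- setdiff(seq_along(lines), contig_line)[1]
  header <- strsplit(lines[header_at], "\t", fixed = TRUE)[[1]]
  loci <- header[-1]
  contig <- loci
  if (length(contig_line)) {
    contig <- strsplit(lines[contig_line[1]], "\t", fixed = TRUE)[[1]][-1]
    if (length(contig) != length(loci))
      stop("parse error line ", contig_line[1],
           ": #contig row length does not match header")
  }
  body <- lines[-c(header_at, contig_line)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(header)))
    stop("parse error line ", which(nf != length(header))[1],
         ": wrong number of fields")
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate individual ids in ", path)
  vals <- do.call(rbind, lapply(parts, `[`, -1L))
  ok <- vals %in% c("0", "1", "2", ".")
  if (!all(ok)) stop("parse error: invalid dosage symbol '",
                     vals[!ok][1], "'")
  dos <- matrix(suppressWarnings(as.integer(ifelse(vals == ".", NA, vals))),
                nrow = length(ids), dimnames = list(ids, loci))
  genotype_table(dos, contig_id = contig)
}

#' Write a genotype table to the TSV dialect read by [read_genotypes()]
#'
#' @param g a [genotype_table()].
#' @param path output file path.
#' @export
write_genotypes_tsv <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(g$genotypes)), collapse = "\t"), con)
  writeLines(paste(c("#contig", g$contig_id), collapse = "\t"), con)
  sym <- ifelse(is.na(g$genotypes), ".", as.character(g$genotypes))
  writeLines(paste(rownames(g$genotypes),
                   apply(sym, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Write a genotype table as a minimal VCF v4.2
#'
#' Loci are written as biallelic SNPs (REF=A, ALT=T placeholders) with GT
#' calls derived from dosage; contig ids populate CHROM and locus index the
#' POS field within each contig.
#'
#' @inheritParams write_genotypes_tsv
#' @export
write_genotypes_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(g$genotypes)),
                   collapse = "\t"), con)
  pos <- stats::ave(seq_along(g$contig_id), g$contig_id, FUN = seq_along)
  gtsym <- c("0/0", "0/1", "1/1")
  for (l in seq_len(ncol(g$genotypes))) {
    d <- g$genotypes[, l]
    calls <- ifelse(is.na(d), "./.", gtsym[d + 1L])
    writeLines(paste(c(g$contig_id[l], pos[l], colnames(g$genotypes)[l],
                       "A", "T", ".", "PASS", ".", "GT", calls),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Genotype filtering configuration
#'
#' Defaults follow common RADseq practice for individual-based spatial
#' analyses: individuals typed at fewer than half their loci are dropped,
#' then loci with minor-allele count below 3 or missingness above
#' `max_snp_missing` are dropped.  Depth filters apply only when the table
#' carries a depth matrix.
#'
#' @param max_ind_missing maximum fraction of missing calls per individual.
#' @param min_allele_count minimum minor-allele count per locus.
#' @param max_snp_missing maximum fraction of missing calls per locus.
#' @param min_depth minimum read depth per call (optional).
#' @param max_depth_factor calls with depth above this multiple of the mean
#'   depth are set missing (optional).
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_ind_missing = 0.5, min_allele_count = 3L,
                          max_snp_missing = 0.5, min_depth = 5,
                          max_depth_factor = 3) {
  stopifnot(max_ind_missing >= 0, max_ind_missing <= 1,
            max_snp_missing >= 0, max_snp_missing <= 1,
            min_allele_count >= 1)
  structure(list(max_ind_missing = max_ind_missing,
                 min_allele_count = as.integer(min_allele_count),
                 max_snp_missing = max_snp_missing,
                 min_depth = min_depth, max_depth_factor = max_depth_factor),
            class = "filter_config")
}

#' Filter a genotype table
#'
#' Applies, in order: depth masking (only if depth is available), removal of
#' individuals with too much missing data, then removal of loci failing the
#' minor-allele-count or missingness thresholds.  The removal counts at each
#' step are attached as attribute `"filter_report"`.
#'
#' @param g a [genotype_table()].
#' @param cfg a [filter_config()].
#' @return The filtered `genotype_table` with a `filter_report` attribute.
#' @export
filter_genotypes <- function(g, cfg = filter_config()) {
  report <- list(n_ind_in = nrow(g$genotypes), n_loci_in = ncol(g$genotypes))
  if (!is.null(g$depth)) {
    mean_dp <- mean(g$depth, na.rm = TRUE)
    mask <- !is.na(g$depth) &
      (g$depth < cfg$min_depth | g$depth > cfg$max_depth_factor * mean_dp)
    report$n_calls_depth_masked <- sum(mask & !is.na(g$genotypes))
    g$genotypes[mask] <- NA_integer_
  } else {
    report$n_calls_depth_masked <- NA_integer_  # no depth: filter skipped
  }
  ind_miss <- rowMeans(is.na(g$genotypes))
  keep_ind <- ind_miss <= cfg$max_ind_missing
  report$n_ind_removed_missing <- sum(!keep_ind)
  if (!any(keep_ind)) stop("all data filtered: every individual exceeds ",
                           cfg$max_ind_missing, " missingness")
  g <- subset_genotypes(g, ind = which(keep_ind))

  alt <- colSums(g$genotypes, na.rm = TRUE)
  typed <- colSums(!is.na(g$genotypes))
  mac <- pmin(alt, 2L * typed - alt)
  loc_miss <- 1 - typed / nrow(g$genotypes)
  fail_mac <- mac < cfg$min_allele_count
  fail_miss <- loc_miss > cfg$max_snp_missing
  report$n_loci_removed_mac <- sum(fail_mac)
  report$n_loci_removed_missing <- sum(fail_miss & !fail_mac)
  keep_loc <- !(fail_mac | fail_miss)
  if (!any(keep_loc)) stop("all data filtered: no locus passes the filters")
  g <- subset_genotypes(g, loci = which(keep_loc))
  report$n_ind_out <- nrow(g$genotypes)
  report$n_loci_out <- ncol(g$genotypes)
  attr(g, "filter_report") <- report
  g
}

#' Retain one randomly chosen SNP per contig
#'
#' Removes physical linkage by keeping a single SNP per RAD contig, chosen
#' uniformly at random; deterministic for a fixed seed.
#'
#' @param g a [genotype_table()].
#' @param seed integer RNG seed.
#' @return A `genotype_table` with one locus per contig.
#' @export
thin_one_snp_per_contig <- function(g, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  idx <- split(seq_along(g$contig_id), g$contig_id)
  pick <- vapply(idx, function(i) if (length(i) == 1L) i else
    i[sample.int(length(i), 1L)], integer(1))
  subset_genotypes(g, loci = sort(unname(pick)))
}

## Seed hygiene: run under a temporary seed, then restore global RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
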