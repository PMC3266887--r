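## File formats: tabular and minimal-VCF genotypes, cohort bundles,
## scenario configuration (JSON), report tables.
##
## Internal SNP indices are 0-based half-open where intervals appear;
## all emitted positions are 1-based bp (VCF convention).

#' Write a genotype matrix as a tabular file
#'
#' Rows = samples, columns = loci, codes 0/1/2, `NA` for missing.
#'
#' @param genotypes n x m matrix (rownames = sample ids).
#' @param map the `region_map`.
#' @param path output path (TSV).
#' @export
write_genotypes_tsv <- function(genotypes, map, path) {
  df <- data.frame(sample = rownames(genotypes) %||%
                     sprintf("S%04d", seq_len(nrow(genotypes))),
                   genotypes, check.names = FALSE)
  colnames(df) <- c("sample", map_snps(map)$locus_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tabular genotype file
#'
#' @param path TSV written by [write_genotypes_tsv()].
#' @param map the `region_map` (column check).
#' @return genotype matrix with sample rownames.
#' @export
read_genotypes_tsv <- function(path, map) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE,
                          colClasses = "character")
  ids <- df$sample
  g <- as.matrix(df[, -1, drop = FALSE])
  for (j in seq_len(ncol(g))) {
    bad <- !(g[, j] %in% c("0", "1", "2") | is.na(g[, j]))
    if (any(bad))
      stop_stage("io", sprintf("malformed genotype at line %d, locus %s",
                               which(bad)[1] + 1L, colnames(g)[j]))
  }
  mode(g) <- "integer"
  rownames(g) <- ids
  expected <- map_snps(map)$locus_id
  if (!identical(colnames(g), expected))
    stop_stage("io", "locus columns do not match the region map")
  g
}

#' Write genotypes as a minimal VCF (GT only)
#'
#' Chromosome 6, Build-36-styled positions, unphased genotypes.
#'
#' @param genotypes n x m matrix of 0/1/2/NA.
#' @param map the `region_map`.
#' @param path output path (.vcf).
#' @export
write_vcf <- function(genotypes, map, path) {
  snps <- map_snps(map)
  ids <- rownames(genotypes) %||% sprintf("S%04d", seq_len(nrow(genotypes)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t")),
             con)
  gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(nrow(snps))) {
    g <- genotypes[, j]
    gt <- ifelse(is.na(g), "./.", gt_of[as.character(g)])
    writeLines(paste(c("6", format(snps$pos[j], scientific = FALSE),
                       snps$locus_id[j], "A", "G", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal GT-only VCF
#'
#' Only biallelic records are accepted; a multi-allelic ALT fails with
#' the offending locus named.
#'
#' @param path .vcf path.
#' @return list with `genotypes` (matrix) and `map` (a `region_map`
#'   rebuilt from the positions, with default anchors).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop_stage("io", "missing #CHROM header line")
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  pos <- integer(length(body)); snp_id <- character(length(body))
  G <- matrix(NA_integer_, length(ids), length(body))
  for (k in seq_along(body)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(cols))
      stop_stage("io", sprintf("malformed VCF row at line %d",
                               hdr + k))
    if (grepl(",", f[5], fixed = TRUE))
      stop_stage("io", sprintf("multi-allelic site at %s:%s (%s)",
                               f[1], f[2], f[3]))
    pos[k] <- as.integer(f[2]); snp_id[k] <- f[3]
    gt <- sub(":.*", "", f[-(1:9)])
    g <- rep(NA_integer_, length(gt))
    g[gt %in% c("0/0", "0|0")] <- 0L
    g[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    g[gt %in% c("1/1", "1|1")] <- 2L
    bad <- !(gt %in% c("./.", ".|.", "0/0", "0|0", "0/1", "1/0", "0|1",
                       "1|0", "1/1", "1|1"))
    if (any(bad))
      stop_stage("io", sprintf("malformed GT '%s' at line %d",
                               gt[which(bad)[1]], hdr + k))
    G[, k] <- g
  }
  rownames(G) <- ids
  map <- region_map(pos, snp_id)
  colnames(G) <- snp_id
  list(genotypes = G, map = map)
}

#' Write a simulated cohort bundle to a directory
#'
#' Emits `genotypes.tsv` (observed, with missing), `truth_haplotypes.tsv`,
#' `truth_hla.tsv`, `phenotype.tsv` and `masks.tsv`; everything needed to
#' reproduce a pipeline run from files.
#'
#' @param cohort a `sim_cohort` after [apply_missingness_and_typing()].
#' @param map the `region_map`.
#' @param dir output directory (created).
#' @export
write_cohort <- function(cohort, map, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes_tsv(cohort$genotypes_obs %||% cohort$genotypes, map,
                      file.path(dir, "genotypes.tsv"))
  H <- cohort$haplotypes
  hdf <- data.frame(sample = rep(rownames(cohort$genotypes), each = 2L),
                    hap = rep(1:2, nrow(cohort$genotypes)),
                    pattern = apply(H, 1, pattern_string))
  utils::write.table(hdf, file.path(dir, "truth_haplotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tdf <- data.frame(sample = hdf$sample, hap = hdf$hap, cohort$truth_hla,
                    check.names = FALSE)
  utils::write.table(tdf, file.path(dir, "truth_hla.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pdf <- data.frame(sample = rownames(cohort$genotypes),
                    phenotype = cohort$phenotype,
                    typed = cohort$typed_mask %||%
                      rep(TRUE, nrow(cohort$genotypes)),
                    validation = cohort$validation_mask %||%
                      rep(FALSE, nrow(cohort$genotypes)))
  utils::write.table(pdf, file.path(dir, "phenotype.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir bundle directory.
#' @param map the `region_map`.
#' @param name cohort name.
#' @return a `sim_cohort`-shaped list usable by [run_pipeline()].
#' @export
read_cohort <- function(dir, map, name = basename(dir)) {
  g <- read_genotypes_tsv(file.path(dir, "genotypes.tsv"), map)
  hdf <- utils::read.table(file.path(dir, "truth_haplotypes.tsv"),
                           sep = "\t", header = TRUE,
                           colClasses = "character")
  H <- t(vapply(hdf$pattern, pattern_vector, integer(n_snps(map))))
  rownames(H) <- NULL
  tdf <- utils::read.table(file.path(dir, "truth_hla.tsv"), sep = "\t",
                           header = TRUE, check.names = FALSE,
                           colClasses = "character")
  pdf <- utils::read.table(file.path(dir, "phenotype.tsv"), sep = "\t",
                           header = TRUE)
  structure(list(name = name, genotypes_obs = g, genotypes = g,
                 phenotype = as.character(pdf$phenotype),
                 haplotypes = H,
                 truth_hla = as.matrix(tdf[, c("HLA-B", "HLA-DRB1",
                                               "HLA-DQB1")]),
                 missing_mask = is.na(g),
                 typed_mask = as.logical(pdf$typed),
                 validation_mask = as.logical(pdf$validation)),
            class = "sim_cohort")
}

#' Write a pipeline configuration
#' @param config a list (see [pipeline_config()]).
#' @param path output path (.json).
#' @export
write_config <- function(config, path) {
  cfg <- Filter(Negate(is.null), unclass(config))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read and validate a pipeline configuration
#' @param path .json path.
#' @return validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop_stage("config", sprintf("config file not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

#' Construct a validated pipeline configuration
#'
#' @param seed master integer seed; all stage randomness derives from it.
#' @param consensus segment-learning consensus threshold.
#' @param mismatch_tolerance dissection mismatch tolerance.
#' @param r2_threshold,maf_min panel constraints.
#' @param threshold stepwise selection threshold.
#' @param alphas power alpha grid.
#' @param recomb_prob,missing_rate,typed_fraction scenario rates.
#' @param scale multiplier on cohort sizes (1 = the study's sizes); used
#'   to run reduced-scale smoke tests.
#' @param null_effects simulate with all GRRs forced to 1.
#' @param input_dir optional directory of cohort bundles (one
#'   subdirectory per cohort) to use instead of simulating.
#' @param out_dir optional output directory for report tables.
#' @return config list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, consensus = 0.95,
                            mismatch_tolerance = 1L, r2_threshold = 0.5,
                            maf_min = 0.05, threshold = 5e-8,
                            alphas = c(0.05, 0.01, 5e-5, 5e-8),
                            recomb_prob = 0.01, missing_rate = 0.01,
                            typed_fraction = 0.8, scale = 1,
                            null_effects = FALSE, input_dir = NULL,
                            out_dir = NULL) {
  stopifnot(consensus > 0.5, consensus <= 1,
            mismatch_tolerance >= 0,
            r2_threshold > 0, r2_threshold <= 1,
            maf_min >= 0, maf_min < 0.5,
            threshold > 0, threshold < 1,
            all(alphas > 0), all(alphas < 1), scale > 0, scale <= 1)
  if (is.null(seed)) stop_stage("config", "seed is mandatory")
  # JSON round-trips render absent fields as empty lists
  if (length(input_dir) == 0L) input_dir <- NULL
  if (length(out_dir) == 0L) out_dir <- NULL
  structure(list(seed = as.integer(seed), consensus = consensus,
                 mismatch_tolerance = mismatch_tolerance,
                 r2_threshold = r2_threshold, maf_min = maf_min,
                 threshold = threshold, alphas = alphas,
                 recomb_prob = recomb_prob, missing_rate = missing_rate,
                 typed_fraction = typed_fraction, scale = scale,
                 null_effects = null_effects,
                 input_dir = input_dir, out_dir = out_dir),
            class = "pipeline_config")
}
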