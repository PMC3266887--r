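## Extended-versus-recombinant haplotype dissection.
##
## Haplotypes carrying a focal HLA allele are classified against a
## reference extended haplotype over the HLA-B..HLA-DQB1 span: matches
## within the mismatch tolerance are "extended", the rest "recombinant"
## with a breakpoint interval between the first divergent SNP on the
## Class I side and the adjacent retained SNP.

#' Construct a reference extended haplotype
#'
#' @param name label, e.g. "B*0801-DRB1*0301-DQB1*02".
#' @param alleles named character vector of anchor alleles (`HLA-B`,
#'   `HLA-DRB1`, `HLA-DQB1`).
#' @param snp_pattern 0/1 vector over the panel SNPs.
#' @return object of class `reference_extended`.
#' @export
reference_extended <- function(name, alleles, snp_pattern) {
  structure(list(name = name, alleles = alleles,
                 snp_pattern = as.integer(snp_pattern)),
            class = "reference_extended")
}

#' Classify one haplotype against a reference extended haplotype
#'
#' @param haplotype 0/1 vector over the panel SNPs.
#' @param hap_alleles named character vector of this haplotype's HLA
#'   calls (used to check the focal allele); may contain `NA`.
#' @param reference a `reference_extended`.
#' @param map the `region_map`.
#' @param focal_gene gene whose allele defines carrier status.
#' @param mismatch_tolerance mismatches allowed over the B..DQB1 span
#'   while still counting as extended (default 1).
#' @param b_flank the span is extended this many bp telomeric of the
#'   HLA-B anchor so the SNPs tagging HLA-B itself are compared
#'   (default 4.5e5).
#' @return list with `label` ("extended", "recombinant" or "other") and
#'   `breakpoint` (half-open bp interval `c(lo, hi)` or `NULL`).
#' @export
classify_against_reference <- function(haplotype, hap_alleles, reference,
                                       map, focal_gene = "HLA-DRB1",
                                       mismatch_tolerance = 1L,
                                       b_flank = 4.5e5) {
  focal <- reference$alleles[[focal_gene]]
  hal <- hap_alleles[[focal_gene]]
  if (is.na(hal) || !allele_matches(hal, focal))
    return(list(label = "other", breakpoint = NULL))
  snp_pos <- map_snps(map)$pos
  span <- which(snp_pos >= anchor_pos(map, "HLA-B") - b_flank &
                  snp_pos <= anchor_pos(map, "HLA-DQB1"))
  mism <- haplotype[span] != reference$snp_pattern[span]
  if (sum(mism) <= mismatch_tolerance)
    return(list(label = "extended", breakpoint = NULL))
  # first divergent SNP scanning from the centromeric (DQB1) end down
  j <- max(which(mism))
  lo <- snp_pos[span[j]]
  hi <- if (j < length(span)) snp_pos[span[j + 1L]]
        else anchor_pos(map, "HLA-DQB1")
  list(label = "recombinant", breakpoint = c(lo, hi))
}

#' Percentage share, printed-style
#'
#' `100 * n_subset / n_total` rounded half away from zero to one decimal,
#' the convention used in published "N (%)" columns.
#'
#' @param n_subset,n_total non-negative counts, `n_total > 0`.
#' @return percentage with one decimal.
#' @export
share_extended <- function(n_subset, n_total) {
  if (n_total <= 0) stop_stage("dissect", "n_total must be positive")
  stopifnot(n_subset >= 0, n_subset <= n_total)
  round_half_up(100 * n_subset / n_total, 1)
}

#' Dissect carriers of a focal allele into extended and recombinant
#'
#' Classifies every carrier haplotype in one or more cohorts against the
#' reference and tabulates per-cohort case/control counts and frequencies
#' for the extended and recombinant strata.
#'
#' @param cohorts named list; each element a list with `haplotypes`
#'   (2n x m matrix), `calls` (2n x genes allele calls) and `phenotype`
#'   (length n, "case"/"control").
#' @param reference a `reference_extended`.
#' @param map the `region_map`.
#' @param focal_gene gene defining carrier status (default HLA-DRB1).
#' @param mismatch_tolerance see [classify_against_reference()].
#' @return object of class `dissection_table`: `summary` (N, N extended
#'   with %, N recombinant with %), `by_cohort` (per cohort and stratum:
#'   case/control carrier chromosome counts and frequencies), and
#'   `classes` (per-cohort character vectors of per-haplotype labels).
#' @export
dissect_focal_allele <- function(cohorts, reference, map,
                                 focal_gene = "HLA-DRB1",
                                 mismatch_tolerance = 1L) {
  classes <- list(); rows <- list()
  n_ext <- 0L; n_rec <- 0L
  for (nm in names(cohorts)) {
    ch <- cohorts[[nm]]
    nh <- nrow(ch$haplotypes)
    pheno_hap <- rep(ch$phenotype, each = 2L)
    lab <- character(nh)
    for (k in seq_len(nh)) {
      cl <- classify_against_reference(ch$haplotypes[k, ], ch$calls[k, ],
                                       reference, map, focal_gene,
                                       mismatch_tolerance)
      lab[k] <- cl$label
    }
    classes[[nm]] <- lab
    n_ext <- n_ext + sum(lab == "extended")
    n_rec <- n_rec + sum(lab == "recombinant")
    for (stratum in c("extended", "recombinant")) {
      a <- sum(lab == stratum & pheno_hap == "case")
      c_ <- sum(lab == stratum & pheno_hap == "control")
      n_case_chr <- sum(pheno_hap == "case")
      n_ctrl_chr <- sum(pheno_hap == "control")
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = nm, stratum = stratum,
        case_carriers = a, control_carriers = c_,
        case_chromosomes = n_case_chr, control_chromosomes = n_ctrl_chr,
        freq_cases = a / n_case_chr, freq_controls = c_ / n_ctrl_chr)
    }
  }
  total <- n_ext + n_rec
  summary <- data.frame(
    haplotype = reference$name,
    n_total = total, n_extended = n_ext, n_recombinant = n_rec,
    pct_extended = if (total > 0) share_extended(n_ext, total) else NA_real_,
    pct_recombinant = if (total > 0) share_extended(n_rec, total)
                      else NA_real_)
  structure(list(summary = summary,
                 by_cohort = do.call(rbind, rows),
                 classes = classes),
            class = "dissection_table")
}

#' Allele label comparison with 2-digit grouping
#'
#' `allele_matches("DQB1*0201", "DQB1*02")` is `TRUE`: a 2-digit query
#' matches all its 4-digit subtypes.
#'
#' @param have observed allele label.
#' @param want queried allele label (possibly 2-digit).
#' @return logical.
#' @export
allele_matches <- function(have, want) {
  if (is.na(have) || is.na(want)) return(FALSE)
  if (have == want) return(TRUE)
  startsWith(have, want)
}
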