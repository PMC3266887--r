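## Region map and scenario containers for the synthetic MHC world.
##
## Coordinates are styled after NCBI Build 36 (chromosome 6, 25-35 Mb).
## Internally SNPs are addressed by 1-based column index into the genotype
## matrix; bp positions are carried alongside and used for all interval
## logic (breakpoints, class boundaries). Emitted files use 1-based bp.

# Build 36 style anchor coordinates for the three classical genes.
.HLA_B_POS    <- 31429628L
.HLA_DRB1_POS <- 32654525L
.HLA_DQB1_POS <- 32735635L

# Approximate subregion boundaries (Build 36): Class I ends ~31.6 Mb,
# Class III spans ~31.6-32.3 Mb, Class II follows.
.CLASS1_END   <- 31.6e6
.CLASS3_END   <- 32.3e6

#' Construct a region map
#'
#' A region map is an ordered table of loci: biallelic SNPs (alleles coded
#' 0/1) plus exactly three HLA anchor loci (HLA-B, HLA-DRB1, HLA-DQB1, in
#' genomic order) marking where the classical genes sit between the SNPs.
#'
#' @param snp_pos integer vector of strictly increasing SNP positions (bp).
#' @param snp_id optional character vector of SNP identifiers.
#' @param anchor_pos named numeric vector of length 3 with names
#'   `HLA-B`, `HLA-DRB1`, `HLA-DQB1`.
#' @return an object of class `region_map`: a data.frame with columns
#'   `locus_id`, `pos`, `kind` ("snp" or "hla_anchor"), `gene`.
#' @export
region_map <- function(snp_pos, snp_id = NULL,
                       anchor_pos = c(`HLA-B` = .HLA_B_POS,
                                      `HLA-DRB1` = .HLA_DRB1_POS,
                                      `HLA-DQB1` = .HLA_DQB1_POS)) {
  if (is.null(snp_id)) snp_id <- sprintf("snp%03d", seq_along(snp_pos))
  stopifnot(length(snp_id) == length(snp_pos))
  if (length(anchor_pos) != 3L ||
      !identical(names(anchor_pos), c("HLA-B", "HLA-DRB1", "HLA-DQB1")))
    stop("anchor_pos must name HLA-B, HLA-DRB1, HLA-DQB1 in that order")
  if (is.unsorted(anchor_pos, strictly = TRUE))
    stop("HLA anchors must be in genomic order")
  df <- rbind(
    data.frame(locus_id = snp_id, pos = as.numeric(snp_pos),
               kind = "snp", gene = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(locus_id = names(anchor_pos), pos = as.numeric(anchor_pos),
               kind = "hla_anchor", gene = names(anchor_pos),
               stringsAsFactors = FALSE))
  df <- df[order(df$pos), , drop = FALSE]
  rownames(df) <- NULL
  if (is.unsorted(df$pos, strictly = TRUE))
    stop("locus positions must be strictly increasing")
  class(df) <- c("region_map", "data.frame")
  df
}

#' SNP sub-table of a region map
#' @param map a `region_map`.
#' @return data.frame of the SNP loci, in genomic order.
#' @export
map_snps <- function(map) {
  out <- map[map$kind == "snp", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Anchor position lookup
#' @param map a `region_map`.
#' @param gene one of "HLA-B", "HLA-DRB1", "HLA-DQB1".
#' @return bp position of the anchor.
#' @export
anchor_pos <- function(map, gene) {
  i <- which(map$kind == "hla_anchor" & map$gene == gene)
  if (length(i) != 1L) stop("unknown anchor gene: ", gene)
  map$pos[i]
}

#' Number of SNPs in a region map
#' @param map a `region_map`.
#' @return integer SNP count.
#' @export
n_snps <- function(map) sum(map$kind == "snp")

#' Construct a haplotype template
#'
#' An ancestral haplotype: a fixed 0/1 SNP pattern, the classical HLA
#' alleles it carries, its control-population frequency in each cohort,
#' its per-copy genotype relative risk (GRR), and the bp position of the
#' causal variant it carries (risk travels with whichever mosaic segment
#' contains that position).
#'
#' @param name template label.
#' @param snp_pattern integer 0/1 vector over the map's SNPs.
#' @param hla_alleles named character vector with entries for `HLA-B`,
#'   `HLA-DRB1`, `HLA-DQB1`.
#' @param cohort_freqs named numeric vector of per-cohort frequencies.
#' @param grr per-copy genotype relative risk (> 0); 1 for neutral. Either
#'   a scalar (same effect in every cohort) or a named per-cohort vector
#'   (observed haplotype odds ratios are cohort-specific).
#' @param causal_position bp position of the causal variant, or `NA` when
#'   all grr values are 1.
#' @return an object of class `haplotype_template`.
#' @export
haplotype_template <- function(name, snp_pattern, hla_alleles, cohort_freqs,
                               grr = 1, causal_position = NA_real_) {
  stopifnot(all(snp_pattern %in% c(0L, 1L)), all(grr > 0),
            all(cohort_freqs >= 0), all(cohort_freqs <= 1))
  if (any(grr != 1) && is.na(causal_position))
    stop("templates with grr != 1 must carry a causal_position")
  structure(list(name = name,
                 snp_pattern = as.integer(snp_pattern),
                 hla_alleles = hla_alleles,
                 cohort_freqs = cohort_freqs,
                 grr = grr,
                 causal_position = causal_position),
            class = "haplotype_template")
}

#' Construct a cohort specification
#'
#' @param name cohort label.
#' @param n_cases,n_controls positive case/control counts.
#' @param templates list of `haplotype_template`s; per-cohort frequencies
#'   must sum to at most 1 (the remainder is filled with background
#'   haplotypes drawn SNP-wise at template-averaged allele frequencies).
#' @param recomb_prob probability that a sampled haplotype is a de novo
#'   two-template mosaic with one breakpoint.
#' @param prevalence population disease prevalence K (default 1/500).
#' @param missing_rate per-genotype missingness rate.
#' @param typed_fraction share of the cases with "lab" HLA typing.
#' @param typed_ctrl_fraction share of the controls with lab typing (a
#'   typed control panel, as from a donor-registry survey).
#' @param validation_size held-out typed patients used only to validate
#'   imputation (default 79).
#' @param seed integer seed driving all randomness for this cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(name, n_cases, n_controls, templates,
                        recomb_prob = 0.01, prevalence = 0.002,
                        missing_rate = 0.01, typed_fraction = 0.8,
                        typed_ctrl_fraction = 0.1,
                        validation_size = 79L, seed = 1L) {
  stopifnot(n_cases > 0, n_controls > 0,
            recomb_prob >= 0, recomb_prob <= 1,
            prevalence > 0, prevalence < 1,
            missing_rate >= 0, missing_rate <= 1,
            typed_fraction >= 0, typed_fraction <= 1)
  fsum <- sum(vapply(templates, function(t) unname(t$cohort_freqs[[name]]),
                     numeric(1)))
  if (fsum > 1 + 1e-9)
    stop(sprintf("template frequencies for cohort %s sum to %.3f > 1",
                 name, fsum))
  structure(list(name = name, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 templates = templates, recomb_prob = recomb_prob,
                 prevalence = prevalence, missing_rate = missing_rate,
                 typed_fraction = typed_fraction,
                 typed_ctrl_fraction = typed_ctrl_fraction,
                 validation_size = as.integer(validation_size),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## ---------------------------------------------------------------------
## Default scenario
## ---------------------------------------------------------------------

# Fixed internal seed for the deterministic construction of template SNP
# patterns. This is part of the stated world, not a tuning knob.
.SCENARIO_PATTERN_SEED <- 60301L

.default_snp_positions <- function() {
  # 49 SNPs across the classical MHC with denser Class I coverage:
  # 20 in Class I, 12 in Class III, 17 in Class II.
  round(c(seq(29.8e6, 31.55e6, length.out = 20),
          seq(31.65e6, 32.28e6, length.out = 12),
          seq(32.33e6, 33.20e6, length.out = 17)))
}

# Local haplotype blocks around each gene used to encode allele identity.
.block_idx <- function(pos, lo, hi) which(pos >= lo & pos <= hi)

# Deterministically draw k distinct 0/1 codes of given length with a
# minimum pairwise Hamming distance, from an already-seeded RNG stream.
.draw_codes <- function(k, len, min_dist = 2L) {
  codes <- list()
  tries <- 0L; stall <- 0L
  while (length(codes) < k) {
    cand <- sample(0:1, len, replace = TRUE)
    ok <- all(vapply(codes, function(c) sum(c != cand) >= min_dist,
                     logical(1)))
    tries <- tries + 1L
    if (ok) {
      codes[[length(codes) + 1L]] <- cand
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > 2000L) { codes <- list(); stall <- 0L }  # greedy dead end
    }
    if (tries > 200000L) stop("could not draw separated codes")
  }
  codes
}

#' Build the default three-cohort scenario
#'
#' Returns the 49-SNP region map and three cohort specifications
#' (Sweden/Iceland 430/1090, Spain 256/322, Finland 86/564 cases/controls)
#' whose control haplotype frequencies and per-copy risks plant four
#' independent signals: the extended B*0801-DRB1*0301-DQB1*02 haplotype
#' (GRR 3.33, causal position at the Class III / Class II border), the
#' DQB1*02-bearing DRB1*0701 haplotypes (GRR 2.23, causal in the
#' DQA1-DQB1 interval), the B*1402-DRB1*0102-DQB1*05 haplotype (GRR 4.59,
#' causal telomeric to Class II) and the protective
#' B*0702-DRB1*1501-DQB1*06 haplotype (GRR 0.14, causal in the DRB1-DQB1
#' block). Recombinant and neutral templates fill out realistic European
#' MHC haplotype structure; the recombinant-B*0801 template's frequencies
#' are invented (no published values exist).
#'
#' @param recomb_prob de novo mosaic probability per haplotype.
#' @param missing_rate per-genotype missingness rate.
#' @param typed_fraction share of individuals with lab HLA typing.
#' @param seeds integer vector of three per-cohort seeds.
#' @param null_effects if `TRUE`, all template GRRs are set to 1 (no
#'   causal variants planted); used for null calibration checks.
#' @return list with elements `map` (a `region_map`) and `cohorts`
#'   (list of three `cohort_spec`s).
#' @export
build_default_scenario <- function(recomb_prob = 0.01, missing_rate = 0.01,
                                   typed_fraction = 0.8,
                                   seeds = c(101L, 202L, 303L),
                                   null_effects = FALSE) {
  pos <- .default_snp_positions()
  map <- region_map(pos)
  m <- length(pos)

  b_idx  <- .block_idx(pos, 31.00e6, 31.60e6)   # 6 SNPs near HLA-B
  dr_idx <- .block_idx(pos, 32.49e6, 32.67e6)   # 4 SNPs near HLA-DRB1
  dq_idx <- .block_idx(pos, 32.70e6, 33.20e6)   # 10 SNPs near/past HLA-DQB1

  # template table: name, B, DRB1, DQB1, ctrl freqs (SWE, SPA, FIN), grr,
  # causal bp. Frequencies for the risk and recombinant rows follow the
  # published control columns; the rec_B08 row is invented; neutral rows
  # model other common European haplotypes.
  tdef <- list(
    list("ext_DR3",  "B*0801", "DRB1*0301", "DQB1*0201",
         c(0.097, 0.026, 0.083), c(2.96, 4.50, 3.57), 32315000),
    list("rec_DR3",  "B*1801", "DRB1*0301", "DQB1*0201",
         c(0.039, 0.093, 0.030), 1, NA),
    list("rec_B08",  "B*0801", "DRB1*1104", "DQB1*0301",
         c(0.020, 0.008, 0.015), 1, NA),
    list("ext_DR7",  "B*1302", "DRB1*0701", "DQB1*0202",
         c(0.008, 0.009, 0.023), c(2.06, 2.59, 3.69), 32717000),
    list("rec_DR7_DQ2", "B*4402", "DRB1*0701", "DQB1*0202",
         c(0.049, 0.132, 0.038), c(2.44, 1.92, 2.92), 32717000),
    list("rec_DR7_nonDQ2", "B*5701", "DRB1*0701", "DQB1*0303",
         c(0.033, 0.033, 0.008), 1, NA),
    list("ext_DR1",  "B*1402", "DRB1*0102", "DQB1*0501",
         c(0.002, 0.030, 0.002), c(13.24, 3.11, 13.71), 32000000),
    list("rec_DR1",  "B*3501", "DRB1*0102", "DQB1*0501",
         c(0.001, 0.016, 0.003), c(2.55, 3.83, 3.22), 32000000),
    list("DR1_0101", "B*4001", "DRB1*0101", "DQB1*0502",
         c(0.121, 0.107, 0.211), 1, NA),
    list("ext_DR15", "B*0702", "DRB1*1501", "DQB1*0602",
         c(0.077, 0.034, 0.067), c(0.18, 0.06, 0.14), 32690000),
    list("rec_DR15", "B*1501", "DRB1*1501", "DQB1*0602",
         c(0.073, 0.073, 0.063), c(0.15, 0.08, 0.25), 32690000),
    list("n_DR4",    "B*4403", "DRB1*0401", "DQB1*0302",
         c(0.100, 0.075, 0.080), 1, NA),
    list("n_DR11",   "B*3502", "DRB1*1101", "DQB1*0601",
         c(0.055, 0.080, 0.055), 1, NA),
    list("n_DR16",   "B*5101", "DRB1*1601", "DQB1*0503",
         c(0.060, 0.050, 0.050), 1, NA),
    list("n_DR404",  "B*2705", "DRB1*0404", "DQB1*0304",
         c(0.040, 0.055, 0.050), 1, NA),
    list("n_DR13",   "B*4901", "DRB1*1301", "DQB1*0603",
         c(0.055, 0.054, 0.065), 1, NA),
    list("n_DR8",    "B*3901", "DRB1*0801", "DQB1*0402",
         c(0.060, 0.035, 0.050), 1, NA),
    list("n_DR1302", "B*1510", "DRB1*1302", "DQB1*0604",
         c(0.060, 0.040, 0.057), 1, NA))

  b_all  <- unique(vapply(tdef, `[[`, character(1), 2))
  dr_all <- unique(vapply(tdef, `[[`, character(1), 3))
  dq_all <- unique(vapply(tdef, `[[`, character(1), 4))

  # historical recombination structure: recombinants share the segment of
  # their extended counterpart on one side of a fixed historical
  # breakpoint (between HLA-B and HLA-DRB1, except rec_DR7_nonDQ2 whose
  # second break falls between HLA-DRB1 and HLA-DQB1).
  share_ops <- list(
    list("rec_DR3",  "ext_DR3",  32.40e6, Inf),
    list("rec_B08",  "ext_DR3",  -Inf,    31.90e6),
    list("rec_DR7_DQ2",    "ext_DR7", 31.70e6, Inf),
    list("rec_DR7_nonDQ2", "ext_DR7", 31.70e6, 32.6999e6),
    list("rec_DR1",  "ext_DR1",  31.97e6, Inf),
    list("rec_DR15", "ext_DR15", 31.90e6, Inf))
  apply_sharing <- function(pl) {
    for (op in share_ops) {
      i <- which(pos >= op[[3]] & pos <= op[[4]])
      pl[[op[[1]]]][i] <- pl[[op[[2]]]][i]
    }
    pl
  }
  tpl_names <- vapply(tdef, `[[`, character(1), 1)
  freqs_mat <- t(vapply(tdef, `[[`, numeric(3), 5))  # template x cohort
  grrs_mat <- t(vapply(tdef, function(td) rep(td[[6]], length.out = 3),
                       numeric(3)))
  # weighted SNP-column r^2 over the template + background mixture, for a
  # given template weight vector (background = independent draws at
  # template-averaged frequencies)
  mix_r2 <- function(P, w) {
    wt <- w / sum(w)
    tmass <- 0.95  # template mass; background fills the rest
    pbar <- as.numeric(wt %*% P)
    EX <- tmass * pbar + (1 - tmass) * pbar
    EXY <- tmass * crossprod(P * wt, P) + (1 - tmass) * outer(pbar, pbar)
    # cross term: one haplotype, so EXY mixes within-haplotype sources:
    # a single haplotype is template (prob tmass) or background; within
    # background, sites are independent.
    V <- EX * (1 - EX)
    C <- EXY - outer(EX, EX)
    r2 <- C^2 / outer(V, V)
    diag(r2) <- 0
    r2
  }
  block_snps <- c(b_idx, dr_idx, dq_idx)

  patterns <- local_seed(.SCENARIO_PATTERN_SEED, {
    b_codes  <- .draw_codes(length(b_all),  length(b_idx),  2L)
    dr_codes <- .draw_codes(length(dr_all), length(dr_idx), 1L)
    dq_codes <- .draw_codes(length(dq_all), length(dq_idx), 4L)
    names(b_codes) <- b_all; names(dr_codes) <- dr_all
    names(dq_codes) <- dq_all
    base <- lapply(tdef, function(td) sample(0:1, m, replace = TRUE))
    names(base) <- tpl_names
    assign_codes <- function(base) {
      for (i in seq_along(tdef)) {
        td <- tdef[[i]]
        base[[i]][b_idx]  <- b_codes[[td[[2]]]]
        base[[i]][dr_idx] <- dr_codes[[td[[3]]]]
        base[[i]][dq_idx] <- dq_codes[[td[[4]]]]
      }
      base
    }
    base <- assign_codes(base)
    # decorrelation pass: the panel contract requires low pairwise r^2
    # between backbone SNPs, so free (non-block) base bits are redrawn
    # until no SNP pair exceeds 0.45 under any cohort's control weights
    # or under case-enriched weights. Deterministic (seeded above).
    weight_sets <- c(lapply(1:3, function(j) freqs_mat[, j]),
                     lapply(1:3, function(j) freqs_mat[, j] * grrs_mat[, j]))
    receives <- function(tpl, j) {
      for (op in share_ops)
        if (op[[1]] == tpl && pos[j] >= op[[3]] && pos[j] <= op[[4]])
          return(TRUE)
      FALSE
    }
    for (round in 1:2000) {
      pl <- apply_sharing(base)
      P <- t(vapply(pl, identity, integer(m)))
      worst <- 0
      viol <- matrix(integer(0), 0, 2)
      maf_bad <- integer(0)
      for (w in weight_sets) {
        r2 <- mix_r2(P, w)
        worst <- max(worst, max(r2))
        v <- which(r2 > 0.45 & upper.tri(r2), arr.ind = TRUE)
        if (nrow(v)) viol <- rbind(viol, v)
        pbar <- as.numeric((w / sum(w)) %*% P)
        maf_bad <- union(maf_bad, which(pbar < 0.10 | pbar > 0.90))
      }
      maf_free <- setdiff(maf_bad, block_snps)
      for (j in maf_free)
        for (tn in tpl_names)
          if (!receives(tn, j)) base[[tn]][j] <- sample(0:1, 1)
      if (worst <= 0.45 && !length(maf_free)) break
      fixed_block <- FALSE
      for (k in seq_len(nrow(viol))) {
        pair <- viol[k, ]
        if (!(pair[1] %in% block_snps) || !(pair[2] %in% block_snps)) {
          j <- if (!(pair[1] %in% block_snps)) pair[1] else pair[2]
          for (tn in tpl_names)
            if (!receives(tn, j)) base[[tn]][j] <- sample(0:1, 1)
        } else if (!fixed_block) {
          # both SNPs carry allele codes: redraw the code set of the gene
          # block containing the first one and re-stamp all templates
          if (pair[1] %in% b_idx) {
            b_codes <- .draw_codes(length(b_all), length(b_idx), 2L)
            names(b_codes) <- b_all
          } else if (pair[1] %in% dr_idx) {
            dr_codes <- .draw_codes(length(dr_all), length(dr_idx), 1L)
            names(dr_codes) <- dr_all
          } else {
            dq_codes <- .draw_codes(length(dq_all), length(dq_idx), 4L)
            names(dq_codes) <- dq_all
          }
          base <- assign_codes(base)
          fixed_block <- TRUE
        }
      }
      if (round == 2000) stop("decorrelation did not converge")
    }
    apply_sharing(base)
  })

  cohort_names <- c("Sweden/Iceland", "Spain", "Finland")
  templates <- lapply(seq_along(tdef), function(i) {
    td <- tdef[[i]]
    fr <- td[[5]]; names(fr) <- cohort_names
    grr <- if (null_effects) 1 else td[[6]]
    if (length(grr) == 3) names(grr) <- cohort_names
    if (null_effects) td[[7]] <- NA_real_
    haplotype_template(
      name = td[[1]],
      snp_pattern = patterns[[td[[1]]]],
      hla_alleles = c(`HLA-B` = td[[2]], `HLA-DRB1` = td[[3]],
                      `HLA-DQB1` = td[[4]]),
      cohort_freqs = fr, grr = grr, causal_position = td[[7]])
  })

  sizes <- list(`Sweden/Iceland` = c(430L, 1090L),
                Spain = c(256L, 322L),
                Finland = c(86L, 564L))
  cohorts <- lapply(seq_along(cohort_names), function(i) {
    nm <- cohort_names[i]
    cohort_spec(nm, sizes[[nm]][1], sizes[[nm]][2], templates,
                recomb_prob = recomb_prob, missing_rate = missing_rate,
                typed_fraction = typed_fraction, seed = seeds[i])
  })
  names(cohorts) <- cohort_names
  list(map = map, cohorts = cohorts)
}
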