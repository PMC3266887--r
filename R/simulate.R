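## Synthetic case-control cohort generation.
##
## Haplotypes are drawn from ancestral templates at their stated control-
## population frequencies; the unfilled remainder is background noise
## (SNP-wise independent draws at template-averaged allele frequencies,
## GRR 1). With probability `recomb_prob` a haplotype is a de novo mosaic
## of two independently drawn sources with a single breakpoint uniform
## over the HLA-B..HLA-DQB1 interval. Disease risk is multiplicative
## across the two haplotypes of an individual; a haplotype carries its
## source template's GRR only when the segment containing that template's
## causal position was inherited from it. Cases and controls are
## ascertained by rejection sampling at population prevalence K.

.template_freqs <- function(spec) {
  vapply(spec$templates, function(t) unname(t$cohort_freqs[[spec$name]]),
         numeric(1))
}

# per-cohort effective grr of each template (scalar grr applies everywhere)
.template_grrs <- function(spec) {
  vapply(spec$templates, function(t) {
    g <- t$grr
    if (length(g) == 1L) unname(g) else unname(g[[spec$name]])
  }, numeric(1))
}

.background_freqs <- function(spec) {
  f <- .template_freqs(spec)
  pat <- vapply(spec$templates, `[[`, integer(length(spec$templates[[1]]$snp_pattern)),
                "snp_pattern")
  as.numeric(pat %*% f / sum(f))
}

# grr contributed by a (possibly one-sided) template segment: `left` says
# whether the segment is the telomeric side (pos < bp) of the mosaic.
.segment_grr <- function(tpl, bp, left) {
  if (is.null(tpl)) return(1)
  cp <- tpl$causal_position
  if (is.na(cp) || tpl$grr == 1) return(1)
  if (is.na(bp)) return(tpl$grr)           # intact haplotype
  if (left && cp < bp) return(tpl$grr)
  if (!left && cp >= bp) return(tpl$grr)
  1
}

# Analytic E[grr] over the haplotype-sampling distribution; used to
# calibrate the baseline penetrance f0 so that population prevalence
# equals K exactly under the model.
.expected_grr <- function(spec, map) {
  f <- .template_freqs(spec)
  bg <- 1 - sum(f)
  grr <- .template_grrs(spec)
  cp <- vapply(spec$templates, `[[`, numeric(1), "causal_position")
  a <- anchor_pos(map, "HLA-B"); b <- anchor_pos(map, "HLA-DQB1")
  fr <- c(f, bg); gr <- c(grr, 1); cpos <- c(cp, NA)
  S1 <- sum(fr * gr)
  if (spec$recomb_prob == 0) return(S1)
  k <- length(fr)
  S2 <- 0
  for (L in seq_len(k)) for (R in seq_len(k)) {
    cuts <- sort(unique(pmin(pmax(c(cpos[L], cpos[R]), a), b)))
    cuts <- cuts[!is.na(cuts)]
    edges <- unique(c(a, cuts, b))
    val <- 0
    for (s in seq_len(length(edges) - 1L)) {
      mid <- (edges[s] + edges[s + 1L]) / 2
      gl <- if (!is.na(cpos[L]) && cpos[L] < mid) gr[L] else 1
      grv <- if (!is.na(cpos[R]) && cpos[R] >= mid) gr[R] else 1
      val <- val + gl * grv * (edges[s + 1L] - edges[s]) / (b - a)
    }
    S2 <- S2 + fr[L] * fr[R] * val
  }
  (1 - spec$recomb_prob) * S1 + spec$recomb_prob * S2
}

#' Simulate one case-control cohort
#'
#' Draws haplotype pairs from the spec's template distribution, assigns
#' disease status under a multiplicative penetrance model calibrated to
#' the population prevalence, and ascertains by rejection sampling until
#' the requested case and control counts are reached. Deterministic given
#' `spec$seed`.
#'
#' @param spec a `cohort_spec`.
#' @param map the `region_map` the spec's templates are defined over.
#' @return an object of class `sim_cohort`: a list with `genotypes`
#'   (n x m matrix, 0/1/2), `phenotype` ("case"/"control"), `haplotypes`
#'   (2n x m truth matrix, rows 2i-1 and 2i belong to individual i),
#'   `hap_info` (source templates, breakpoints, per-haplotype GRR),
#'   `truth_hla` (2n x 3 character matrix of per-haplotype allele labels,
#'   "other" for background), plus the spec and baseline penetrance.
#' @export
simulate_cohort <- function(spec, map) local_seed(spec$seed, {
  f <- .template_freqs(spec)
  ntpl <- length(f)
  bg <- 1 - sum(f)
  grr <- .template_grrs(spec)
  cp <- vapply(spec$templates, `[[`, numeric(1), "causal_position")
  Eg <- .expected_grr(spec, map)
  f0 <- spec$prevalence / Eg^2
  if (f0 * max(grr)^2 > 1)
    stop_stage("simulate", sprintf(
      "unreachable prevalence: f0 * max(grr)^2 = %.3f > 1",
      f0 * max(grr)^2))
  a <- anchor_pos(map, "HLA-B"); b <- anchor_pos(map, "HLA-DQB1")
  probs <- c(f, bg)   # index ntpl+1 = background

  draw_haps <- function(nh) {
    left <- sample.int(ntpl + 1L, nh, replace = TRUE, prob = probs)
    mosaic <- stats::runif(nh) < spec$recomb_prob
    right <- left
    right[mosaic] <- sample.int(ntpl + 1L, sum(mosaic), replace = TRUE,
                                prob = probs)
    bp <- rep(NA_real_, nh)
    bp[mosaic] <- stats::runif(sum(mosaic), a, b)
    gl <- ifelse(left <= ntpl & !is.na(cp[pmin(left, ntpl)]) &
                   (is.na(bp) | cp[pmin(left, ntpl)] < bp),
                 grr[pmin(left, ntpl)], 1)
    gl[left > ntpl] <- 1
    gr <- rep(1, nh)
    sel <- mosaic & right <= ntpl
    gr[sel] <- ifelse(!is.na(cp[right[sel]]) & cp[right[sel]] >= bp[sel],
                      grr[right[sel]], 1)
    g <- ifelse(mosaic, gl * gr, gl)
    data.frame(left = left, right = ifelse(mosaic, right, NA_integer_),
               bp = bp, grr = g)
  }

  need_ca <- spec$n_cases; need_co <- spec$n_controls
  kept_ca <- list(); kept_co <- list()
  got_ca <- 0L; got_co <- 0L
  guard <- 0L
  while (got_ca < need_ca || got_co < need_co) {
    guard <- guard + 1L
    if (guard > 2000L)
      stop_stage("simulate", "rejection sampling failed to reach quotas")
    nb <- max(2000L, ceiling((need_ca - got_ca) / spec$prevalence * 1.1))
    nb <- min(nb, 400000L)
    h1 <- draw_haps(nb); h2 <- draw_haps(nb)
    pen <- pmin(1, f0 * h1$grr * h2$grr)
    is_case <- stats::runif(nb) < pen
    if (got_ca < need_ca) {
      idx <- which(is_case)[seq_len(min(sum(is_case), need_ca - got_ca))]
      if (length(idx)) {
        kept_ca[[length(kept_ca) + 1L]] <-
          cbind(h1[idx, , drop = FALSE], h2[idx, , drop = FALSE])
        got_ca <- got_ca + length(idx)
      }
    }
    if (got_co < need_co) {
      idx <- which(!is_case)[seq_len(min(sum(!is_case), need_co - got_co))]
      if (length(idx)) {
        kept_co[[length(kept_co) + 1L]] <-
          cbind(h1[idx, , drop = FALSE], h2[idx, , drop = FALSE])
        got_co <- got_co + length(idx)
      }
    }
  }
  dca <- do.call(rbind, kept_ca); dco <- do.call(rbind, kept_co)
  names(dca) <- names(dco) <- c("l1", "r1", "bp1", "g1",
                                "l2", "r2", "bp2", "g2")
  dd <- rbind(dca, dco)
  n <- nrow(dd)
  phenotype <- c(rep("case", need_ca), rep("control", need_co))

  # materialize haplotype patterns
  m <- n_snps(map)
  snp_pos <- map_snps(map)$pos
  pbg <- .background_freqs(spec)
  tpl_pat <- t(vapply(spec$templates, `[[`, integer(m), "snp_pattern"))
  hap_src <- data.frame(
    individual = rep(seq_len(n), each = 2L),
    hap = rep(1:2, n),
    left = as.integer(t(dd[, c("l1", "l2")])),
    right = as.integer(t(dd[, c("r1", "r2")])),
    bp = as.numeric(t(dd[, c("bp1", "bp2")])),
    grr = as.numeric(t(dd[, c("g1", "g2")])))
  H <- matrix(0L, nrow = 2L * n, ncol = m)
  src_of <- function(row) {
    # per-SNP source index (template id or 0 = background) for one hap
    lf <- hap_src$left[row]; rt <- hap_src$right[row]; bp <- hap_src$bp[row]
    s <- rep(if (lf <= ntpl) lf else 0L, m)
    if (!is.na(bp)) s[snp_pos >= bp] <- if (rt <= ntpl) rt else 0L
    s
  }
  plain <- is.na(hap_src$bp)
  for (t in seq_len(ntpl)) {
    rows <- which(plain & hap_src$left == t)
    if (length(rows))
      H[rows, ] <- matrix(tpl_pat[t, ], length(rows), m, byrow = TRUE)
  }
  bgrows <- which(plain & hap_src$left == ntpl + 1L)
  if (length(bgrows))
    H[bgrows, ] <- matrix(stats::rbinom(length(bgrows) * m, 1L,
                                        rep(pbg, each = length(bgrows))),
                          length(bgrows), m)
  for (row in which(!plain)) {
    s <- src_of(row)
    h <- integer(m)
    for (t in unique(s)) {
      i <- which(s == t)
      h[i] <- if (t == 0L) stats::rbinom(length(i), 1L, pbg[i])
              else tpl_pat[t, i]
    }
    H[row, ] <- h
  }

  # truth HLA labels per haplotype
  genes <- c("HLA-B", "HLA-DRB1", "HLA-DQB1")
  gpos <- vapply(genes, function(g) anchor_pos(map, g), numeric(1))
  allele_of <- function(tidx, gene) {
    if (tidx == 0L || tidx > ntpl) "other"
    else unname(spec$templates[[tidx]]$hla_alleles[[gene]])
  }
  truth_hla <- matrix(NA_character_, 2L * n, length(genes),
                      dimnames = list(NULL, genes))
  for (row in seq_len(2L * n)) {
    bp <- hap_src$bp[row]
    for (gi in seq_along(genes)) {
      side <- if (!is.na(bp) && gpos[gi] >= bp) hap_src$right[row]
              else hap_src$left[row]
      if (side > ntpl) side <- 0L
      truth_hla[row, gi] <- allele_of(side, genes[gi])
    }
  }

  geno <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
          H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  ids <- sprintf("%s_%04d", gsub("[^A-Za-z]", "", spec$name), seq_len(n))
  rownames(geno) <- ids
  colnames(geno) <- map_snps(map)$locus_id
  tpl_names <- vapply(spec$templates, `[[`, character(1), "name")
  lab <- function(i) ifelse(is.na(i) | i > ntpl, "background",
                            tpl_names[pmin(i, ntpl)])
  hap_src$left_template <- lab(hap_src$left)
  hap_src$right_template <- ifelse(is.na(hap_src$bp), NA_character_,
                                   lab(hap_src$right))
  structure(list(name = spec$name, genotypes = geno, phenotype = phenotype,
                 haplotypes = H, hap_info = hap_src, truth_hla = truth_hla,
                 f0 = f0, expected_grr = Eg, spec = spec),
            class = "sim_cohort")
})

#' Apply genotype missingness and HLA-typing availability
#'
#' Masks genotypes missing independently at `spec$missing_rate`, marks a
#' `spec$typed_fraction` subset of the cases plus a
#' `spec$typed_ctrl_fraction` subset of the controls as carrying lab HLA
#' typing (clinical typing of patients plus a typed control panel), and
#' holds out a validation set of typed patients (default
#' `spec$validation_size`, 79 individuals). Deterministic
#' given `spec$seed` (a derived stream, so the cohort draw itself is
#' unchanged).
#'
#' @param cohort a `sim_cohort`.
#' @param spec the `cohort_spec` used to generate it.
#' @param validation_size optional override of `spec$validation_size`
#'   (used when a pooled multi-cohort validation set is allocated).
#' @return the cohort with added fields `genotypes_obs` (with `NA` for
#'   missing), `missing_mask`, `typed_mask`, `validation_mask`.
#' @export
apply_missingness_and_typing <- function(cohort, spec,
                                         validation_size = NULL) {
  if (is.null(validation_size)) validation_size <- spec$validation_size
  local_seed(spec$seed + 1000003L, {
    g <- cohort$genotypes
    n <- nrow(g); m <- ncol(g)
    miss <- matrix(stats::runif(n * m) < spec$missing_rate, n, m)
    gobs <- g
    gobs[miss] <- NA_integer_
    cases <- which(cohort$phenotype == "case")
    ctrls <- which(cohort$phenotype == "control")
    n_typed <- round(spec$typed_fraction * length(cases))
    n_typed_c <- round((spec$typed_ctrl_fraction %||% 0) * length(ctrls))
    typed <- rep(FALSE, n)
    if (n_typed > 0) typed[sample(cases, n_typed)] <- TRUE
    if (n_typed_c > 0) typed[sample(ctrls, n_typed_c)] <- TRUE
    val <- rep(FALSE, n)
    typed_cases <- which(typed & cohort$phenotype == "case")
    if (validation_size > 0) {
      if (length(typed_cases) < validation_size)
        stop_stage("typing", sprintf(
          "typed patient subset (%d) smaller than validation size (%d)",
          length(typed_cases), validation_size))
      val[sample(typed_cases, validation_size)] <- TRUE
    }
    cohort$genotypes_obs <- gobs
    cohort$missing_mask <- miss
    cohort$typed_mask <- typed
    cohort$validation_mask <- val
    cohort
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort '%s': %d cases / %d controls, %d SNPs\n",
              x$name, sum(x$phenotype == "case"),
              sum(x$phenotype == "control"), ncol(x$genotypes)))
  invisible(x)
}
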