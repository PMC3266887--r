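## HLA allele imputation from phased SNP haplotypes.
##
## A typed training subset is used to (i) pick a tag SNP per common HLA
## allele (maximum haploid r^2 with the allele indicator), (ii) learn the
## allele-defining segment: the longest run of consecutive panel SNPs
## around the tag whose carrier-consensus pattern is matched by >= 95% of
## carrier haplotypes and occurs on zero non-carrier haplotypes, and
## (iii) call alleles on all haplotypes by exact segment match.

.GENES <- c("HLA-B", "HLA-DRB1", "HLA-DQB1")

.haploid_r2 <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Select tagging and backbone SNPs
#'
#' For each common HLA allele (>= `min_carriers` carrier haplotypes in the
#' training set) the SNP with maximal haploid r^2 against the allele
#' indicator is chosen as its tag, for the `n_tags` most common alleles.
#' The panel is then filled with `n_backbone` SNPs spread uniformly in bp
#' (with 1.5x target density in the Class I region) subject to minor
#' allele frequency >= `maf_min` and pairwise backbone r^2 <
#' `r2_threshold`.
#'
#' @param haplotypes training haplotype matrix (rows = chromosomes).
#' @param hla matrix/data.frame of per-haplotype truth labels with columns
#'   `HLA-B`, `HLA-DRB1`, `HLA-DQB1` ("other" = no common allele).
#' @param map the `region_map`.
#' @param n_tags number of alleles given tag SNPs (default 11).
#' @param n_backbone number of backbone SNPs (default 38).
#' @param r2_threshold pairwise backbone r^2 ceiling (default 0.5).
#' @param maf_min minor allele frequency floor (default 0.05), evaluated
#'   on `control_haplotypes` when given, else on the training set.
#' @param min_carriers minimum carrier haplotypes per tagged allele.
#' @param control_haplotypes optional haplotype matrix of control
#'   chromosomes for the MAF filter.
#' @param class1_weight relative backbone target density in Class I.
#' @param tag_flank tag SNPs are searched within this distance (bp) of
#'   the allele's gene anchor; HLA-tagging SNPs are local by nature.
#' @return object of class `tag_snp_panel`: `tags` (data.frame allele,
#'   gene, snp index, r2), `backbone` (SNP indices), `panel` (all panel
#'   SNP indices, sorted), `r2_summary`.
#' @export
select_tag_snps <- function(haplotypes, hla, map, n_tags = 11L,
                            n_backbone = 38L, r2_threshold = 0.5,
                            maf_min = 0.05, min_carriers = 10L,
                            control_haplotypes = NULL,
                            class1_weight = 1.5, tag_flank = 6e5) {
  haplotypes <- as.matrix(haplotypes)
  m <- ncol(haplotypes)
  snp_pos <- map_snps(map)$pos
  stopifnot(m == n_snps(map))
  hla <- as.matrix(hla)

  counts <- list()
  for (g in .GENES) {
    tab <- table(hla[, g])
    tab <- tab[names(tab) != "other"]
    for (al in names(tab)) counts[[al]] <- list(gene = g, n = tab[[al]])
  }
  common <- names(counts)[vapply(counts, function(x) x$n >= min_carriers,
                                 logical(1))]
  if (!length(common)) stop_stage("panel", "no common alleles to tag")
  common <- common[order(-vapply(counts[common], `[[`, numeric(1), "n"))]
  tagged <- utils::head(common, n_tags)

  tags <- data.frame(allele = character(0), gene = character(0),
                     snp = integer(0), r2 = numeric(0))
  used <- integer(0)
  for (al in tagged) {
    g <- counts[[al]]$gene
    ind <- as.integer(hla[, g] == al)
    local <- which(abs(snp_pos - anchor_pos(map, g)) <= tag_flank)
    r2v <- rep(-1, m)
    r2v[local] <- vapply(local, function(j)
      .haploid_r2(haplotypes[, j], ind), numeric(1))
    r2v[used] <- -1
    j <- which.max(r2v)
    tags <- rbind(tags, data.frame(allele = al, gene = g, snp = j,
                                   r2 = r2v[j]))
    used <- c(used, j)
  }

  maf_haps <- if (is.null(control_haplotypes)) haplotypes
              else as.matrix(control_haplotypes)
  p <- colMeans(maf_haps)
  eligible <- setdiff(which(pmin(p, 1 - p) >= maf_min), used)
  # uniform bp targets, Class I weighted denser
  lo <- min(snp_pos); hi <- max(snp_pos)
  c1 <- min(.CLASS1_END, hi)
  len1 <- max(c1 - lo, 0); len2 <- hi - max(c1, lo)
  w1 <- len1 * class1_weight
  n1 <- round(n_backbone * w1 / (w1 + len2))
  n2 <- n_backbone - n1
  targets <- c(if (n1 > 0) seq(lo, c1, length.out = n1 + 1L)[-1] else NULL,
               if (n2 > 0) seq(c1, hi, length.out = n2 + 1L)[-1] else NULL)
  backbone <- integer(0)
  for (tg in targets) {
    cand <- setdiff(eligible, backbone)
    cand <- cand[order(abs(snp_pos[cand] - tg))]
    picked <- NA_integer_
    for (j in cand) {
      ok <- all(vapply(backbone, function(k)
        .haploid_r2(haplotypes[, j], haplotypes[, k]) < r2_threshold,
        logical(1)))
      if (ok) { picked <- j; break }
    }
    if (is.na(picked))
      stop_stage("panel", sprintf(
        "cannot place %d backbone SNPs: MAF >= %.2f and pairwise r2 < %.2f leave too few eligible SNPs",
        n_backbone, maf_min, r2_threshold))
    backbone <- c(backbone, picked)
  }
  backbone <- sort(backbone)
  bb_r2 <- if (length(backbone) > 1) {
    rr <- stats::cor(haplotypes[, backbone])^2
    diag(rr) <- NA
    max(rr, na.rm = TRUE)
  } else 0
  structure(list(tags = tags, backbone = backbone,
                 panel = sort(unique(c(tags$snp, backbone))),
                 r2_summary = c(max_backbone_r2 = bb_r2)),
            class = "tag_snp_panel")
}

#' Learn allele-defining SNP segments
#'
#' For each common allele the window is grown outward from its tag SNP
#' while the carrier-consensus pattern still covers at least `consensus`
#' of carrier haplotypes; extension side ties are broken toward the
#' window more centered on the tag. The final (largest) window is emitted
#' only if its pattern occurs on zero non-carrier training haplotypes;
#' otherwise the allele is reported as untaggable.
#'
#' @param haplotypes training haplotype matrix (chromosomes x SNPs).
#' @param hla per-haplotype truth labels (columns per gene).
#' @param panel a `tag_snp_panel`; alleles without an explicit tag are
#'   anchored at their max-r^2 panel SNP.
#' @param map the `region_map`.
#' @param consensus carrier-consensus coverage threshold (default 0.95).
#' @param min_carriers alleles with fewer carriers are skipped (warning).
#' @param artifact_budget phasing artifacts: a first pass tolerates up to
#'   this many non-carrier occurrences per window (default
#'   `max(2, 0.2%)` of non-carriers); chromosomes whose sequence matches
#'   an allele's core although their typing excludes that allele are
#'   discarded as mis-phased, and the final pass enforces strict
#'   zero-collision uniqueness on the cleaned training set. Set to 0 to
#'   disable the cleaning pass.
#' @return object of class `allele_segments`: list with `segments`
#'   (per-allele list: allele, gene, interval `[i, j)` in panel SNP
#'   indices, pattern string, carriers, coverage), `untaggable`, and
#'   `artifact_rows` (indices of training chromosomes discarded as phase
#'   artifacts).
#' @export
learn_allele_segments <- function(haplotypes, hla, panel, map,
                                  consensus = 0.95, min_carriers = 10L,
                                  artifact_budget = NULL) {
  haplotypes <- as.matrix(haplotypes)
  hla <- as.matrix(hla)
  if (is.null(artifact_budget))
    artifact_budget <- max(2L, round(0.002 * nrow(haplotypes)))
  pass1 <- .learn_segments_once(haplotypes, hla, panel, map, consensus,
                                min_carriers, allow = artifact_budget)
  drop <- unique(unlist(pass1$collisions))
  if (artifact_budget == 0L || length(drop) == 0L) {
    pass1$artifact_rows <- integer(0)
    pass1$collisions <- NULL
    return(pass1)
  }
  keep <- setdiff(seq_len(nrow(haplotypes)), drop)
  out <- .learn_segments_once(haplotypes[keep, , drop = FALSE],
                              hla[keep, , drop = FALSE], panel, map,
                              consensus, min_carriers, allow = 0L)
  out$artifact_rows <- drop
  out$collisions <- NULL
  out
}

.learn_segments_once <- function(haplotypes, hla, panel, map,
                                 consensus, min_carriers, allow = 0L) {
  m <- ncol(haplotypes)
  segments <- list(); untaggable <- character(0)
  collisions <- list()

  alleles <- list()
  for (g in .GENES) {
    tab <- table(hla[, g]); tab <- tab[names(tab) != "other"]
    for (al in names(tab)) alleles[[al]] <- list(gene = g, n = tab[[al]])
  }
  snp_pos <- map_snps(map)$pos
  grow_from <- function(tag, Hc, cons) {
    coverage <- function(l, r) {
      idx <- l:r
      mean(rowSums(Hc[, idx, drop = FALSE] !=
                     matrix(cons[idx], nrow(Hc), length(idx),
                            byrow = TRUE)) == 0)
    }
    l <- r <- tag
    if (coverage(l, r) < consensus) return(NULL)
    repeat {
      cl <- if (l > 1) coverage(l - 1L, r) else -1
      cr <- if (r < m) coverage(l, r + 1L) else -1
      okl <- cl >= consensus; okr <- cr >= consensus
      if (!okl && !okr) break
      if (okl && okr) {
        # prefer the extension keeping the window centered on the tag
        bal_l <- abs((tag - (l - 1L)) - (r - tag))
        bal_r <- abs((tag - l) - (r + 1L - tag))
        if (bal_l <= bal_r) l <- l - 1L else r <- r + 1L
      } else if (okl) l <- l - 1L else r <- r + 1L
    }
    list(l = l, r = r, coverage = coverage(l, r))
  }
  for (al in names(alleles)) {
    g <- alleles[[al]]$gene
    carriers <- which(hla[, g] == al)
    if (length(carriers) < min_carriers) {
      warning(sprintf("allele %s skipped: %d carriers < %d", al,
                      length(carriers), min_carriers))
      next
    }
    ind <- as.integer(hla[, g] == al)
    local <- which(abs(snp_pos - anchor_pos(map, g)) <= 6e5)
    r2v <- vapply(local, function(j) .haploid_r2(haplotypes[, j], ind),
                  numeric(1))
    # anchor at the panel tag when available, then fall back through the
    # next-best local SNPs: an anchor outside the carriers' conserved
    # core cannot grow a unique window
    cand <- local[order(-r2v)]
    tag0 <- panel$tags$snp[panel$tags$allele == al]
    if (length(tag0)) cand <- unique(c(tag0, cand))
    cand <- utils::head(cand, 6L)
    Hc <- haplotypes[carriers, , drop = FALSE]
    non <- setdiff(seq_len(nrow(haplotypes)), carriers)
    Hn <- haplotypes[non, , drop = FALSE]
    cons <- as.integer(colMeans(Hc) >= 0.5)
    found <- NULL
    for (tag in cand) {
      gw <- grow_from(tag, Hc, cons)
      if (is.null(gw)) next
      idx <- gw$l:gw$r
      pat <- cons[idx]
      hit_non <- rowSums(Hn[, idx, drop = FALSE] !=
                           matrix(pat, nrow(Hn), length(idx),
                                  byrow = TRUE)) == 0
      if (sum(hit_non) > allow) next
      if (any(hit_non))
        collisions[[al]] <- non[hit_non]
      found <- list(allele = al, gene = g,
                    interval = c(gw$l, gw$r + 1L), tag = tag,
                    pattern = pattern_string(pat),
                    carriers = length(carriers), coverage = gw$coverage)
      break
    }
    if (is.null(found)) untaggable <- c(untaggable, al)
    else segments[[al]] <- found
  }
  structure(list(segments = segments, untaggable = untaggable,
                 collisions = collisions),
            class = "allele_segments")
}

#' Impute HLA alleles on phased haplotypes
#'
#' A haplotype is called for an allele iff it matches that allele's
#' defining segment exactly. Matching no segment of a gene yields a
#' no-call; matching more than one segment of the same gene yields a
#' no-call with a conflict flag. Genes are called independently.
#'
#' @param haplotypes haplotype matrix (chromosomes x SNPs).
#' @param segments an `allele_segments` object.
#' @return object of class `hla_callset`: `calls` (chromosomes x genes
#'   character matrix, `NA` = no-call), `conflict` (logical matrix).
#' @export
impute_hla_alleles <- function(haplotypes, segments) {
  haplotypes <- as.matrix(haplotypes)
  nh <- nrow(haplotypes)
  calls <- matrix(NA_character_, nh, length(.GENES),
                  dimnames = list(NULL, .GENES))
  conflict <- matrix(FALSE, nh, length(.GENES),
                     dimnames = list(NULL, .GENES))
  for (seg in segments$segments) {
    idx <- seg$interval[1]:(seg$interval[2] - 1L)
    pat <- pattern_vector(seg$pattern)
    hit <- rowSums(haplotypes[, idx, drop = FALSE] !=
                     matrix(pat, nh, length(idx), byrow = TRUE)) == 0
    g <- seg$gene
    clash <- hit & !is.na(calls[, g])
    conflict[clash, g] <- TRUE
    calls[hit, g] <- seg$allele
  }
  calls[conflict] <- NA_character_
  structure(list(calls = calls, conflict = conflict),
            class = "hla_callset")
}

#' Assign per-gene typing labels to phased haplotypes
#'
#' Lab HLA typing yields an unordered allele pair per gene and individual.
#' Attaching those alleles to the two inferred haplotypes is done per
#' gene, by aligning the inferred pair to the truth pair over the SNPs
#' local to that gene's anchor (within `flank` bp), so that a switch
#' error far from the gene cannot swap its labels.
#'
#' @param phased_haps inferred haplotype matrix (2n x m).
#' @param truth_haps truth haplotype matrix (2n x m).
#' @param truth_hla per-truth-haplotype labels (2n x genes).
#' @param map the `region_map`.
#' @param flank half-width (bp) of the anchoring window per gene.
#' @return a 2n x genes character matrix of labels aligned to
#'   `phased_haps` rows.
#' @export
assign_typing_to_haplotypes <- function(phased_haps, truth_haps, truth_hla,
                                        map, flank = 5e5) {
  snp_pos <- map_snps(map)$pos
  n <- nrow(phased_haps) / 2L
  out <- as.matrix(truth_hla)
  for (g in .GENES) {
    ap <- anchor_pos(map, g)
    idx <- which(abs(snp_pos - ap) <= flank)
    if (length(idx) < 3L)
      idx <- order(abs(snp_pos - ap))[1:5]
    for (i in seq_len(n)) {
      r <- c(2L * i - 1L, 2L * i)
      straight <- sum(phased_haps[r[1], idx] != truth_haps[r[1], idx]) +
                  sum(phased_haps[r[2], idx] != truth_haps[r[2], idx])
      crossed  <- sum(phased_haps[r[1], idx] != truth_haps[r[2], idx]) +
                  sum(phased_haps[r[2], idx] != truth_haps[r[1], idx])
      if (crossed < straight)
        out[r, g] <- truth_hla[rev(r), g]
    }
  }
  out
}

#' Evaluate imputation performance
#'
#' Per-allele confusion counts and sensitivity / specificity / positive
#' predictive value on a chosen subset of haplotypes.
#'
#' @param callset an `hla_callset`.
#' @param truth per-haplotype truth labels (columns per gene).
#' @param subset integer or logical index of haplotype rows to evaluate.
#' @param label set label stored with the result ("training" or
#'   "validation").
#' @return data.frame with one row per allele: TP/FP/FN/TN, sensitivity,
#'   specificity, ppv, set.
#' @export
evaluate_imputation <- function(callset, truth, subset = NULL,
                                label = "training") {
  truth <- as.matrix(truth)
  calls <- callset$calls
  if (!is.null(subset)) {
    calls <- calls[subset, , drop = FALSE]
    truth <- truth[subset, , drop = FALSE]
  }
  if (nrow(calls) == 0) stop_stage("evaluate", "empty evaluation set")
  out <- list()
  for (g in .GENES) {
    alleles <- setdiff(unique(c(truth[, g], stats::na.omit(calls[, g]))),
                       c("other", NA))
    for (al in alleles) {
      is_c <- truth[, g] == al
      called <- !is.na(calls[, g]) & calls[, g] == al
      TP <- sum(is_c & called); FP <- sum(!is_c & called)
      FN <- sum(is_c & !called); TN <- sum(!is_c & !called)
      out[[length(out) + 1L]] <- data.frame(
        gene = g, allele = al, TP = TP, FP = FP, FN = FN, TN = TN,
        sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
        specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
        ppv = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
        set = label)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
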