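## End-to-end pipeline: simulate (or load) cohorts -> phase -> learn
## panel/segments on the typed training subset -> impute HLA alleles ->
## dissect extended vs recombinant haplotypes -> per-cohort, stratified
## and meta association -> stepwise conditional scan -> power table.

.hla_dosage <- function(calls, allele, gene) {
  nh <- nrow(calls)
  n <- nh / 2L
  called <- !is.na(calls[, gene])
  hit <- called & vapply(calls[, gene], allele_matches, logical(1),
                         want = allele)
  d <- hit[seq(1, nh, 2)] + hit[seq(2, nh, 2)]
  both_nc <- !called[seq(1, nh, 2)] & !called[seq(2, nh, 2)]
  d[both_nc] <- NA_integer_
  d
}

.class_dosage <- function(class_labels, which_class) {
  hit <- class_labels == which_class
  nh <- length(hit)
  hit[seq(1, nh, 2)] + hit[seq(2, nh, 2)]
}

# per-chromosome carrier indicator of "DRB1*0701 and DQB1*02"
.dr7dq2_indicator <- function(calls) {
  dr <- calls[, "HLA-DRB1"]; dq <- calls[, "HLA-DQB1"]
  ok <- !is.na(dr) & !is.na(dq)
  ok & dr == "DRB1*0701" & startsWith(ifelse(is.na(dq), "", dq), "DQB1*02")
}

.assoc_row <- function(per_cohort_tables, cohort_ns) {
  per <- lapply(per_cohort_tables, allele_association)
  ok <- vapply(per, function(x) !is.na(x$p) && x$p > 0, logical(1))
  meta <- if (any(ok))
    meta_weighted_z(
      vapply(per[ok], `[[`, numeric(1), "p"),
      vapply(per[ok], function(x) {
        lor <- log(x$or)
        if (!is.finite(lor) || lor == 0)
          if ((x$freq_case %||% 0) >= (x$freq_ctrl %||% 0)) 1 else -1
        else sign(lor)
      }, numeric(1)),
      cohort_ns[ok]) else NULL
  cmh <- cmh_combined(per_cohort_tables)
  list(per_cohort = per, meta = meta, cmh = cmh)
}

#' Run the full fine-mapping pipeline
#'
#' @param config a `pipeline_config`.
#' @param scenario optional scenario (list with `map`, `cohorts`) to use
#'   instead of the default one.
#' @return object of class `run_report`; see Details.
#'
#' @details The report contains `imputation_performance` (training and
#' validation), `dissection` (per family), `association` (per focal
#' allele and stratum: per-cohort results, CMH OR, combined p),
#' `conditional` (the stepwise scan), `power` (recombinant-haplotype
#' power table), `lambda_gc` (per cohort, SNP markers of the
#' unconditioned scan), and provenance (`seed`, `config`).
#' @export
run_pipeline <- function(config = pipeline_config(), scenario = NULL) {
  if (is.null(scenario))
    scenario <- build_default_scenario(
      recomb_prob = config$recomb_prob,
      missing_rate = config$missing_rate,
      typed_fraction = config$typed_fraction,
      seeds = config$seed * 10L + c(1L, 2L, 3L),
      null_effects = isTRUE(config$null_effects))
  sc_scale <- config$scale %||% 1
  if (sc_scale < 1)
    for (nm in names(scenario$cohorts)) {
      sp <- scenario$cohorts[[nm]]
      sp$n_cases <- max(40L, as.integer(round(sp$n_cases * sc_scale)))
      sp$n_controls <- max(60L, as.integer(round(sp$n_controls * sc_scale)))
      sp$validation_size <- max(8L, as.integer(round(79 * sc_scale / 3)))
      scenario$cohorts[[nm]] <- sp
    }
  map <- scenario$map

  # --- cohorts: simulate or load -------------------------------------
  cohorts <- list()
  if (!is.null(config$input_dir)) {
    dirs <- sort(list.dirs(config$input_dir, recursive = FALSE))
    if (!length(dirs))
      stop_stage("pipeline", "input_dir contains no cohort bundles")
    for (d in dirs) cohorts[[basename(d)]] <- read_cohort(d, map)
  } else {
    raw <- list()
    for (nm in names(scenario$cohorts))
      raw[[nm]] <- simulate_cohort(scenario$cohorts[[nm]], map)
    # one pooled validation set of 79 typed patients, allocated across
    # cohorts proportionally to their typed counts
    typed_n <- vapply(names(raw), function(nm)
      round(scenario$cohorts[[nm]]$typed_fraction *
              sum(raw[[nm]]$phenotype == "case")), numeric(1))
    val_total <- max(vapply(scenario$cohorts, `[[`, integer(1),
                            "validation_size"))
    val_alloc <- floor(val_total * typed_n / sum(typed_n))
    rem <- val_total - sum(val_alloc)
    if (rem > 0) {
      o <- order(-(val_total * typed_n / sum(typed_n) - val_alloc))
      val_alloc[o[seq_len(rem)]] <- val_alloc[o[seq_len(rem)]] + 1L
    }
    for (nm in names(raw))
      cohorts[[nm]] <- apply_missingness_and_typing(
        raw[[nm]], scenario$cohorts[[nm]],
        validation_size = val_alloc[[nm]])
  }

  # --- phasing -------------------------------------------------------
  phased <- lapply(cohorts, function(co)
    partition_ligation_phase(co$genotypes_obs))

  # --- typing labels aligned to phased haplotypes --------------------
  labels <- mapply(function(co, ph)
    assign_typing_to_haplotypes(ph$haplotypes, co$haplotypes,
                                co$truth_hla, map),
    cohorts, phased, SIMPLIFY = FALSE)

  hap_rows <- function(ind) c(rbind(2L * ind - 1L, 2L * ind))
  pool_rows <- function(which_mask) {
    out_h <- list(); out_l <- list()
    for (nm in names(cohorts)) {
      ind <- which(which_mask(cohorts[[nm]]))
      if (!length(ind)) next
      out_h[[nm]] <- phased[[nm]]$haplotypes[hap_rows(ind), , drop = FALSE]
      out_l[[nm]] <- labels[[nm]][hap_rows(ind), , drop = FALSE]
    }
    list(h = do.call(rbind, out_h), l = do.call(rbind, out_l))
  }
  train <- pool_rows(function(co) co$typed_mask & !co$validation_mask)
  valid <- pool_rows(function(co) co$validation_mask)
  ctrl <- pool_rows(function(co) co$phenotype == "control")

  # --- panel and allele-defining segments ----------------------------
  panel <- select_tag_snps(train$h, train$l, map,
                           r2_threshold = config$r2_threshold,
                           maf_min = config$maf_min,
                           control_haplotypes = ctrl$h)
  segments <- suppressWarnings(
    learn_allele_segments(train$h, train$l, panel, map,
                          consensus = config$consensus))

  # --- imputation and evaluation -------------------------------------
  calls <- lapply(phased, function(ph)
    impute_hla_alleles(ph$haplotypes, segments))
  eval_on <- function(pool, label) {
    cs <- structure(list(
      calls = impute_hla_alleles(pool$h, segments)$calls,
      conflict = NULL), class = "hla_callset")
    evaluate_imputation(cs, pool$l, NULL, label)
  }
  perf <- rbind(eval_on(train, "training"), eval_on(valid, "validation"))

  # --- dissection ----------------------------------------------------
  tpl <- scenario$cohorts[[1]]$templates
  tpl_by_name <- stats::setNames(tpl, vapply(tpl, `[[`, character(1),
                                             "name"))
  families <- list(
    DR3  = list(ref = "ext_DR3",  focal_gene = "HLA-DRB1"),
    DR7  = list(ref = "ext_DR7",  focal_gene = "HLA-DRB1"),
    DR1  = list(ref = "ext_DR1",  focal_gene = "HLA-DRB1"),
    DR15 = list(ref = "ext_DR15", focal_gene = "HLA-DRB1"))
  dcohorts <- lapply(names(cohorts), function(nm)
    list(haplotypes = phased[[nm]]$haplotypes,
         calls = calls[[nm]]$calls,
         phenotype = cohorts[[nm]]$phenotype))
  names(dcohorts) <- names(cohorts)
  dissection <- lapply(families, function(fam) {
    t <- tpl_by_name[[fam$ref]]
    ref <- reference_extended(
      paste(t$hla_alleles, collapse = "-"), t$hla_alleles, t$snp_pattern)
    dissect_focal_allele(dcohorts, ref, map, fam$focal_gene,
                         config$mismatch_tolerance)
  })

  # --- association tables (focal alleles + strata) -------------------
  cohort_ns <- vapply(cohorts, function(co) length(co$phenotype),
                      numeric(1))
  assoc <- list()
  focal_alleles <- list(c("HLA-DRB1", "DRB1*0301"),
                        c("HLA-DRB1", "DRB1*0701"),
                        c("HLA-DRB1", "DRB1*0102"),
                        c("HLA-DRB1", "DRB1*1501"),
                        c("HLA-DQB1", "DQB1*02"))
  for (fa in focal_alleles) {
    tabs <- lapply(names(cohorts), function(nm) {
      cs <- calls[[nm]]$calls
      called <- !is.na(cs[, fa[1]])
      hit <- called & vapply(cs[, fa[1]], allele_matches, logical(1),
                             want = fa[2])
      ph_hap <- rep(cohorts[[nm]]$phenotype, each = 2L)
      allele_counts(sum(hit & ph_hap == "case" & called),
                    sum(!hit & ph_hap == "case" & called),
                    sum(hit & ph_hap == "control" & called),
                    sum(!hit & ph_hap == "control" & called))
    })
    assoc[[fa[2]]] <- .assoc_row(tabs, cohort_ns)
  }
  for (fam in names(dissection)) {
    bc <- dissection[[fam]]$by_cohort
    for (stratum in c("extended", "recombinant")) {
      tabs <- lapply(names(cohorts), function(nm) {
        r <- bc[bc$cohort == nm & bc$stratum == stratum, ]
        allele_counts(r$case_carriers,
                      r$case_chromosomes - r$case_carriers,
                      r$control_carriers,
                      r$control_chromosomes - r$control_carriers)
      })
      assoc[[paste0(fam, ":", stratum)]] <- .assoc_row(tabs, cohort_ns)
    }
  }

  # --- marker dosages for the conditional scan -----------------------
  seg_alleles <- vapply(segments$segments, `[[`, character(1), "allele")
  seg_genes <- vapply(segments$segments, `[[`, character(1), "gene")
  build_dosages <- function(nm) {
    cs <- calls[[nm]]$calls
    cls <- lapply(dissection, function(d) d$classes[[nm]])
    g_imp <- phased[[nm]]$imputed_genotypes
    cols <- list()
    for (k in seq_along(seg_alleles))
      cols[[paste0("hla:", seg_alleles[k])]] <-
        .hla_dosage(cs, seg_alleles[k], seg_genes[k])
    for (fam in names(cls)) {
      cols[[paste0("hap:", fam, ":extended")]] <-
        .class_dosage(cls[[fam]], "extended")
      cols[[paste0("hap:", fam, ":recombinant")]] <-
        .class_dosage(cls[[fam]], "recombinant")
    }
    dr7 <- .dr7dq2_indicator(cs)
    cols[["hap:DR7-DQB1*02"]] <- dr7[seq(1, length(dr7), 2)] +
      dr7[seq(2, length(dr7), 2)]
    for (j in seq_len(ncol(g_imp)))
      cols[[paste0("snp:", map_snps(map)$locus_id[j])]] <- g_imp[, j]
    do.call(cbind, cols)
  }
  scan_cohorts <- lapply(names(cohorts), function(nm)
    list(dosages = build_dosages(nm),
         phenotype = cohorts[[nm]]$phenotype))
  names(scan_cohorts) <- names(cohorts)
  # SNPs are scanned but only HLA allele / haplotype markers may enter
  # the model as conditioning covariates
  mk <- colnames(scan_cohorts[[1]]$dosages)
  conditional <- stepwise_conditional(scan_cohorts,
                                      threshold = config$threshold,
                                      selectable = mk[!startsWith(mk, "snp:")])

  # --- genomic control (SNP markers, unconditioned scan) -------------
  lambda <- vapply(names(cohorts), function(nm) {
    d <- conditional$scans[[1]]$per_cohort[[nm]]
    chi2 <- d$z[startsWith(d$marker, "snp:")]^2
    genomic_inflation(chi2[!is.na(chi2)], min_values = 30L)
  }, numeric(1))

  # --- power table ----------------------------------------------------
  power_rows <- do.call(rbind, lapply(names(dissection), function(fam) {
    bc <- dissection[[fam]]$by_cohort
    rec <- bc[bc$stratum == "recombinant", ]
    ext_or <- assoc[[paste0(fam, ":extended")]]$cmh$or_cmh
    data.frame(haplotype = paste0("recombinant-", fam),
               ctrl_freq = sum(rec$control_carriers) /
                 sum(rec$control_chromosomes),
               grr = ext_or)
  }))
  power <- power_table(power_rows,
                       n_cases = sum(vapply(cohorts, function(co)
                         sum(co$phenotype == "case"), numeric(1))),
                       n_controls = sum(vapply(cohorts, function(co)
                         sum(co$phenotype == "control"), numeric(1))),
                       alphas = config$alphas)

  report <- structure(list(
    map = map, config = config, seed = config$seed,
    cohorts = cohorts, phased = phased, labels = labels,
    panel = panel, segments = segments, calls = calls,
    imputation_performance = perf,
    dissection = dissection, association = assoc,
    conditional = conditional, lambda_gc = lambda, power = power,
    version = as.character(utils::packageVersion("hladissect"))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write report tables to a directory
#'
#' @param report a `run_report`.
#' @param dir output directory (created).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(report$imputation_performance, "imputation_performance.tsv")
  wt(do.call(rbind, lapply(report$dissection, `[[`, "summary")),
     "dissection_summary.tsv")
  wt(do.call(rbind, lapply(names(report$dissection), function(f)
    cbind(family = f, report$dissection[[f]]$by_cohort))),
    "dissection_by_cohort.tsv")
  assoc_df <- do.call(rbind, lapply(names(report$association),
                                    function(nm) {
    a <- report$association[[nm]]
    data.frame(marker = nm,
               or_cmh = a$cmh$or_cmh,
               ci_lo = a$cmh$ci_lo, ci_hi = a$cmh$ci_hi,
               p_combined = if (!is.null(a$meta)) a$meta$p_combined
                            else NA_real_)
  }))
  wt(assoc_df, "association_combined.tsv")
  wt(report$conditional$steps, "conditional_steps.tsv")
  wt(report$power, "power_table.tsv")
  wt(data.frame(cohort = names(report$lambda_gc),
                lambda_gc = report$lambda_gc), "lambda_gc.tsv")
  wt(data.frame(seed = report$seed, version = report$version),
     "provenance.tsv")
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", length(x$cohorts), "cohorts,",
      nrow(x$conditional$steps), "conditional steps\n")
  cat("lambda_gc:", paste(sprintf("%s=%.3f", names(x$lambda_gc),
                                  x$lambda_gc), collapse = ", "), "\n")
  invisible(x)
}
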