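## Allele- and haplotype-based association statistics: 1-df chi-square
## tests on 2x2 allele-count tables, Cochran-Mantel-Haenszel pooling with
## Robins-Breslow-Greenland confidence intervals, sample-size-weighted
## z-score meta-analysis, genomic-control inflation, logistic regression
## scans and the stepwise conditional search for independent signals.

#' Build a 2x2 allele-count table from printed frequencies
#'
#' Reconstructs carrier / non-carrier chromosome counts from published
#' allele frequencies and sample sizes: `a = round(freq_case * 2 *
#' n_cases)` etc., with half-away-from-zero rounding.
#'
#' @param freq_case,freq_ctrl allele frequencies in cases and controls.
#' @param n_cases,n_controls individuals per group.
#' @return object of class `allele_counts`: list with `a` (case
#'   carriers), `b` (case non-carriers), `c` (control carriers), `d`
#'   (control non-carriers).
#' @export
counts_from_freqs <- function(freq_case, freq_ctrl, n_cases, n_controls) {
  stopifnot(freq_case >= 0, freq_case <= 1, freq_ctrl >= 0, freq_ctrl <= 1)
  a <- round_half_up(freq_case * 2 * n_cases)
  c_ <- round_half_up(freq_ctrl * 2 * n_controls)
  allele_counts(a, 2 * n_cases - a, c_, 2 * n_controls - c_)
}

#' Construct a 2x2 allele-count table
#' @param a,b carrier / non-carrier chromosomes in cases.
#' @param c,d carrier / non-carrier chromosomes in controls.
#' @return object of class `allele_counts`.
#' @export
allele_counts <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  structure(list(a = a, b = b, c = c, d = d), class = "allele_counts")
}

#' Allele-based association test on a 2x2 table
#'
#' Pearson 1-degree-of-freedom chi-square without continuity correction,
#' comparing allele frequency between case and control chromosomes; odds
#' ratio `ad/bc` with a Woolf (log-OR) 95% confidence interval.
#'
#' @param table an `allele_counts` object.
#' @return object of class `assoc_result`: freq_case, freq_ctrl, chi2,
#'   p (two-tailed), or, ci_lo, ci_hi, or_defined flag.
#' @export
allele_association <- function(table) {
  a <- as.numeric(table$a); b <- as.numeric(table$b)
  c_ <- as.numeric(table$c); d <- as.numeric(table$d)
  n1 <- a + b; n2 <- c_ + d
  m1 <- a + c_; m2 <- b + d
  N <- n1 + n2
  chi2 <- if (n1 > 0 && n2 > 0 && m1 > 0 && m2 > 0)
    N * (a * d - b * c_)^2 / (n1 * n2 * m1 * m2) else NA_real_
  p <- if (!is.na(chi2)) stats::pchisq(chi2, 1, lower.tail = FALSE)
       else NA_real_
  or_defined <- all(c(a, b, c_, d) > 0)
  or <- if (or_defined) (a * d) / (b * c_) else NA_real_
  se <- if (or_defined) sqrt(1 / a + 1 / b + 1 / c_ + 1 / d) else NA_real_
  structure(list(
    freq_case = if (n1 > 0) a / n1 else NA_real_,
    freq_ctrl = if (n2 > 0) c_ / n2 else NA_real_,
    chi2 = chi2, p = p, or = or,
    ci_lo = if (or_defined) exp(log(or) - 1.959964 * se) else NA_real_,
    ci_hi = if (or_defined) exp(log(or) + 1.959964 * se) else NA_real_,
    or_defined = or_defined, counts = table),
    class = "assoc_result")
}

#' Haplotype-based association test
#'
#' Tests one haplotype label against all other haplotypes combined.
#'
#' @param labels character vector of per-chromosome haplotype labels.
#' @param phenotype per-chromosome "case"/"control" vector (same length).
#' @param focal the haplotype label to test.
#' @return an `assoc_result`.
#' @export
haplotype_association <- function(labels, phenotype, focal) {
  stopifnot(length(labels) == length(phenotype))
  if (!any(labels == focal, na.rm = TRUE))
    stop_stage("assoc", sprintf("focal label '%s' absent", focal))
  keep <- !is.na(labels)
  labels <- labels[keep]; phenotype <- phenotype[keep]
  is_f <- labels == focal
  is_ca <- phenotype == "case"
  allele_association(allele_counts(
    sum(is_f & is_ca), sum(!is_f & is_ca),
    sum(is_f & !is_ca), sum(!is_f & !is_ca)))
}

#' Cochran-Mantel-Haenszel combined odds ratio
#'
#' Common odds ratio over strata, `sum(a_i d_i / N_i) / sum(b_i c_i /
#' N_i)`, with a Robins-Breslow-Greenland 95% confidence interval.
#'
#' @param tables list of `allele_counts`, one per stratum.
#' @return object of class `stratified_assoc`: or_cmh, ci_lo, ci_hi,
#'   or_defined, per-stratum tables.
#' @export
cmh_combined <- function(tables) {
  stopifnot(length(tables) >= 1)
  R <- S <- 0
  sPR <- sPSQR <- sQS <- 0
  for (t in tables) {
    N <- t$a + t$b + t$c + t$d
    if (N == 0) next
    Ri <- t$a * t$d / N; Si <- t$b * t$c / N
    Pi <- (t$a + t$d) / N; Qi <- (t$b + t$c) / N
    R <- R + Ri; S <- S + Si
    sPR <- sPR + Pi * Ri
    sPSQR <- sPSQR + Pi * Si + Qi * Ri
    sQS <- sQS + Qi * Si
  }
  or_defined <- R > 0 && S > 0
  or <- if (or_defined) R / S else NA_real_
  if (or_defined) {
    v <- sPR / (2 * R^2) + sPSQR / (2 * R * S) + sQS / (2 * S^2)
    lo <- exp(log(or) - 1.959964 * sqrt(v))
    hi <- exp(log(or) + 1.959964 * sqrt(v))
  } else lo <- hi <- NA_real_
  structure(list(or_cmh = or, ci_lo = lo, ci_hi = hi,
                 or_defined = or_defined, tables = tables),
            class = "stratified_assoc")
}

#' Sample-size-weighted z-score meta-analysis
#'
#' Per-cohort two-tailed p values are converted to signed z-scores and
#' combined as `sum(z_i * sqrt(N_i)) / sqrt(sum(N_i))`; the combined p is
#' the two-tailed normal tail of the combined z.
#'
#' @param p vector of per-cohort two-tailed p values in (0, 1].
#' @param sign vector of effect direction signs (+1 / -1), relative to a
#'   common reference allele.
#' @param n per-cohort sample sizes used as weights.
#' @return object of class `meta_result`: z (per-cohort), z_combined,
#'   p_combined, weights.
#' @export
meta_weighted_z <- function(p, sign, n) {
  stopifnot(length(p) == length(sign), length(p) == length(n))
  if (any(p <= 0)) stop_stage("meta", "p = 0 not representable; supply z")
  stopifnot(all(p <= 1), all(sign %in% c(-1, 1)), all(n > 0))
  z <- sign * stats::qnorm(p / 2, lower.tail = FALSE)
  zc <- sum(z * sqrt(n)) / sqrt(sum(n))
  structure(list(z = z, weights = sqrt(n), z_combined = zc,
                 p_combined = 2 * stats::pnorm(abs(zc), lower.tail = FALSE)),
            class = "meta_result")
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chi2) / qchisq(0.5, 1)` over null-region 1-df test
#' statistics.
#'
#' @param chi2 vector of 1-df chi-square statistics (HLA region excluded
#'   by the caller).
#' @param min_values minimum number of statistics required (default 100).
#' @return lambda (numeric).
#' @export
genomic_inflation <- function(chi2, min_values = 100L) {
  chi2 <- chi2[!is.na(chi2)]
  if (length(chi2) < min_values)
    stop_stage("lambda", sprintf("need >= %d chi-square values, got %d",
                                 min_values, length(chi2)))
  stats::median(chi2) / stats::qchisq(0.5, df = 1)
}

#' Logistic regression scan over markers
#'
#' Fits `phenotype ~ marker + covariates` per marker by IRLS (binomial
#' logit) and reports the Wald test on the marker term. Markers collinear
#' with the covariates are flagged and get no p value; non-convergence
#' and separation are flagged.
#'
#' @param dosages n x k matrix of marker dosages in 0/1/2 (`NA` allowed;
#'   rows with `NA` are dropped per marker).
#' @param phenotype length-n vector, "case"/"control" or 0/1.
#' @param covariates optional n x c matrix of covariate dosages.
#' @return data.frame per marker: beta, se, z, p, n, flag
#'   ("" | "collinear" | "separation" | "no_convergence").
#' @export
logistic_scan <- function(dosages, phenotype, covariates = NULL) {
  dosages <- as.matrix(dosages)
  y <- if (is.character(phenotype) || is.factor(phenotype))
    as.integer(as.character(phenotype) == "case") else as.integer(phenotype)
  n <- length(y)
  stopifnot(nrow(dosages) == n)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
  }
  k <- ncol(dosages)
  out <- data.frame(marker = colnames(dosages) %||% paste0("m", seq_len(k)),
                    beta = NA_real_, se = NA_real_, z = NA_real_,
                    p = NA_real_, n = NA_integer_, flag = "",
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    x <- dosages[, j]
    keep <- !is.na(x) & !is.na(y)
    if (!is.null(covariates))
      keep <- keep & stats::complete.cases(covariates)
    X <- cbind(1, if (!is.null(covariates)) covariates[keep, , drop = FALSE],
               x[keep])
    out$n[j] <- sum(keep)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) { out$flag[j] <- "collinear"; next }
    fit <- suppressWarnings(
      stats::glm.fit(X, y[keep], family = stats::binomial()))
    cf <- fit$coefficients
    beta <- cf[length(cf)]
    if (!fit$converged) { out$flag[j] <- "no_convergence"; next }
    mu <- fit$fitted.values
    if (abs(beta) > 15 || any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
      out$flag[j] <- "separation"; next
    }
    W <- mu * (1 - mu)
    XtWX <- crossprod(X * sqrt(W))
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(cov)) { out$flag[j] <- "collinear"; next }
    se <- sqrt(diag(cov))[length(cf)]
    out$beta[j] <- beta; out$se[j] <- se
    out$z[j] <- beta / se
    out$p[j] <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  }
  out
}

#' Stepwise conditional scan for independent signals
#'
#' Step 0 is the unconditioned per-cohort scan; at each step the marker
#' with the smallest meta-combined p (weighted z-score meta over cohorts,
#' direction from each cohort's beta) is added as a covariate in every
#' cohort and the scan repeats, until no remaining marker reaches
#' `threshold` (default genome-wide 5e-8). Markers duplicating an
#' already-selected dosage column are treated as aliases and skipped.
#'
#' @param cohorts named list; each element a list with `dosages` (n x k,
#'   identical marker columns across cohorts), `phenotype`.
#' @param threshold combined-p selection threshold.
#' @param max_steps safety cap on steps.
#' @param selectable optional character vector of marker names eligible
#'   for selection as conditioning covariates (default: all markers).
#'   Test SNPs are typically scanned but never conditioned on; only the
#'   top residual HLA allele/haplotype enters the model.
#' @return object of class `conditional_scan`: `steps` (data.frame of
#'   selected marker, combined p per step), `scans` (list of per-step
#'   per-marker meta results), `aliases`.
#' @export
stepwise_conditional <- function(cohorts, threshold = 5e-8,
                                 max_steps = 10L, selectable = NULL) {
  stopifnot(length(cohorts) >= 1)
  markers <- colnames(cohorts[[1]]$dosages)
  if (is.null(markers) || length(markers) == 0)
    stop_stage("stepwise", "empty marker set")
  ns <- vapply(cohorts, function(ch) length(ch$phenotype), numeric(1))
  selected <- character(0)
  scans <- list(); steps <- list()
  meta_scan <- function(sel) {
    per <- lapply(cohorts, function(ch) {
      cov <- if (length(sel))
        ch$dosages[, sel, drop = FALSE] else NULL
      logistic_scan(ch$dosages, ch$phenotype, covariates = cov)
    })
    comb <- data.frame(marker = markers, p_combined = NA_real_,
                       z_combined = NA_real_, flag = "",
                       stringsAsFactors = FALSE)
    for (j in seq_along(markers)) {
      ps <- vapply(per, function(d) d$p[j], numeric(1))
      zs <- vapply(per, function(d) d$beta[j], numeric(1))
      fl <- vapply(per, function(d) d$flag[j], character(1))
      ok <- !is.na(ps) & fl == ""
      if (!any(ok)) { comb$flag[j] <- paste(unique(fl), collapse = "+"); next }
      mr <- meta_weighted_z(pmax(ps[ok], 1e-300), ifelse(zs[ok] >= 0, 1, -1),
                            ns[ok])
      comb$p_combined[j] <- mr$p_combined
      comb$z_combined[j] <- mr$z_combined
    }
    list(per_cohort = per, combined = comb)
  }
  # alias detection: identical dosage columns (pooled over cohorts)
  pooled <- do.call(rbind, lapply(cohorts, function(ch) ch$dosages))
  keyof <- apply(pooled, 2, function(col) paste(col, collapse = ","))
  aliases <- split(markers, keyof)
  primary <- vapply(aliases, `[[`, character(1), 1L)
  is_alias <- !(markers %in% primary)

  for (step in seq_len(max_steps)) {
    sc <- meta_scan(selected)
    scans[[step]] <- sc
    cand <- sc$combined
    cand <- cand[!(cand$marker %in% selected) & !is_alias[match(cand$marker, markers)], ]
    if (!is.null(selectable))
      cand <- cand[cand$marker %in% selectable, ]
    cand <- cand[!is.na(cand$p_combined), ]
    if (!nrow(cand)) break
    best <- cand[which.min(cand$p_combined), ]
    if (best$p_combined >= threshold) break
    selected <- c(selected, best$marker)
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(selected), marker = best$marker,
      p_combined = best$p_combined)
  }
  structure(list(
    steps = if (length(steps)) do.call(rbind, steps)
            else data.frame(step = integer(0), marker = character(0),
                            p_combined = numeric(0)),
    scans = scans,
    aliases = aliases[vapply(aliases, length, integer(1)) > 1]),
    class = "conditional_scan")
}
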