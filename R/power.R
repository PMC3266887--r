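## Analytic power for single-stage case-control allele tests under a
## multiplicative disease model.
##
## The per-copy genotype relative risk (GRR) is identified with the
## allele odds ratio (exact under multiplicative risk in the rare-disease
## limit). Expected case and control allele frequencies follow from HWE
## genotype frequencies and the penetrances f0, f0*r, f0*r^2 with f0
## calibrated so that population prevalence equals K; power of the
## two-sided 1-df allele test uses the normal approximation with the
## null-variance threshold and alternative-variance shift on 2n
## chromosomes.

#' Construct a multiplicative disease model
#'
#' @param p population risk-allele frequency in (0, 1).
#' @param r per-copy genotype relative risk (> 0).
#' @param K population prevalence (default 0.002, i.e. 1 in 500).
#' @return object of class `disease_model` with penetrances `f0`,
#'   `f0*r`, `f0*r^2`.
#' @export
disease_model <- function(p, r, K = 0.002) {
  stopifnot(p > 0, p < 1, r > 0, K > 0, K < 1)
  denom <- (1 - p)^2 + 2 * p * (1 - p) * r + p^2 * r^2
  f0 <- K / denom
  pen <- f0 * c(1, r, r^2)
  if (any(pen <= 0) || any(pen > 1))
    stop_stage("power", "penetrances outside (0, 1]")
  structure(list(p = p, r = r, K = K, f0 = f0, penetrances = pen),
            class = "disease_model")
}

#' GRR from observed case/control allele frequencies
#'
#' The allele odds ratio, used as the per-copy genotype relative risk of
#' a haplotype; valid under multiplicative risk for a rare disease.
#'
#' @param freq_case,freq_ctrl allele frequencies strictly inside (0, 1).
#' @return the GRR estimate.
#' @export
grr_from_observed <- function(freq_case, freq_ctrl) {
  if (freq_case <= 0 || freq_case >= 1 || freq_ctrl <= 0 || freq_ctrl >= 1)
    stop_stage("power", "frequencies must be strictly inside (0, 1)")
  (freq_case / (1 - freq_case)) / (freq_ctrl / (1 - freq_ctrl))
}

#' Expected case and control allele frequencies under a disease model
#'
#' Bayes inversion of HWE genotype frequencies through the penetrances.
#'
#' @param model a `disease_model`.
#' @return list with `freq_case`, `freq_ctrl`.
#' @export
expected_case_control_freqs <- function(model) {
  p <- model$p; r <- model$r; K <- model$K; f0 <- model$f0
  g <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  pen <- model$penetrances
  case_geno <- g * pen / K
  ctrl_geno <- g * (1 - pen) / (1 - K)
  list(freq_case = case_geno[2] / 2 + case_geno[3],
       freq_ctrl = ctrl_geno[2] / 2 + ctrl_geno[3])
}

#' Analytic power of the single-stage allele test
#'
#' Two-sided 1-df allele-frequency comparison on 2n chromosomes: normal
#' approximation with pooled-frequency null SE and alternative SE.
#'
#' @param n_cases,n_controls individuals per group.
#' @param model a `disease_model`.
#' @param alpha significance level in (0, 1).
#' @return power in `[0, 1]`.
#' @export
power_single_stage <- function(n_cases, n_controls, model, alpha) {
  stopifnot(alpha > 0, alpha < 1, n_cases > 0, n_controls > 0)
  fr <- expected_case_control_freqs(model)
  p1 <- fr$freq_case; p2 <- fr$freq_ctrl
  m1 <- 2 * n_cases; m2 <- 2 * n_controls
  pbar <- (m1 * p1 + m2 * p2) / (m1 + m2)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / m1 + 1 / m2))
  se1 <- sqrt(p1 * (1 - p1) / m1 + p2 * (1 - p2) / m2)
  za <- stats::qnorm(1 - alpha / 2)
  d <- p1 - p2
  pow <- stats::pnorm((d - za * se0) / se1) +
         stats::pnorm((-d - za * se0) / se1)
  min(max(pow, 0), 1)
}

#' Power table over dissection rows
#'
#' For each recombinant haplotype row the GRR is transferred from its
#' extended counterpart (allele odds ratio of the extended case/control
#' frequencies, or a supplied `grr` column), and power is evaluated at
#' the recombinant's control frequency for each alpha.
#'
#' @param rows data.frame with columns `haplotype`, `ctrl_freq`
#'   (recombinant control frequency) and either `grr` or both
#'   `ext_freq_case` and `ext_freq_ctrl`.
#' @param n_cases,n_controls combined study size.
#' @param alphas significance grid (default 0.05, 0.01, 5e-5, 5e-8).
#' @param K population prevalence.
#' @return data.frame: haplotype, ctrl_freq, grr, one power column per
#'   alpha (`power_<alpha>`); rows with missing inputs are skipped with a
#'   warning.
#' @export
power_table <- function(rows, n_cases, n_controls,
                        alphas = c(0.05, 0.01, 5e-5, 5e-8), K = 0.002) {
  out <- list()
  for (i in seq_len(nrow(rows))) {
    row <- rows[i, ]
    grr <- if (!is.null(row$grr) && !is.na(row$grr)) row$grr
           else if (!is.null(row$ext_freq_case) &&
                    !is.na(row$ext_freq_case) &&
                    !is.na(row$ext_freq_ctrl))
             grr_from_observed(row$ext_freq_case, row$ext_freq_ctrl)
           else NA_real_
    if (is.na(grr) || is.na(row$ctrl_freq) ||
        row$ctrl_freq <= 0 || row$ctrl_freq >= 1) {
      warning(sprintf("power row '%s' skipped: missing frequencies",
                      row$haplotype))
      next
    }
    model <- disease_model(row$ctrl_freq, grr, K)
    pw <- vapply(alphas, function(a)
      power_single_stage(n_cases, n_controls, model, a), numeric(1))
    rec <- data.frame(haplotype = row$haplotype, ctrl_freq = row$ctrl_freq,
                      grr = grr)
    for (k in seq_along(alphas))
      rec[[paste0("power_", format(alphas[k], scientific = TRUE))]] <- pw[k]
    out[[length(out) + 1L]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
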