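## Long-range haplotype phasing by maximum-likelihood EM with partition
## ligation.
##
## The classical Bayesian-coalescent phaser is replaced by a deterministic
## EM over haplotype frequencies: genotypes are split into small windows
## (<= 12 SNPs), each window is phased by EM with missing genotypes summed
## over compatible completions, and adjacent windows are ligated by
## re-running EM over concatenations of the retained frequent patterns.
## Adequate in the strong-LD regime of the MHC and fully reproducible.

.MAX_WINDOW <- 12L
.PAIR_EXPANSION_CAP <- 65536L

# Enumerate ordered compatible haplotype pairs for one genotype row.
# Haplotypes are coded as integers (bit i = SNP i, LSB = first SNP).
# Returns a two-column matrix (h1, h2) of integer codes.
.compatible_pairs <- function(g) {
  w <- length(g)
  opts <- lapply(seq_len(w), function(j) {
    if (is.na(g[j])) cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
    else if (g[j] == 0L) cbind(0L, 0L)
    else if (g[j] == 2L) cbind(1L, 1L)
    else if (g[j] == 1L) cbind(c(0L, 1L), c(1L, 0L))
    else stop("invalid genotype code: ", g[j])
  })
  total <- prod(vapply(opts, nrow, numeric(1)))
  if (total > .PAIR_EXPANSION_CAP)
    stop_stage("phase", "too many compatible completions for one genotype")
  h1 <- 0L; h2 <- 0L
  for (j in seq_len(w)) {
    o <- opts[[j]]
    k <- nrow(o)
    h1 <- rep(h1, each = k) + rep(o[, 1], times = length(h1)) * 2L^(j - 1L)
    h2 <- rep(h2, each = k) + rep(o[, 2], times = length(h2)) * 2L^(j - 1L)
  }
  cbind(h1, h2)
}

.code_to_pattern <- function(code, w) {
  vapply(seq_len(w), function(j) bitwAnd(code %/% 2L^(j - 1L), 1L),
         integer(1))
}

# Shared EM engine over per-individual candidate pair sets.
# pairs: data.frame with columns ind, a, b (indices into the haplotype
# registry). Returns frequencies, per-pair posteriors and loglik trace.
.em_pairs <- function(pairs, n_hap, n_ind, tol = 1e-6, max_iter = 500L,
                      init = NULL) {
  f <- if (is.null(init)) rep(1 / n_hap, n_hap) else init / sum(init)
  ord_w <- ifelse(pairs$a == pairs$b, 1, 2)  # unordered pair weight
  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    lik <- ord_w * f[pairs$a] * f[pairs$b]
    tot <- rowsum(lik, pairs$ind)[, 1]
    ll <- sum(log(pmax(tot, 1e-300)))
    loglik <- c(loglik, ll)
    post <- lik / tot[match(pairs$ind, sort(unique(pairs$ind)))]
    cnt <- rowsum(c(post, post), c(pairs$a, pairs$b))
    newf <- rep(0, n_hap)
    newf[as.integer(rownames(cnt))] <- cnt[, 1]
    newf <- newf / (2 * n_ind)
    delta <- max(abs(newf - f))
    f <- newf
    if (delta < tol) break
  }
  lik <- ord_w * f[pairs$a] * f[pairs$b]
  tot <- rowsum(lik, pairs$ind)[, 1]
  post <- lik / tot[match(pairs$ind, sort(unique(pairs$ind)))]
  list(freq = f, post = post, loglik = loglik, n_iter = length(loglik))
}

#' EM phasing of a single SNP window
#'
#' Estimates haplotype frequencies in a window of at most 12 SNPs by EM
#' over all genotype-compatible haplotype pairs (missing genotypes are
#' summed over their compatible completions), and returns per-individual
#' posterior distributions over unordered compatible pairs.
#'
#' @param genotypes n x w matrix of 0/1/2/NA genotype codes.
#' @param tol EM convergence tolerance on max frequency change.
#' @param max_iter maximum EM iterations.
#' @param floor frequency floor below which patterns are dropped from the
#'   returned frequency table; default `1/(4n)`.
#' @return list with `freq_table` (data.frame pattern/frequency, pruned at
#'   the floor and renormalized), `pairs` (per-individual data.frame of
#'   unordered pattern pairs and posteriors), `loglik` (EM trace),
#'   `errors` (row indices with invalid genotype codes).
#' @export
em_phase_window <- function(genotypes, tol = 1e-6, max_iter = 500L,
                            floor = NULL) {
  genotypes <- as.matrix(genotypes)
  w <- ncol(genotypes); n <- nrow(genotypes)
  if (w > .MAX_WINDOW)
    stop_stage("phase", sprintf("window of %d SNPs exceeds limit %d",
                                w, .MAX_WINDOW))
  stopifnot(n >= 1)
  bad <- which(apply(genotypes, 1, function(g)
    any(!is.na(g) & !(g %in% c(0L, 1L, 2L)))))
  rows <- setdiff(seq_len(n), bad)
  plist <- lapply(rows, function(i) .compatible_pairs(genotypes[i, ]))
  codes <- sort(unique(unlist(lapply(plist, as.vector))))
  pairs <- do.call(rbind, lapply(seq_along(plist), function(k) {
    pm <- plist[[k]]
    # canonical unordered pairs
    lo <- pmin(pm[, 1], pm[, 2]); hi <- pmax(pm[, 1], pm[, 2])
    u <- unique(cbind(lo, hi))
    data.frame(ind = k, a = match(u[, 1], codes), b = match(u[, 2], codes))
  }))
  em <- .em_pairs(pairs, length(codes), length(rows),
                  tol = tol, max_iter = max_iter)
  if (is.null(floor)) floor <- 1 / (4 * max(length(rows), 1L))
  pat <- vapply(codes, function(cd)
    pattern_string(.code_to_pattern(cd, w)), character(1))
  keep <- em$freq > floor
  ft <- data.frame(pattern = pat[keep], frequency = em$freq[keep])
  ft$frequency <- ft$frequency / sum(ft$frequency)
  ft <- ft[order(-ft$frequency), , drop = FALSE]
  rownames(ft) <- NULL
  pairs$pattern1 <- pat[pairs$a]
  pairs$pattern2 <- pat[pairs$b]
  pairs$posterior <- em$post
  pairs$ind <- rows[pairs$ind]
  list(freq_table = ft,
       pairs = pairs[, c("ind", "pattern1", "pattern2", "posterior")],
       loglik = em$loglik, errors = bad)
}

# Keep the strongest candidate pairs per individual.
.prune_pairs <- function(df, keep = 20L, min_post = 0) {
  out <- lapply(split(df, df$ind), function(d) {
    d <- d[order(-d$posterior), , drop = FALSE]
    sel <- d$posterior >= min_post
    sel[1] <- TRUE
    d <- d[sel, , drop = FALSE]
    utils::head(d, keep)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# Re-run EM over per-individual candidate pattern pairs (patterns are
# strings of arbitrary length). Used by the ligation steps.
.em_string_pairs <- function(df, n_ind, tol, max_iter, top_patterns) {
  pats <- sort(unique(c(df$pattern1, df$pattern2)))
  a <- match(df$pattern1, pats); b <- match(df$pattern2, pats)
  init <- rep(0, length(pats))
  wsum <- rowsum(c(df$posterior, df$posterior), c(a, b))
  init[as.integer(rownames(wsum))] <- wsum[, 1]
  # retain only the most frequent patterns; individuals whose candidate
  # pairs all involve rarer patterns keep their full pair set, so the EM
  # (not list order) decides between tied join orientations
  if (length(pats) > top_patterns) {
    keep <- rank(-init, ties.method = "first") <= top_patterns
    ok <- keep[a] | keep[b]  # the rarer side is the forced complement
    dead <- setdiff(unique(df$ind), unique(df$ind[ok]))
    ok[df$ind %in% dead] <- TRUE
    df <- df[ok, , drop = FALSE]
    pats <- sort(unique(c(df$pattern1, df$pattern2)))
    a <- match(df$pattern1, pats); b <- match(df$pattern2, pats)
    init <- rep(0, length(pats))
    wsum <- rowsum(c(df$posterior, df$posterior), c(a, b))
    init[as.integer(rownames(wsum))] <- wsum[, 1]
  }
  pairs <- data.frame(ind = match(df$ind, sort(unique(df$ind))), a = a, b = b)
  em <- .em_pairs(pairs, length(pats), n_ind, tol = tol,
                  max_iter = max_iter, init = init + 1e-9)
  df$posterior <- em$post
  list(df = df, freq = data.frame(pattern = pats, frequency = em$freq))
}

#' Phase a cohort by partition-ligation EM
#'
#' Splits the SNPs into consecutive windows of at most `window_size`,
#' EM-phases each window, then ligates adjacent blocks left to right by
#' EM over concatenations of the surviving candidate pairs (the most
#' frequent `top_patterns` patterns are retained per ligation). Missing
#' genotypes are imputed from the best-guess haplotype pair and flagged.
#'
#' @param genotypes n x m matrix of 0/1/2/NA genotype codes.
#' @param window_size maximum SNPs per window (<= 12).
#' @param top_patterns patterns retained per ligation step.
#' @param tol,max_iter EM controls.
#' @param pair_keep candidate pairs retained per individual between steps.
#' @return an object of class `phased_cohort`: `haplotypes` (2n x m 0/1
#'   matrix, rows 2i-1 and 2i for individual i, within-individual order
#'   canonicalized lexicographically), `certainty` (posterior probability
#'   of the reported pair), `imputed_flags` (n x m logical), `freq_table`
#'   of full-length haplotypes, `errors`.
#' @export
partition_ligation_phase <- function(genotypes, window_size = 8L,
                                     top_patterns = 30L, tol = 1e-6,
                                     max_iter = 500L, pair_keep = 20L) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes); m <- ncol(genotypes)
  if (n < 2L) stop_stage("phase", "need at least 2 individuals")
  if (window_size > .MAX_WINDOW)
    stop_stage("phase", "window_size exceeds limit")
  n_win <- ceiling(m / window_size)
  bounds <- round(seq(0L, m, length.out = n_win + 1L))
  wins <- lapply(seq_len(n_win), function(k) (bounds[k] + 1L):bounds[k + 1L])

  errors <- integer(0)
  blocks <- lapply(wins, function(idx) {
    res <- em_phase_window(genotypes[, idx, drop = FALSE],
                           tol = tol, max_iter = max_iter)
    errors <<- union(errors, res$errors)
    .prune_pairs(res$pairs, keep = 2L * pair_keep)
  })

  cur <- blocks[[1]]
  if (n_win > 1L) for (k in 2L:n_win) {
    nxt <- blocks[[k]]
    merged <- merge(cur, nxt, by = "ind", suffixes = c(".L", ".R"))
    straight <- data.frame(
      ind = merged$ind,
      pattern1 = paste0(merged$pattern1.L, merged$pattern1.R),
      pattern2 = paste0(merged$pattern2.L, merged$pattern2.R),
      posterior = merged$posterior.L * merged$posterior.R)
    crossed <- data.frame(
      ind = merged$ind,
      pattern1 = paste0(merged$pattern1.L, merged$pattern2.R),
      pattern2 = paste0(merged$pattern2.L, merged$pattern1.R),
      posterior = merged$posterior.L * merged$posterior.R)
    both <- rbind(straight, crossed)
    # canonicalize unordered pairs and merge duplicates
    swap <- both$pattern1 > both$pattern2
    tmp <- both$pattern1[swap]
    both$pattern1[swap] <- both$pattern2[swap]
    both$pattern2[swap] <- tmp
    key <- paste(both$ind, both$pattern1, both$pattern2, sep = "|")
    agg <- rowsum(both$posterior, key)
    first <- !duplicated(key)
    both <- both[first, , drop = FALSE]
    both$posterior <- agg[match(paste(both$ind, both$pattern1,
                                      both$pattern2, sep = "|"),
                                rownames(agg)), 1]
    both <- .prune_pairs(both, keep = 3L * pair_keep)
    res <- .em_string_pairs(both, length(unique(both$ind)),
                            tol = tol, max_iter = max_iter,
                            top_patterns = top_patterns)
    cur <- .prune_pairs(res$df, keep = pair_keep, min_post = 1e-7)
  }

  # best-guess pair per individual
  H <- matrix(NA_integer_, 2L * n, m)
  certainty <- rep(NA_real_, n)
  for (i in unique(cur$ind)) {
    d <- cur[cur$ind == i, , drop = FALSE]
    j <- which.max(d$posterior)
    p1 <- d$pattern1[j]; p2 <- d$pattern2[j]
    if (p1 > p2) { tt <- p1; p1 <- p2; p2 <- tt }
    H[2L * i - 1L, ] <- pattern_vector(p1)
    H[2L * i, ] <- pattern_vector(p2)
    certainty[i] <- d$posterior[j]
  }
  imputed <- is.na(genotypes)
  geno_imp <- H[seq(1L, 2L * n, 2L), , drop = FALSE] +
              H[seq(2L, 2L * n, 2L), , drop = FALSE]
  # missing genotypes: replace the best-pair value with the posterior-modal
  # genotype aggregated over the candidate pair distribution. Candidate
  # completions at a missing site are reweighted by the marginal allele
  # frequency there: unique (background) completions otherwise all sit at
  # the frequency floor and would receive uninformative uniform posteriors.
  pall <- colMeans(genotypes, na.rm = TRUE) / 2
  pall[is.na(pall)] <- 0.5
  for (i in unique(cur$ind)) {
    mis <- which(imputed[i, ])
    if (!length(mis)) next
    d <- cur[cur$ind == i, , drop = FALSE]
    if (nrow(d) < 2L) next
    w <- d$posterior / sum(d$posterior)
    for (j in mis) {
      a1 <- as.integer(substr(d$pattern1, j, j))
      a2 <- as.integer(substr(d$pattern2, j, j))
      gj <- a1 + a2
      wj <- w * pall[j]^gj * (1 - pall[j])^(2L - gj)
      pg <- rowsum(wj, gj)
      geno_imp[i, j] <- as.integer(rownames(pg))[which.max(pg[, 1])]
    }
  }
  # final full-length frequency table
  pats <- c(apply(H[seq(1L, 2L * n, 2L), , drop = FALSE], 1,
                  pattern_string),
            apply(H[seq(2L, 2L * n, 2L), , drop = FALSE], 1,
                  pattern_string))
  tab <- table(pats)
  ft <- data.frame(pattern = names(tab),
                   frequency = as.numeric(tab) / sum(tab))
  ft <- ft[order(-ft$frequency), , drop = FALSE]
  rownames(ft) <- NULL
  structure(list(haplotypes = H, certainty = certainty,
                 imputed_flags = imputed, imputed_genotypes = geno_imp,
                 freq_table = ft, errors = errors),
            class = "phased_cohort")
}

#' Switch error rate against truth haplotypes
#'
#' Fraction of adjacent truly-heterozygous site pairs at which the
#' inferred parental assignment flips, minimized over the two possible
#' alignments of each individual's inferred pair to truth.
#'
#' @param inferred,truth 2n x m haplotype matrices (rows 2i-1, 2i per
#'   individual).
#' @return list with `switch_rate`, `n_switches`, `n_transitions`.
#' @export
switch_error_rate <- function(inferred, truth) {
  n <- nrow(truth) / 2L
  sw <- 0L; tr <- 0L
  for (i in seq_len(n)) {
    t1 <- truth[2L * i - 1L, ]; t2 <- truth[2L * i, ]
    h1 <- inferred[2L * i - 1L, ]
    het <- which(t1 != t2)
    if (length(het) < 2L) next
    # phase indicator at het sites: does inferred hap1 carry t1's allele?
    ph <- h1[het] == t1[het]
    flips <- sum(ph[-1] != ph[-length(ph)])
    flips <- min(flips, sum(!ph[-1] != !ph[-length(ph)]))  # symmetric
    sw <- sw + flips
    tr <- tr + length(het) - 1L
  }
  list(switch_rate = if (tr > 0) sw / tr else 0,
       n_switches = sw, n_transitions = tr)
}
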