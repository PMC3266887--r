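# Shared fixtures, memoised so heavy simulations run once per test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a small single-cohort world for unit tests (500 individuals)
small_world <- function() fixture("small_world", function() {
  sc <- build_default_scenario(seeds = c(7101L, 7202L, 7303L))
  spec <- sc$cohorts[["Sweden/Iceland"]]
  spec$n_cases <- 100L
  spec$n_controls <- 400L
  co <- simulate_cohort(spec, sc$map)
  co <- apply_missingness_and_typing(co, spec, validation_size = 20L)
  list(sc = sc, map = sc$map, spec = spec, co = co)
})

small_phased <- function() fixture("small_phased", function() {
  w <- small_world()
  partition_ligation_phase(w$co$genotypes_obs)
})

# the full default three-cohort world, run end to end with the package's
# default seed; shared by the acceptance tests
default_report <- function() fixture("default_report", function() {
  run_pipeline(pipeline_config(seed = 1L))
})

# align truth haplotype labels to phased rows, whole-haplotype variant
align_pairs <- function(inferred, truth) {
  n <- nrow(truth) / 2L
  out <- truth
  for (i in seq_len(n)) {
    r <- c(2L * i - 1L, 2L * i)
    straight <- sum(inferred[r[1], ] != truth[r[1], ]) +
                sum(inferred[r[2], ] != truth[r[2], ])
    crossed <- sum(inferred[r[1], ] != truth[r[2], ]) +
               sum(inferred[r[2], ] != truth[r[1], ])
    if (crossed < straight) out[r, ] <- truth[rev(r), ]
  }
  out
}

# exhaustive maximum-likelihood phasing for tiny problems (<= 4 SNPs):
# enumerate every assignment of a compatible ordered pair to each
# individual and maximize the product of implied haplotype frequencies.
exhaustive_ml_phase <- function(genotypes) {
  n <- nrow(genotypes)
  plist <- lapply(seq_len(n), function(i)
    hladissect:::.compatible_pairs(genotypes[i, ]))
  # unordered pair choices per individual
  plist <- lapply(plist, function(pm) {
    u <- unique(cbind(pmin(pm[, 1], pm[, 2]), pmax(pm[, 1], pm[, 2])))
    u
  })
  counts <- vapply(plist, nrow, integer(1))
  best <- NULL; best_ll <- -Inf
  idx <- rep(1L, n)
  repeat {
    haps <- unlist(lapply(seq_len(n), function(i) plist[[i]][idx[i], ]))
    tab <- table(haps) / (2 * n)
    ll <- sum(log(tab[as.character(haps)]))
    if (ll > best_ll) { best_ll <- ll; best <- idx }
    j <- 1L
    while (j <= n) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= counts[j]) break
      idx[j] <- 1L; j <- j + 1L
    }
    if (j > n) break
  }
  lapply(seq_len(n), function(i) plist[[i]][best[i], ])
}

# exhaustive allele-defining-window scan: all windows containing the tag,
# keep those with carrier-consensus coverage >= consensus and zero
# non-carrier matches; return the largest (ties toward centered on tag).
exhaustive_segment_scan <- function(haps, carrier, tag, consensus = 0.95) {
  m <- ncol(haps)
  Hc <- haps[carrier, , drop = FALSE]
  Hn <- haps[!carrier, , drop = FALSE]
  cons <- as.integer(colMeans(Hc) >= 0.5)
  best <- NULL
  for (l in seq_len(tag)) for (r in tag:m) {
    idx <- l:r
    cov <- mean(rowSums(Hc[, idx, drop = FALSE] !=
                          matrix(cons[idx], nrow(Hc), length(idx),
                                 byrow = TRUE)) == 0)
    if (cov < consensus) next
    hit <- any(rowSums(Hn[, idx, drop = FALSE] !=
                         matrix(cons[idx], nrow(Hn), length(idx),
                                byrow = TRUE)) == 0)
    if (hit) next
    sz <- r - l + 1L
    cen <- abs((tag - l) - (r - tag))
    if (is.null(best) || sz > best$sz ||
        (sz == best$sz && cen < best$cen))
      best <- list(l = l, r = r, sz = sz, cen = cen,
                   pattern = hladissect:::pattern_string(cons[idx]))
  }
  best
}
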