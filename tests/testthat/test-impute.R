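# Tag SNP selection, allele-defining segments, imputation, evaluation.

# a hand-built 20-SNP haploid training set with labeled carriers
.toy_training <- function(n_car = 30, n_non = 120, seed = 99) {
  set.seed(seed)
  m <- 20
  base <- matrix(rbinom(n_non * m, 1, 0.5), n_non, m)
  core <- rbinom(m, 1, 0.5)
  carr <- matrix(rep(core, n_car), n_car, m, byrow = TRUE)
  # carriers share positions 8..12 exactly; elsewhere re-randomized
  idx_shared <- 8:12
  for (i in seq_len(n_car)) {
    flip <- setdiff(seq_len(m), idx_shared)
    carr[i, flip] <- rbinom(length(flip), 1, 0.5)
  }
  haps <- rbind(carr, base)
  # remove accidental non-carrier matches of the shared core
  for (i in (n_car + 1):(n_car + n_non)) {
    if (all(haps[i, idx_shared] == core[idx_shared]))
      haps[i, idx_shared[1]] <- 1L - core[idx_shared[1]]
  }
  labels <- matrix("other", nrow(haps), 3,
                   dimnames = list(NULL, c("HLA-B", "HLA-DRB1",
                                           "HLA-DQB1")))
  labels[seq_len(n_car), "HLA-DRB1"] <- "DRB1*9901"
  map <- region_map(round(seq(32.2e6, 33.15e6, length.out = m)))
  list(haps = haps, labels = labels, map = map, core = core,
       shared = idx_shared)
}

test_that("a perfect tag SNP is selected and greedy matches exhaustive
           max-r2", {
  t <- .toy_training()
  # make SNP 10 a perfect indicator of the allele
  t$haps[, 10] <- 0L
  t$haps[t$labels[, "HLA-DRB1"] == "DRB1*9901", 10] <- 1L
  panel <- select_tag_snps(t$haps, t$labels, t$map, n_tags = 1L,
                           n_backbone = 10L, min_carriers = 10L)
  expect_equal(panel$tags$snp, 10L)
  expect_equal(panel$tags$r2, 1)
  # exhaustive max-r2 search agrees
  ind <- as.integer(t$labels[, "HLA-DRB1"] == "DRB1*9901")
  r2s <- vapply(seq_len(ncol(t$haps)), function(j)
    suppressWarnings(stats::cor(t$haps[, j], ind)^2), numeric(1))
  expect_equal(which.max(r2s), 10L)
  # panel respects requested sizes
  expect_length(panel$backbone, 10L)
  expect_lte(panel$r2_summary[["max_backbone_r2"]], 0.5)
})

test_that("panel selection fails informatively when constraints cannot be
           met", {
  t <- .toy_training()
  expect_error(
    select_tag_snps(t$haps, t$labels, t$map, n_tags = 1L,
                    n_backbone = 25L, min_carriers = 10L),
    "backbone")
})

test_that("segment learning matches the exhaustive window-scan oracle", {
  t <- .toy_training()
  panel <- select_tag_snps(t$haps, t$labels, t$map, n_tags = 1L,
                           n_backbone = 10L, min_carriers = 10L)
  segs <- learn_allele_segments(t$haps, t$labels, panel, t$map,
                                consensus = 0.95, min_carriers = 10L)
  seg <- segs$segments[["DRB1*9901"]]
  expect_false(is.null(seg))
  carrier <- t$labels[, "HLA-DRB1"] == "DRB1*9901"
  oracle <- exhaustive_segment_scan(t$haps, carrier, seg$tag)
  expect_equal(unname(seg$interval), c(oracle$l, oracle$r + 1L))
  expect_equal(seg$pattern, oracle$pattern)
  # emitted segment occurs on zero non-carrier haplotypes
  idx <- seg$interval[1]:(seg$interval[2] - 1L)
  pat <- hladissect:::pattern_vector(seg$pattern)
  non <- t$haps[!carrier, idx, drop = FALSE]
  expect_equal(sum(rowSums(non != matrix(pat, nrow(non), length(idx),
                                         byrow = TRUE)) == 0), 0L)
})

test_that("an allele whose every carrier window recurs in non-carriers is
           untaggable", {
  set.seed(7)
  m <- 12
  core <- rbinom(m, 1, 0.5)
  # 20 carriers and 40 non-carriers with the *same* pattern pool:
  # nothing distinguishes carriers
  haps <- matrix(rep(core, 60), 60, m, byrow = TRUE)
  labels <- matrix("other", 60, 3,
                   dimnames = list(NULL, c("HLA-B", "HLA-DRB1",
                                           "HLA-DQB1")))
  labels[1:20, "HLA-DRB1"] <- "DRB1*9901"
  map <- region_map(round(seq(32.2e6, 33.15e6, length.out = m)))
  panel <- list(tags = data.frame(allele = character(0), gene = character(0),
                                  snp = integer(0), r2 = numeric(0)))
  segs <- learn_allele_segments(haps, labels, panel, map,
                                consensus = 0.95, min_carriers = 10L)
  expect_true("DRB1*9901" %in% segs$untaggable)
  expect_null(segs$segments[["DRB1*9901"]])
})

test_that("rare alleles are skipped with a warning", {
  t <- .toy_training(n_car = 4)
  panel <- select_tag_snps(t$haps, t$labels, t$map, n_tags = 1L,
                           n_backbone = 10L, min_carriers = 3L)
  expect_warning(
    learn_allele_segments(t$haps, t$labels, panel, t$map,
                          min_carriers = 10L),
    "skipped")
})

test_that("imputation calls by exact segment match, with no-call on
           conflicts", {
  segs <- structure(list(segments = list(
    A = list(allele = "B*1111", gene = "HLA-B", interval = c(2L, 5L),
             tag = 3L, pattern = "101"),
    B = list(allele = "B*2222", gene = "HLA-B", interval = c(2L, 4L),
             tag = 3L, pattern = "10"),
    C = list(allele = "DRB1*3333", gene = "HLA-DRB1", interval = c(6L, 8L),
             tag = 6L, pattern = "11")),
    untaggable = character(0)), class = "allele_segments")
  haps <- rbind(
    c(0, 1, 0, 1, 0, 1, 1, 0),   # matches A and B (conflict) and C
    c(0, 1, 0, 0, 0, 1, 1, 0),   # matches B only, and C
    c(0, 0, 0, 0, 0, 0, 0, 0))   # matches nothing
  calls <- impute_hla_alleles(haps, segs)
  expect_true(is.na(calls$calls[1, "HLA-B"]))
  expect_true(calls$conflict[1, "HLA-B"])
  expect_equal(unname(calls$calls[1, "HLA-DRB1"]), "DRB1*3333")
  expect_equal(unname(calls$calls[2, "HLA-B"]), "B*2222")
  expect_equal(unname(calls$calls[2, "HLA-DRB1"]), "DRB1*3333")
  expect_true(all(is.na(calls$calls[3, ])))
})

test_that("evaluation reproduces direct confusion counts", {
  calls <- matrix(NA_character_, 100, 3,
                  dimnames = list(NULL, c("HLA-B", "HLA-DRB1",
                                          "HLA-DQB1")))
  truth <- matrix("other", 100, 3,
                  dimnames = list(NULL, c("HLA-B", "HLA-DRB1",
                                          "HLA-DQB1")))
  truth[1:10, "HLA-B"] <- "B*1111"
  calls[1:9, "HLA-B"] <- "B*1111"    # 9 of 10 carriers called, 1 no-call
  cs <- structure(list(calls = calls, conflict = NULL),
                  class = "hla_callset")
  perf <- evaluate_imputation(cs, truth)
  row <- perf[perf$allele == "B*1111", ]
  expect_equal(row$TP, 9L); expect_equal(row$FN, 1L)
  expect_equal(row$FP, 0L); expect_equal(row$TN, 90L)
  expect_equal(row$sensitivity, 0.9)
  expect_equal(row$ppv, 1.0)
  expect_equal(row$specificity, 1.0)
  expect_error(evaluate_imputation(cs, truth, subset = integer(0)),
               "empty")
})

test_that("uniformly random calls have PPV near carrier prevalence", {
  set.seed(11)
  k <- 4
  alleles <- paste0("B*", 1111 + seq_len(k))
  prev <- c(0.4, 0.3, 0.2, 0.1)
  ppv_err <- replicate(20, {
    n <- 400
    truth <- matrix(sample(alleles, 3 * n, TRUE, prob = prev), n, 3,
                    dimnames = list(NULL, c("HLA-B", "HLA-DRB1",
                                            "HLA-DQB1")))
    calls <- matrix(sample(alleles, 3 * n, TRUE), n, 3,
                    dimnames = dimnames(truth))
    cs <- structure(list(calls = calls, conflict = NULL),
                    class = "hla_callset")
    perf <- evaluate_imputation(cs, truth)
    mean(perf$ppv[match(alleles, perf$allele)] - prev, na.rm = TRUE)
  })
  expect_lt(abs(mean(ppv_err)), 0.02)
})

test_that("training PPV is 1 when consensus is 1", {
  # calls can only land on haplotypes matching the full consensus window,
  # which by the zero-non-carrier rule are true carriers
  t <- .toy_training()
  panel <- select_tag_snps(t$haps, t$labels, t$map, n_tags = 1L,
                           n_backbone = 10L, min_carriers = 10L)
  segs <- learn_allele_segments(t$haps, t$labels, panel, t$map,
                                consensus = 1.0, min_carriers = 10L)
  calls <- impute_hla_alleles(t$haps, segs)
  cs <- structure(list(calls = calls$calls, conflict = NULL),
                  class = "hla_callset")
  perf <- evaluate_imputation(cs, t$labels)
  expect_true(all(perf$ppv[!is.na(perf$ppv)] == 1))
})
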