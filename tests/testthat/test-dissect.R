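# Extended vs recombinant classification, breakpoints, shares.

test_that("share_extended reproduces printed percentages", {
  expect_equal(share_extended(634, 907), 69.9)
  expect_equal(share_extended(47, 140), 33.6)
  expect_equal(share_extended(294, 574), 51.2)
  expect_equal(share_extended(0, 50), 0.0)
  expect_equal(share_extended(1, 8), 12.5)  # exact half rounds away from 0
  expect_error(share_extended(1, 0), "positive")
  expect_error(share_extended(5, 4))
})

.dissect_fixture <- function() {
  sc <- build_default_scenario()
  tpl <- sc$cohorts[[1]]$templates
  names(tpl) <- vapply(tpl, `[[`, character(1), "name")
  ref <- reference_extended("extDR3", tpl$ext_DR3$hla_alleles,
                            tpl$ext_DR3$snp_pattern)
  list(sc = sc, tpl = tpl, ref = ref)
}

test_that("classification labels extended, recombinant and other
           correctly", {
  f <- .dissect_fixture()
  al <- f$tpl$ext_DR3$hla_alleles
  # identical haplotype: extended, no breakpoint
  cl <- classify_against_reference(f$tpl$ext_DR3$snp_pattern, al, f$ref,
                                   f$sc$map)
  expect_equal(cl$label, "extended")
  expect_null(cl$breakpoint)
  # historical recombinant template: recombinant with a breakpoint
  cl2 <- classify_against_reference(f$tpl$rec_DR3$snp_pattern,
                                    f$tpl$rec_DR3$hla_alleles, f$ref,
                                    f$sc$map)
  expect_equal(cl2$label, "recombinant")
  expect_length(cl2$breakpoint, 2L)
  # non-carrier of the focal allele: other
  cl3 <- classify_against_reference(f$tpl$ext_DR15$snp_pattern,
                                    f$tpl$ext_DR15$hla_alleles, f$ref,
                                    f$sc$map)
  expect_equal(cl3$label, "other")
})

test_that("breakpoint interval contains the planted breakpoint on
           simulated mosaics", {
  f <- .dissect_fixture()
  set.seed(12)
  snp_pos <- map_snps(f$sc$map)$pos
  a <- anchor_pos(f$sc$map, "HLA-B"); b <- anchor_pos(f$sc$map, "HLA-DQB1")
  al <- f$tpl$ext_DR3$hla_alleles
  lower_ok <- 0L; near <- 0L; total <- 0L
  for (k in 1:200) {
    bp <- runif(1, a + 1, b - 1)
    donor <- f$tpl[[sample(c("n_DR4", "n_DR13", "ext_DR15"), 1)]]
    mosaic <- donor$snp_pattern
    mosaic[snp_pos >= bp] <- f$tpl$ext_DR3$snp_pattern[snp_pos >= bp]
    # mosaic carries DRB1*0301 iff the DRB1 anchor is on the reference side
    if (anchor_pos(f$sc$map, "HLA-DRB1") < bp) next
    cl <- classify_against_reference(mosaic, al, f$ref, f$sc$map)
    if (cl$label != "recombinant") next  # chance full match of the flank
    total <- total + 1L
    # the lower end never overshoots the true breakpoint; the upper end
    # can fall short when donor SNPs match the reference by chance, so
    # localization is asserted to within a few SNP spacings
    if (cl$breakpoint[1] <= bp) lower_ok <- lower_ok + 1L
    jup <- which(snp_pos >= cl$breakpoint[2])[1]
    up5 <- if (is.na(jup) || jup + 5L > length(snp_pos)) b
           else snp_pos[jup + 5L]
    if (cl$breakpoint[1] <= bp && bp < up5) near <- near + 1L
  }
  expect_gt(total, 100L)
  expect_equal(lower_ok, total)
  expect_gte(near / total, 0.90)
})

test_that("raising the mismatch tolerance never decreases the extended
           count", {
  f <- .dissect_fixture()
  set.seed(13)
  # noisy copies of the reference
  haps <- t(replicate(60, {
    h <- f$tpl$ext_DR3$snp_pattern
    flip <- sample(49, rbinom(1, 3, 0.5))
    h[flip] <- 1L - h[flip]
    h
  }))
  counts <- vapply(0:3, function(tol) {
    sum(vapply(seq_len(60), function(i)
      classify_against_reference(haps[i, ], f$tpl$ext_DR3$hla_alleles,
                                 f$ref, f$sc$map,
                                 mismatch_tolerance = tol)$label ==
        "extended", logical(1)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("dissection partitions carriers and matches a planted
           extended:recombinant ratio", {
  f <- .dissect_fixture()
  spec <- f$sc$cohorts[["Sweden/Iceland"]]
  spec$n_cases <- 50L
  spec$n_controls <- 450L
  co <- simulate_cohort(spec, f$sc$map)
  # truth-based calls
  calls <- co$truth_hla
  ch <- list(SWE = list(haplotypes = co$haplotypes, calls = calls,
                        phenotype = co$phenotype))
  dt <- dissect_focal_allele(ch, f$ref, f$sc$map)
  # partition: extended + recombinant = all DRB1*0301 carriers
  ncar <- sum(calls[, "HLA-DRB1"] == "DRB1*0301")
  expect_equal(dt$summary$n_extended + dt$summary$n_recombinant, ncar)
  expect_equal(dt$summary$n_total, ncar)
  # planted ratio 0.097 : 0.039 (plus de novo mosaics)
  p_ext <- 0.097 / 0.136
  se <- sqrt(p_ext * (1 - p_ext) / ncar)
  expect_lt(abs(dt$summary$n_extended / ncar - p_ext), 4 * se)
  # percentages recompute from counts
  expect_equal(dt$summary$pct_extended,
               share_extended(dt$summary$n_extended, dt$summary$n_total))
  # zero-carrier focal allele: empty row, no division error
  ref0 <- reference_extended(
    "none", c(`HLA-B` = "B*0000", `HLA-DRB1` = "DRB1*0000",
              `HLA-DQB1` = "DQB1*0000"),
    f$tpl$ext_DR3$snp_pattern)
  dt0 <- dissect_focal_allele(ch, ref0, f$sc$map)
  expect_equal(dt0$summary$n_total, 0L)
  expect_true(is.na(dt0$summary$pct_extended))
})

test_that("allele label matching honours 2-digit grouping", {
  expect_true(allele_matches("DQB1*0201", "DQB1*02"))
  expect_true(allele_matches("DQB1*0202", "DQB1*02"))
  expect_false(allele_matches("DQB1*0602", "DQB1*02"))
  expect_false(allele_matches(NA_character_, "DQB1*02"))
})
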