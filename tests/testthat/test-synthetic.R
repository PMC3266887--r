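# Synthetic cohort generator: scenario contents, genotype/haplotype
# consistency, frequency recovery, effect recovery, determinism.

test_that("default scenario encodes the stated world", {
  sc <- build_default_scenario()
  expect_equal(n_snps(sc$map), 49L)
  expect_length(sc$cohorts, 3L)
  expect_equal(vapply(sc$cohorts, `[[`, integer(1), "n_cases"),
               c(`Sweden/Iceland` = 430L, Spain = 256L, Finland = 86L))
  expect_equal(vapply(sc$cohorts, `[[`, integer(1), "n_controls"),
               c(`Sweden/Iceland` = 1090L, Spain = 322L, Finland = 564L))
  tpl <- sc$cohorts[[1]]$templates
  names(tpl) <- vapply(tpl, `[[`, character(1), "name")
  # extended B*0801-DRB1*0301-DQB1*02 control frequency, Sweden/Iceland
  expect_equal(unname(tpl$ext_DR3$cohort_freqs[["Sweden/Iceland"]]), 0.097)
  # total DRB1*0301 control frequency = extended + recombinant rows
  expect_equal(unname(tpl$ext_DR3$cohort_freqs[["Sweden/Iceland"]] +
                        tpl$rec_DR3$cohort_freqs[["Sweden/Iceland"]]),
               0.136)
  # DR15 causal position sits between the HLA-DRB1 and HLA-DQB1 anchors
  expect_gt(tpl$ext_DR15$causal_position, anchor_pos(sc$map, "HLA-DRB1"))
  expect_lt(tpl$ext_DR15$causal_position, anchor_pos(sc$map, "HLA-DQB1"))
  # per-cohort frequency sums <= 1 in every cohort
  for (nm in names(sc$cohorts)) {
    fsum <- sum(vapply(tpl, function(t) t$cohort_freqs[[nm]], numeric(1)))
    expect_lte(fsum, 1)
  }
  # anchors in genomic order
  expect_true(anchor_pos(sc$map, "HLA-B") < anchor_pos(sc$map, "HLA-DRB1"))
  expect_true(anchor_pos(sc$map, "HLA-DRB1") <
                anchor_pos(sc$map, "HLA-DQB1"))
})

test_that("genotypes equal the sum of truth haplotypes and runs are
           deterministic", {
  w <- small_world()
  H <- w$co$haplotypes
  n <- nrow(w$co$genotypes)
  g2 <- H[seq(1, 2 * n, 2), ] + H[seq(2, 2 * n, 2), ]
  expect_identical(unname(w$co$genotypes), g2)
  co2 <- simulate_cohort(w$spec, w$map)
  expect_identical(w$co$genotypes, co2$genotypes)
  expect_identical(w$co$truth_hla, co2$truth_hla)
})

test_that("control haplotype frequencies converge to spec at n = 5000", {
  sc <- build_default_scenario(seeds = c(911L, 912L, 913L))
  spec <- sc$cohorts[["Sweden/Iceland"]]
  spec$n_cases <- 10L
  spec$n_controls <- 5000L
  co <- simulate_cohort(spec, sc$map)
  ctrl <- which(co$phenotype == "control")
  rows <- c(rbind(2 * ctrl - 1, 2 * ctrl))
  nchr <- length(rows)
  tpl <- spec$templates
  for (t in tpl[c(1, 2, 9, 10)]) {
    f <- t$cohort_freqs[["Sweden/Iceland"]]
    plain <- is.na(co$hap_info$bp[rows])
    obs <- mean(co$hap_info$left_template[rows] == t$name & plain)
    se <- sqrt(f * (1 - f) / nchr)
    expect_lt(abs(obs - f), 3 * se + 1e-9)
  }
  # DRB1*0301-bearing control frequency near the published total
  obs <- mean(co$truth_hla[rows, "HLA-DRB1"] == "DRB1*0301")
  expect_lt(abs(obs - 0.136), 3 * sqrt(0.136 * 0.864 / nchr))
})

test_that("degenerate one-template pool yields homozygotes at prevalence", {
  map <- region_map(round(seq(29.9e6, 33.1e6, length.out = 12)))
  pat <- rep(c(0L, 1L), 6)
  tpl <- haplotype_template("only", pat,
                            c(`HLA-B` = "B*0801", `HLA-DRB1` = "DRB1*0301",
                              `HLA-DQB1` = "DQB1*0201"),
                            c(toy = 1.0), grr = 1)
  spec <- cohort_spec("toy", 25L, 200L, list(tpl), recomb_prob = 0,
                      missing_rate = 0, typed_fraction = 1,
                      validation_size = 0L, seed = 33L)
  co <- simulate_cohort(spec, map)
  expect_true(all(co$genotypes == matrix(2L * pat, 225, 12, byrow = TRUE)))
  # case yield per simulated individual ~ prevalence K
  expect_equal(co$f0, spec$prevalence)
})

test_that("planted odds ratio is covered by the estimated CI across
           seeded replicates", {
  map <- region_map(round(seq(29.9e6, 33.1e6, length.out = 12)))
  local_seed <- hladissect:::local_seed
  local_seed(51L, {
    pats <- matrix(rbinom(12 * 3, 1, 0.5), 3)
  })
  risk <- haplotype_template("risk", pats[1, ],
                             c(`HLA-B` = "B*0801", `HLA-DRB1` = "DRB1*0301",
                               `HLA-DQB1` = "DQB1*0201"),
                             c(toy = 0.10), grr = 3.33,
                             causal_position = 32e6)
  covered <- 0L
  for (k in 1:20) {
    spec <- cohort_spec("toy", 500L, 1000L, list(risk), recomb_prob = 0,
                        missing_rate = 0, typed_fraction = 1,
                        validation_size = 0L, seed = 6000L + k)
    co <- simulate_cohort(spec, map)
    plain <- is.na(co$hap_info$bp)
    carrier <- co$hap_info$left_template == "risk" & plain
    pheno <- rep(co$phenotype, each = 2)
    res <- allele_association(allele_counts(
      sum(carrier & pheno == "case"), sum(!carrier & pheno == "case"),
      sum(carrier & pheno == "control"),
      sum(!carrier & pheno == "control")))
    if (res$ci_lo <= 3.33 && res$ci_hi >= 3.33) covered <- covered + 1L
  }
  expect_gte(covered, 18L)
})

test_that("missingness and typing masks behave as specified", {
  w <- small_world()
  co <- w$co
  # identity when rates are trivial
  spec0 <- w$spec
  spec0$missing_rate <- 0
  spec0$typed_fraction <- 1
  spec0$typed_ctrl_fraction <- 1
  co0 <- apply_missingness_and_typing(simulate_cohort(spec0, w$map), spec0,
                                      validation_size = 0L)
  expect_identical(co0$genotypes_obs, co0$genotypes)
  expect_true(all(co0$typed_mask))
  # observed missing fraction within binomial CI of the rate
  p <- mean(co$missing_mask)
  n <- length(co$missing_mask)
  expect_lt(abs(p - 0.01), 4 * sqrt(0.01 * 0.99 / n))
  # validation subset drawn from typed cases
  expect_equal(sum(co$validation_mask), 20L)
  expect_true(all(co$typed_mask[co$validation_mask]))
  expect_true(all(co$phenotype[co$validation_mask] == "case"))
  # typed subset smaller than requested validation fails
  expect_error(
    apply_missingness_and_typing(simulate_cohort(w$spec, w$map), w$spec,
                                 validation_size = 5000L),
    "validation")
})

test_that("unreachable prevalence fails with a diagnostic", {
  map <- region_map(round(seq(29.9e6, 33.1e6, length.out = 12)))
  tpl <- haplotype_template("hot", rep(1L, 12),
                            c(`HLA-B` = "x", `HLA-DRB1` = "y",
                              `HLA-DQB1` = "z"),
                            c(toy = 0.5), grr = 50, causal_position = 32e6)
  spec <- cohort_spec("toy", 10L, 10L, list(tpl), prevalence = 0.4,
                      seed = 1L)
  expect_error(simulate_cohort(spec, map), "unreachable prevalence")
})
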