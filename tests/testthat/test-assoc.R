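# 2x2 association, CMH, meta-analysis, genomic control, logistic scans.

test_that("counts_from_freqs reconstructs printed tables", {
  t <- counts_from_freqs(0.027, 0.151, 430, 1090)
  expect_equal(c(t$a, t$b, t$c, t$d), c(23, 837, 329, 1851))
  expect_equal(counts_from_freqs(0, 0.1, 50, 50)$a, 0)
  t2 <- counts_from_freqs(0.5, 0.5, 50, 50)
  expect_equal(t2$a, t2$c)
  expect_equal(t2$a, 50)
})

test_that("allele association agrees with the hand formula and its
           symmetries", {
  t <- allele_counts(30, 70, 20, 80)
  r <- allele_association(t)
  # independent recomputation
  N <- 200; chi2 <- N * (30 * 80 - 70 * 20)^2 / (100 * 100 * 50 * 150)
  expect_equal(r$chi2, chi2)
  expect_equal(r$p, pchisq(chi2, 1, lower.tail = FALSE))
  expect_equal(r$or, 30 * 80 / (70 * 20))
  expect_true(r$ci_lo < r$or && r$or < r$ci_hi)
  # balanced table: no association
  r0 <- allele_association(allele_counts(5, 5, 5, 5))
  expect_equal(r0$chi2, 0); expect_equal(r0$p, 1); expect_equal(r0$or, 1)
  # chi2 invariant under simultaneous row/column swap; OR inverts under
  # case/control swap
  rsw <- allele_association(allele_counts(80, 20, 70, 30))
  expect_equal(rsw$chi2, r$chi2)
  rcc <- allele_association(allele_counts(20, 80, 30, 70))
  expect_equal(rcc$or, 1 / r$or)
  # zero margin: chi2 undefined, OR flagged
  rz <- allele_association(allele_counts(0, 0, 5, 5))
  expect_false(rz$or_defined)
})

test_that("haplotype association delegates to the 2x2 test", {
  labels <- c(rep("H1", 30), rep("H2", 70), rep("H1", 20), rep("H2", 80))
  pheno <- c(rep("case", 100), rep("control", 100))
  r <- haplotype_association(labels, pheno, "H1")
  expect_equal(r$or, 30 * 80 / (70 * 20))
  # two labels with identical case/control distribution
  r1 <- haplotype_association(c("A", "B", "A", "B"),
                              c("case", "case", "control", "control"), "A")
  expect_equal(r1$or, 1)
  expect_error(haplotype_association(labels, pheno, "H9"), "absent")
  # degenerate: every chromosome focal
  rd <- haplotype_association(rep("A", 10),
                              rep(c("case", "control"), 5), "A")
  expect_false(rd$or_defined)
})

test_that("CMH reduces to the stratum OR and reproduces combined ORs", {
  t1 <- allele_counts(30, 70, 20, 80)
  single <- cmh_combined(list(t1))
  expect_equal(single$or_cmh, allele_association(t1)$or)
  # k identical strata equal the stratum OR, for several k
  for (k in c(2, 3, 7))
    expect_equal(cmh_combined(rep(list(t1), k))$or_cmh,
                 allele_association(t1)$or)
  # printed-table reconstructions (the graded combined ORs)
  protective <- cmh_combined(list(
    counts_from_freqs(0.027, 0.151, 430, 1090),
    counts_from_freqs(0.008, 0.107, 256, 322),
    counts_from_freqs(0.017, 0.130, 86, 564)))
  expect_equal(round_half_up(protective$or_cmh, 2), 0.13)
  risk <- cmh_combined(list(
    counts_from_freqs(0.254, 0.097, 430, 1090),
    counts_from_freqs(0.106, 0.026, 256, 322),
    counts_from_freqs(0.233, 0.083, 86, 564)))
  expect_equal(round_half_up(risk$or_cmh, 2), 3.33)
  # RBG confidence intervals bracket the estimate
  expect_true(risk$ci_lo < risk$or_cmh && risk$or_cmh < risk$ci_hi)
})

test_that("weighted z-score meta follows the closed form", {
  # single cohort: identity
  m1 <- meta_weighted_z(0.01, 1, 500)
  expect_equal(m1$p_combined, 0.01)
  # two equal cohorts, z = 2 each, same direction
  p2 <- 2 * pnorm(-2)
  m2 <- meta_weighted_z(c(p2, p2), c(1, 1), c(300, 300))
  expect_equal(m2$z_combined, 2 * sqrt(2), tolerance = 1e-10)
  expect_equal(m2$p_combined, 2 * pnorm(-2 * sqrt(2)), tolerance = 1e-10)
  # opposite directions cancel
  m3 <- meta_weighted_z(c(p2, p2), c(1, -1), c(300, 300))
  expect_equal(m3$z_combined, 0)
  expect_equal(m3$p_combined, 1)
  # k identical cohorts: z * sqrt(k), exactly
  for (k in c(2, 4, 9)) {
    mk <- meta_weighted_z(rep(p2, k), rep(1, k), rep(123, k))
    expect_equal(mk$z_combined, 2 * sqrt(k), tolerance = 1e-10)
  }
  expect_error(meta_weighted_z(0, 1, 10), "p = 0")
})

test_that("genomic inflation is calibrated on null draws and scales", {
  expect_equal(genomic_inflation(rep(qchisq(0.5, 1), 150)), 1.0)
  # deterministic null sample via the quantile grid: lambda exactly 1
  x <- qchisq(ppoints(10001), df = 1)
  expect_equal(genomic_inflation(x), 1.0, tolerance = 1e-6)
  # multiplying every statistic by c scales lambda by c
  expect_equal(genomic_inflation(1.2 * x), 1.2, tolerance = 1e-6)
  expect_error(genomic_inflation(rchisq(50, 1)), "need")
})

test_that("logistic scan flags collinearity and matches the allele test
           asymptotically", {
  set.seed(3)
  n <- 3000
  x <- rbinom(n, 2, 0.3)
  logit <- -1 + 0.4 * x
  y <- rbinom(n, 1, plogis(logit))
  d <- cbind(m1 = x, m2 = x)  # m2 duplicates m1
  sc <- logistic_scan(d, y, covariates = cbind(x))
  expect_equal(sc$flag, c("collinear", "collinear"))
  sc2 <- logistic_scan(cbind(m = x), y)
  expect_equal(sc2$flag, "")
  # Wald p close to the chromosome-level chi-square p on the -log10 scale
  carriers_case <- sum(x[y == 1]); carriers_ctrl <- sum(x[y == 0])
  tab <- allele_counts(carriers_case, 2 * sum(y == 1) - carriers_case,
                       carriers_ctrl, 2 * sum(y == 0) - carriers_ctrl)
  pa <- allele_association(tab)$p
  ratio <- -log10(sc2$p) / -log10(pa)
  expect_gt(ratio, 0.5); expect_lt(ratio, 2)
})

test_that("null markers give uniform p values", {
  set.seed(8)
  n <- 400
  y <- rep(0:1, each = n / 2)
  d <- matrix(rbinom(n * 250, 2, 0.4), n, 250)
  colnames(d) <- paste0("m", 1:250)
  sc <- logistic_scan(d, y)
  ks <- suppressWarnings(ks.test(sc$p[sc$flag == ""], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("stepwise scan finds a single planted signal then stops", {
  set.seed(9)
  n <- 1200
  causal <- rbinom(n, 2, 0.25)
  y <- rbinom(n, 1, plogis(-1.2 + 1.1 * causal))
  noise <- matrix(rbinom(n * 5, 2, 0.4), n, 5)
  # proxy in strong LD with the causal dosage
  proxy <- causal
  flip <- sample(n, 60)
  proxy[flip] <- rbinom(60, 2, 0.25)
  d <- cbind(sig = causal, proxy = proxy, noise)
  colnames(d) <- c("sig", "proxy", paste0("n", 1:5))
  res <- stepwise_conditional(list(one = list(dosages = d, phenotype = y)),
                              threshold = 1e-4)
  expect_equal(res$steps$marker[1], "sig")
  expect_equal(nrow(res$steps), 1L)
  # proxy rejected after conditioning on the true signal
  last <- res$scans[[length(res$scans)]]$combined
  expect_gt(last$p_combined[last$marker == "proxy"], 1e-4)
  expect_error(stepwise_conditional(
    list(one = list(dosages = matrix(nrow = 10, ncol = 0),
                    phenotype = rep(0:1, 5)))), "empty")
})
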