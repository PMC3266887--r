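# hladissect

Haplotype-based fine-mapping of HLA association signals in case-control
data, built around the study design used for selective IgA deficiency
(IgAD; serum IgA < 0.07 g/l): three European cohorts, long-range
haplotype phasing over a 49-SNP panel spanning the classical MHC,
segment-based imputation of classical *HLA-B*, *-DRB1* and *-DQB1*
alleles, and dissection of each disease-associated allele into its
**extended** ancestral haplotype versus **recombinant** carriers, so that
the segment carrying the causal variant can be localized.

The package is aimed at statistical geneticists who want a reproducible,
fully testable re-implementation of this analysis style. Because the
original cohorts are not deposited, it ships a synthetic-cohort generator
that plants the published haplotype structure (control frequencies and
per-cohort odds ratios of the extended B\*0801-DRB1\*0301-DQB1\*02,
DRB1\*0701-DQB1\*02, B\*1402-DRB1\*0102-DQB1\*05 and protective
B\*0702-DRB1\*1501-DQB1\*06 haplotypes) under a multiplicative disease
model with prevalence K = 1/500, and every downstream stage is exercised
end to end against that ground truth.

## The statistics at the core

* **Allele/haplotype association.** For carrier counts *a,b* (case
  chromosomes) and *c,d* (control chromosomes), the 1-df Pearson test
  χ² = N(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)] with OR = ad/bc and a Woolf CI.
* **Stratified pooling.** Cochran–Mantel–Haenszel common odds ratio
  OR = Σᵢ(aᵢdᵢ/Nᵢ) / Σᵢ(bᵢcᵢ/Nᵢ) with a Robins–Breslow–Greenland CI.
* **Meta-analysis.** Sample-size-weighted z-scores:
  z = Σᵢ zᵢ√Nᵢ / √ΣᵢNᵢ, with zᵢ the signed two-tailed normal quantile of
  the per-cohort p value.
* **Conditional scan.** Stepwise logistic regression of disease status on
  each marker with the 0/1/2-coded genotypes of already-selected HLA
  alleles as covariates, iterated until no residual HLA marker reaches
  P < 5×10⁻⁸ (SNPs are scanned but never conditioned on).
* **Phasing.** Maximum-likelihood EM over haplotype frequencies with
  partition ligation (windows ≤ 12 SNPs, frequent-pattern retention),
  missing genotypes imputed from the pair posterior.
* **HLA imputation.** For each common allele, the longest run of
  consecutive panel SNPs around its tagging SNP whose carrier-consensus
  pattern covers ≥ 95% of carriers and occurs on zero non-carrier
  training chromosomes; haplotypes are called by exact segment match.
* **Power.** Under a multiplicative model, penetrances f₀, f₀r, f₀r² with
  f₀ = K/[(1−p)² + 2p(1−p)r + p²r²]; analytic two-sided power of the
  allele test on 2n chromosomes, with the GRR of a recombinant haplotype
  transferred from its extended counterpart (GRR ≡ allele odds ratio).

## Worked example

Reconstructing the published combined statistics from the printed
per-cohort frequencies and sample sizes (430/1090, 256/322, 86/564
cases/controls):

```r
library(hladissect)

## protective DRB1*1501 across the three cohorts
t5 <- cmh_combined(list(
  counts_from_freqs(0.027, 0.151, 430, 1090),
  counts_from_freqs(0.008, 0.107, 256, 322),
  counts_from_freqs(0.017, 0.130, 86, 564)))
## extended B*0801-DRB1*0301-DQB1*02
t6 <- cmh_combined(list(
  counts_from_freqs(0.254, 0.097, 430, 1090),
  counts_from_freqs(0.106, 0.026, 256, 322),
  counts_from_freqs(0.233, 0.083, 86, 564)))
cat(sprintf("DRB1*1501 combined OR = %.2f (95%% CI %.2f-%.2f)\n",
            t5$or_cmh, t5$ci_lo, t5$ci_hi))
cat(sprintf("extended DR3 combined OR = %.2f (95%% CI %.2f-%.2f)\n",
            t6$or_cmh, t6$ci_lo, t6$ci_hi))

print(share_extended(634, 907))  # extended share of DRB1*0301 carriers
print(share_extended(47, 140))   # recombinant share of DRB1*0102 carriers

## power of the combined study (772 cases / 1,976 controls) to detect the
## recombinant (non-B*0801) DRB1*0301 haplotypes, had they carried the
## extended haplotype's risk
pool <- (0.039*1090 + 0.093*322 + 0.030*564) / 1976
m <- disease_model(p = pool, r = t6$or_cmh, K = 0.002)
cat(sprintf("power at 5e-5: %.4f ; at 5e-8: %.4f\n",
            power_single_stage(772, 1976, m, 5e-5),
            power_single_stage(772, 1976, m, 5e-8)))
```

prints

```
DRB1*1501 combined OR = 0.13 (95% CI 0.09-0.19)
extended DR3 combined OR = 3.33 (95% CI 2.79-3.97)
[1] 69.9
[1] 33.6
power at 5e-5: 1.0000 ; at 5e-8: 1.0000
```

i.e. the protective DRB1\*1501 haplotype family pools to OR 0.13, the
extended DR3 risk haplotype to OR 3.33, 69.9% of DRB1\*0301 chromosomes
carry the full extended haplotype, and the study had essentially 100%
power to see the recombinants' association had the causal variant
traveled with them — which is what makes their observed null informative
about the causal variant's location.

The full synthetic pipeline (simulate → phase → learn segments → impute
→ dissect → associate → conditional scan → power table):

```r
report <- run_pipeline(pipeline_config(seed = 1))
report$conditional$steps       # the four independent signals, in order
report$dissection$DR3$summary  # extended vs recombinant counts
```

or from the shell:

```sh
Rscript inst/scripts/hladissect run --config default --seed 1 --out out/
```

## Layout

* `R/region.R`, `R/simulate.R` — scenario containers and the cohort
  generator.
* `R/phase.R` — partition-ligation EM phasing.
* `R/impute.R` — tag-SNP panel, allele-defining segments, HLA calls,
  performance evaluation.
* `R/dissect.R` — extended/recombinant classification and breakpoints.
* `R/assoc.R` — χ², CMH, weighted-z meta, genomic control, logistic and
  stepwise conditional scans.
* `R/power.R` — multiplicative-model power.
* `R/io.R`, `R/pipeline.R`, `R/cli.R` — formats, orchestration, CLI.
* `vignettes/hla-fine-mapping.Rmd` — the methods vignette (model,
  parameter choices, what the synthetic world does and does not
  establish).
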