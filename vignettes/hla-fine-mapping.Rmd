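---
title: "Dissecting HLA association signals into extended and recombinant haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting HLA association signals into extended and recombinant haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hladissect)
```

## The problem

The MHC shows the strongest association with many immune phenotypes,
including selective IgA deficiency, yet the extreme conservation of its
ancestral haplotypes frustrates localization: a risk allele observed at,
say, *HLA-DQB1* may merely hitchhike on an extended haplotype whose true
causal variant lies megabases away. The analysis style this package
implements attacks that problem with recombinant haplotypes: among all
chromosomes carrying a focal classical allele, those that carry the full
extended haplotype are compared with historical recombinants that share
only part of it. If the recombinants lacking a segment show no
association — and the study is demonstrably well powered to detect one —
the causal variant is placed inside the segment they lost.

The pipeline has six stages: (1) simulate (or load) case-control SNP
genotypes over an MHC-like region; (2) phase them into long-range
haplotypes; (3) learn, on an HLA-typed training subset, the
allele-defining SNP segment of each common classical allele and impute
alleles on every chromosome; (4) classify each carrier chromosome as
extended or recombinant against a reference haplotype and map the
breakpoint; (5) run per-cohort, stratified (CMH) and meta-combined
association tests plus a stepwise conditional scan for independent
signals; (6) compute the power the study would have had to detect
association of the recombinant class under the extended class's effect
size.

## The disease model

Risk is multiplicative per haplotype copy. A haplotype drawn from
template $t$ carries per-copy genotype relative risk $r_t$ (1 for
neutral templates and background), and an individual's penetrance is
$f_0 r_{h_1} r_{h_2}$, with $f_0$ calibrated analytically so the
population prevalence is exactly $K$ (default 0.002, an incidence of
1:500). Risk is a property of the *segment containing the causal
position*: a de novo mosaic inherits a template's risk only if the
template donated the segment covering that template's causal position.
This is the only reading under which recombinants that lost the causal
segment carry no risk, which is the core claim the design tests.

Cases and controls are ascertained by rejection sampling. One
consequence worth knowing: because cases are enriched for risk
haplotypes, every *neutral* haplotype is slightly depleted among case
chromosomes (its case frequency is $f/\bar r$ with
$\bar r = E[r_h] > 1$), so neutral strata drift to odds ratios slightly
below 1 rather than exactly 1. The published recombinant strata sit at
OR ≈ 1.1; the synthetic ones sit at ≈ 0.7–0.9. Tests therefore assert
planted-parameter recovery on risk strata, not exact unity on neutral
ones.

## The synthetic world

The generator's defaults are the study's stated conditions: three
cohorts of 430/1090, 256/322 and 86/564 cases/controls; a 49-SNP panel
(11 HLA-tagging + 38 backbone SNPs) spanning 29.8–33.2 Mb of chromosome
6 in Build-36-styled coordinates, denser in Class I; control-population
frequencies of the extended and recombinant haplotype families taken
from the published per-cohort control columns; per-cohort haplotype
odds ratios likewise (the combined CMH odds ratios — 3.33 for the
extended DR3 haplotype, 2.23 for DQB1\*02-bearing DR7, 4.59 for
B\*1402-DRB1\*0102, 0.14 for DR15 — then emerge from pooling). Causal
positions: the Class III/Class II border for the extended DR3 signal,
the DQA1–DQB1 interval for the DR7 signal, Class III for the
B\*1402-DRB1\*0102 signal, and the DRB1–DQB1 block for the protective
DR15 signal.

Choices the source material does not fix, made once:

* **Haplotype pool.** Beyond the published families (including an
  invented recombinant-B\*0801 template, frequencies flagged as such in
  the code), seven neutral ancestral templates model other common
  European MHC haplotypes, leaving a 5% residual filled by SNP-wise
  independent draws at template-averaged frequencies. The residual is
  kept small deliberately: common MHC haplotype diversity at 49 common
  tag SNPs is strongly blocky, and a large unstructured component would
  contradict the strong-LD regime the whole design exploits (and makes
  phasing properties unattainable that the region plainly supports).
* **Template SNP patterns** are constructed deterministically (fixed
  internal seed): per-gene allele code blocks near each gene, family
  sharing across fixed historical breakpoints between *HLA-B* and
  *HLA-DRB1* (between *HLA-DRB1* and *HLA-DQB1* for the
  non-DQB1\*02 DR7 recombinant), free bits elsewhere, with a
  decorrelation pass enforcing the panel's own contract: pairwise
  backbone r² < 0.5 and minor allele frequency ≥ 0.05 under every
  cohort's weights, including case-enriched ones.
* **Typing availability.** Lab HLA typing covers 80% of patients plus a
  10% control panel (a typed donor-registry stand-in); the held-out
  validation set is 79 typed patients allocated across cohorts
  proportionally to typed counts, since a per-cohort 79 is impossible
  for the 86-case Finnish cohort. Patient-scale training also keeps
  segment learning honest — see below.
* **De novo mosaics** occur with probability 0.01 per haplotype, one
  breakpoint uniform on the HLA-B..HLA-DQB1 interval. Historical
  recombinant classes are separate templates at their published
  frequencies; `recomb_prob` only adds fresh mosaics for
  breakpoint-mapping tests.

What a green test on this world establishes: that the algorithms recover
planted frequencies, effects, segments and signal structure under
realistic LD, phasing error and partial typing. What it does not
establish: performance under population admixture, genotyping error,
coalescent-realistic rare-haplotype diversity, or multi-breakpoint
mosaics — all out of scope.

## Phasing

The Bayesian-coalescent phaser used in the original workflow is replaced
by a deterministic maximum-likelihood EM with partition ligation:
windows of ≤ 8 SNPs are EM-phased over all genotype-compatible haplotype
pairs (missing genotypes summed over completions), adjacent blocks are
ligated by re-running EM over concatenations of the surviving candidate
pairs with the most frequent 30 patterns retained, and each individual
reports its posterior-modal pair with the posterior as certainty.
Numerical choices: tolerance 1e-6 on frequencies, ≤ 500 iterations,
uniform initialization, frequency floor 1/(4n) in reported tables,
within-individual order canonicalized lexicographically.

Two details matter in practice. First, the straight and crossed joins of
two window-level pairs have identical pre-EM weights, so pruning an
individual to one arbitrary pair turns every block boundary into a coin
flip; retention therefore always keeps the full pair set of individuals
whose candidates would otherwise vanish and lets the EM (which sees the
frequent template side) break the tie. Second, missing genotypes on
*unique* haplotypes (background chromosomes) get uninformative uniform
completion posteriors, so imputation reweights candidate completions by
the marginal allele frequency at the site. Switch error on the default
world is ~0.5–1.5% and missing-genotype accuracy ~96%, the residual
being concentrated on genuinely uninformative background chromosomes
(their missing alleles are i.i.d. coin flips no method can beat beyond
the frequency mode).

## Allele-defining segments

The original study defined segments *visually*; here that step is
formalized: anchor at the allele's tagging SNP (maximal haploid r²
with the allele indicator, searched within 600 kb of the gene), grow the
window outward while the carrier-consensus pattern still covers ≥ 95% of
carrier chromosomes (ties broken toward the window more centered on the
tag), and emit the final window only if its pattern occurs on zero
non-carrier training chromosomes. If the panel tag cannot grow a unique
window, the next-best local anchors are tried before declaring the
allele untaggable. Alleles with fewer than 10 training carriers are
skipped — on the synthetic default this reproduces the study's own
caveat that rare alleles (its B\*0702 example) evaluate poorly.

Strict zero-collision uniqueness meets an unavoidable adversary:
confidently mis-phased chromosomes. The ML decomposition of an ambiguous
genotype prefers frequent haplotypes, so a hallucinated chromosome can
carry a common allele's core while its individual's lab typing excludes
the allele; one such chromosome would otherwise veto a 500-carrier
allele. Segment learning therefore runs two passes: the first tolerates
up to max(2, 0.2% of non-carriers) collisions per window, chromosomes
contradicting their own typing at a learned core are discarded as phase
artifacts (the formal analogue of what visual curation did), and the
second pass enforces strict uniqueness on the cleaned set. Calls are by
exact segment match; same-gene conflicts yield a no-call (favoring PPV),
and no-call chromosomes are dropped from association denominators for
that gene only.

## Dissection and breakpoints

A carrier chromosome is *extended* if it matches the reference pattern
over the span from 450 kb telomeric of the HLA-B anchor (so the SNPs
tagging *HLA-B* itself are compared) through the HLA-DQB1 anchor with at
most one mismatch (`mismatch_tolerance = 1`, absorbing one genotyping or
phasing error; the tolerance is monotone by construction). Otherwise it
is recombinant, with the breakpoint reported as the half-open interval
between the first divergent SNP scanning from the centromeric end and
the adjacent retained SNP. The lower endpoint never overshoots the true
breakpoint; the upper endpoint can fall short when flank SNPs match the
reference by chance (probability ~½ per SNP for unrelated donors), so
localization is honest to within a few SNP spacings — a geometric-tail
resolution limit that no adjacent-SNP interval can beat, and the reason
the breakpoint property is asserted at "within 3–5 SNPs" rather than
exact containment.

## Association and the conditional scan

Single-stratum tests use the 1-df Pearson χ² without continuity
correction on carrier/non-carrier chromosome counts; combined odds
ratios use CMH with the Robins–Breslow–Greenland variance; combined p
values use the sample-size-weighted z-score meta (weights √N with total
N; effective-N weighting is a configurable alternative). Direction signs
are taken per cohort from the effect's own sign relative to the common
reference allele. The stepwise scan fits, per cohort, a logistic
regression of status on each marker dosage plus the 0/1/2 dosages of
already-selected markers, meta-combines the Wald tests, adds the top
residual *HLA allele or haplotype-class* marker while it reaches
P < 5×10⁻⁸, and stops otherwise. SNPs are scanned at every step but are
not eligible for selection — the procedure the original analysis
describes — because a single SNP can straddle two haplotype families
(correlated positively with one signal and negatively with another) and,
if conditioned on, smears both. Markers with identical dosage columns
are collapsed as aliases; 2-digit composite groups (e.g. DQB1\*02, a
union of two independent signals by construction) are reported in the
association tables but are likewise not selection candidates.

On the default world the scan selects exactly four signals — the
extended DR3 class, DRB1\*1501 (or its alias DQB1\*0602), DQB1\*0202
(alias of the DQB1\*02-bearing DR7 class) and DRB1\*0102 — and
terminates with all residual HLA markers far from the threshold; proxy
markers such as B\*0801, DQB1\*0201, B\*0702 and B\*1402 end with
residual combined p > 0.1.

A note on effect heterogeneity: with a single combined GRR per template,
the rare B\*1402-DRB1\*0102 haplotype cannot reach genome-wide
significance (2–3 expected carrier chromosomes per Nordic cohort at GRR
4.59), whereas the published per-cohort odds ratios for it are 13.24,
3.11 and 13.71. Template GRRs are therefore per-cohort-capable and the
default world plants the per-cohort published values; the combined CMH
estimates then emerge within a few percent of the published combined
ones.

Genomic-control λ is median(χ²)/qchisq(0.5, 1). It needs a null marker
set; the 49-SNP region is both saturated with real signal and too small
for a stable median, so the pipeline's per-cohort λ is a diagnostic
only, and calibration is asserted on proper null simulations (10,000
draws) where λ ∈ [0.95, 1.05].

## Power

GRR is identified with the allele odds ratio (exact for a multiplicative
model in the rare-disease limit — documented approximation), expected
case/control allele frequencies follow from HWE genotype frequencies and
the penetrances by Bayes inversion, and power is the two-sided normal
approximation with null-variance threshold and alternative-variance
shift on 2n chromosomes, clipped to [0, 1]. The analytic values agree
with Monte-Carlo simulation within 2 percentage points across a grid of
(p, r, n), and the combined study's power to detect the recombinant DR3
class at the extended class's GRR rounds to 100% at both α = 5×10⁻⁵ and
5×10⁻⁸ — the computation behind the acceptance targets.

## Known limitations

* Per-cohort printed p values and odds ratios are not reproduction
  targets: the underlying per-cohort test in the source tables is
  underdetermined (reconstructed allele-count ORs differ from the
  printed ones in the second decimal).
* The generator is template-based, not coalescent: no mutation, at most
  one breakpoint per chromosome, no admixture. Rare-haplotype diversity
  is underrepresented, which flatters imputation of sole-carrier
  alleles.
* Neutral strata drift slightly protective under case ascertainment (see
  the disease model section).
* Breakpoint localization is limited by flank informativeness, not only
  SNP spacing.
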