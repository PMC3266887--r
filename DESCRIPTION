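Package: hladissect
Title: Haplotype-Based Fine-Mapping of HLA Association Signals
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting case-control association signals in the
    human MHC into contributions from extended and recombinant HLA
    haplotypes. Provides a synthetic cohort generator with planted
    haplotype risks under a multiplicative disease model, EM-based
    long-range haplotype phasing with partition ligation, HLA allele
    imputation from allele-defining SNP segments learned on a typed
    training set, extended-versus-recombinant haplotype classification
    with breakpoint mapping, single-stratum and Cochran-Mantel-Haenszel
    association statistics, weighted z-score meta-analysis, stepwise
    conditional logistic regression scans, genomic-control inflation
    estimates, and analytic power calculations for allele-based tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
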