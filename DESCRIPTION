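Package: ssgwas
Title: Sex-Stratified GWAS Inference on Liability-Threshold Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and inference toolkit for studying sexual dimorphism in
    the genetic architecture of a common disease with a strong male prevalence
    bias. Generates trio and case-control cohorts ascertained under a
    sex-specific liability-threshold model, and provides the full downstream
    pipeline: transmission disequilibrium tests, covariate-adjusted logistic
    association with principal-component covariates, X-chromosome dosage coding,
    fixed-effects meta-analysis with Cochran's Q heterogeneity, power-matched
    sex-permutation null distributions summarised by FDR-threshold enrichment
    fractions, observed-scale GREML heritability with a stepwise spike-in
    series, BLUP SNP effects and out-of-sample polygenic risk scores,
    permutation-based gene-set and pleiotropy enrichment with length- and
    association-matched null sets, and analytic/simulation power calculators
    for the TDT and two-sample t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
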