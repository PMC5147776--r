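---
title: "Sex-stratified GWAS inference on liability-threshold cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-stratified GWAS inference on liability-threshold cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Many common disorders show strong sex differences in prevalence; autism
spectrum disorder is the motivating case, with roughly 1 in 42 boys and 1 in
189 girls affected. Several genetic mechanisms could produce such a bias,
and they make different, testable predictions about common-variant (SNP)
data:

1. **Liability threshold.** The same alleles affect both sexes, but females
   need a higher liability to be affected. Prediction: affected females
   carry more polygenic load than affected males.
2. **X-linked risk.** Risk alleles on the X act in males (hemizygous) but
   are buffered in females. Prediction: male-specific X association and
   male-female effect heterogeneity on the X.
3. **Autosomal gene-by-sex interaction.** Autosomal effects differ between
   the sexes. Prediction: top association signals disagree in direction or
   magnitude across sexes genome-wide.
4. **Hormone-responsive expression.** Risk concentrates in genes whose
   expression responds to androgens/estrogens or is sexually dimorphic in
   the developing brain.
5. **Pleiotropy with secondary sex characteristics.** SNPs with
   sex-heterogeneous effects on anthropometric traits (height, weight, BMI,
   hip, waist) contribute disproportionately to disease risk.

`ssgwas` implements the full inference pipeline for these hypotheses —
sex-stratified association, meta-analysis with heterogeneity, power-matched
sex-permutation nulls, observed-scale heritability with spike-in series,
BLUP risk scoring, and permutation-based set enrichment — together with a
synthetic-cohort generator with known ground truth, so that every analysis
can be exercised end-to-end and tested for calibration and parameter
recovery.

## The generative model

An `architecture_spec()` defines a SNP panel (chromosomes 1-22 and X,
allele frequencies uniform on a configurable range, linkage equilibrium)
and a disease model. Individual liability is

$$ L = g + e, \qquad g = \sum_j \beta_{j,\text{sex}} (x_j - \bar x_j) s, \qquad e \sim N(0,\, 1 - h^2), $$

where the scaling $s$ standardises the polygenic value to variance exactly
$h^2$ (computed from the expected dosage variances $2p_j(1-p_j)$, or
$p_j(1-p_j)$ for the male X), so the per-sex thresholds $T_m$, $T_f$ stay
interpretable as z-cutoffs. An individual is affected when $L > T_{\text{sex}}$.
Defaults are $T_m = \Phi^{-1}(1 - 1/42) \approx 1.98$ and
$T_f = \Phi^{-1}(1 - 1/189) \approx 2.56$, matching the reported male and
female prevalences; the male-female threshold gap is deliberately a free
parameter, since a prevalence ratio pins down the two thresholds only
jointly with the (unknown) liability correlation structure.

Consequences worth knowing when designing experiments:

* Because each sex's polygenic value is standardised to variance $h^2$, the
  *relative* pattern of the causal `beta_male` / `beta_female` entries is
  what matters (zero vs non-zero, sign, ratio); the absolute scale is set
  by `h2_liability`. Sex-limited architectures (`beta_female = 0`) and
  shared ones (`beta_male = beta_female`) are both expressible.
* With the sex-specific default thresholds, ascertained female probands
  genuinely carry more polygenic load — that is the liability-threshold
  model's prediction, and the generator reproduces it (tested). Experiments
  that need a *null* sex difference (for example: does a male-trained risk
  score transfer equally to female cases when there is no gene-by-sex
  interaction?) therefore use equal thresholds, isolating the
  interaction question from the threshold effect.
* Trios are ascertained by rejection sampling: child sex is fixed first
  (the requested proband sex mix is exact), parents are drawn from the
  population, the child by Mendelian transmission (X-aware), and the trio
  is kept if the child's liability crosses its threshold. The sampling
  budget defaults to 500 candidate children per requested trio and failure
  names the offending threshold. For efficiency, rejection operates on the
  causal SNPs only; the neutral panel is filled in afterwards, which is
  distributionally equivalent because neutral genotypes are independent of
  affection.
* All randomness descends from one root seed through named substreams
  (`with_substream()`), so each generator is reproducible in isolation.

What the generator does **not** emulate: linkage disequilibrium (an
optional concern listed as a non-goal; the matched-SNP null machinery
treats "LD-pruned" as de-duplication on this panel), genotyping error,
demographic structure beyond optional multi-batch labels, and assortative
mating. Calibration and recovery results on these cohorts therefore show
the machinery is correct, not that real-data confounding is absent.

## Association, meta-analysis, heterogeneity

* `tdt_scan()` counts minor-allele transmissions from heterozygous parents
  to affected probands, statistic $(b-c)^2/(b+c)$ on 1 df, no continuity
  correction; $\beta = \ln(b/c)$, $se = \sqrt{1/b + 1/c}$. On the X,
  hemizygous fathers are never informative; sons receive only the maternal
  transmission and daughters the paternal allele plus the maternal
  transmission. One proband per family is used (the first-listed affected
  child). Effects are always reported for the cohort minor allele.
* `logistic_scan()` fits case-control status by IRLS (`stats::glm.fit`),
  Wald tests, ten principal-component covariates by default in the analysis
  scripts (`pca_covariates()`, eigenvectors of the standardised autosomal
  genotype covariance). X SNPs use 0/1 male coding and add sex as a
  covariate whenever both sexes are analysed together. Separation is
  flagged at $|\beta| > 20$ and non-converged fits are excluded from
  meta-analysis.
* `fixed_effects_meta()` combines designs and sexes with inverse-variance
  weights; `cochran_q()` is the two-stratum heterogeneity statistic
  (chi-square, 1 df). `bh_qvalues()` wraps the Benjamini-Hochberg step-up;
  an independent brute-force enumeration serves as its test oracle.
* `ld_clump()` is greedy by ascending p with ties broken by (chromosome,
  position, id); defaults r² > 0.2 within 500 kb — the clumping tool the
  study used is named but not parameterised, so these standard defaults are
  explicit configuration.

## The sex-permutation null

The pipeline's central null (`make_permutation_plans()`) permutes sex
labels within technical batch x study design, with the pseudo-male set in
each stratum matched exactly to the true male count, so every permuted
dataset has the same power as the corresponding true sex-specific dataset.
Trios permute as whole families; case-control individuals permute
individually within their case/control role. Principal components are
computed once on the full cohort: permuting sex labels does not change
genotypes, so per-permutation PCA would add cost without changing the null.

Association signal is summarised as the fraction of SNPs in scope passing
an FDR q-value of 0.8 — a deliberately lenient comparison metric, not a
significance claim — and the empirical p is the plain proportion of
permuted runs at least as extreme (the $(r+1)/(n+1)$ variant is available
by flag; "more extreme" is one-sided in the direction of the tested
enrichment). Top-SNP heterogeneity uses ascertainment-adjusted FDR levels
(X: male 0.2, female 0.01; autosomes: male 0.2, female 0.001) applied to
the Cochran's Q q-values within the clumped top-k set.

A power note established during development: when male trios dominate the
cohort (16% female probands, the study's composition), a power-matched
pseudo-male set still contains ~84% true males, so for male-limited X
effects the q<0.8 enrichment fraction of permuted sets trails the observed
one only slightly — the contrast is intrinsically marginal (the original
study's corresponding result was P = 0.04). The top-k heterogeneity excess
is the sharper instrument, and it is the one the qualitative acceptance
experiment asserts; the enrichment comparison is checked directionally.

## Heritability, spike-in, BLUP

`compute_grm()` is the standard standardised-dosage GRM over autosomes;
monomorphic SNPs are excluded. Relatedness filtering uses GRM off-diagonals
with a 0.1 cutoff (greedy, deterministic) as a stated proxy for an
IBD-based PI-HAT filter — IBD estimation itself is out of scope.

`reml_h2()` fits $y = Xb + g + e$, $g \sim (0, A V_g)$, by
average-information REML with expectation-maximisation fallback, on the
eigenbasis of $A$ (every iteration is $O(nq^2)$ after one
eigendecomposition). The fit is deliberately **unconstrained**: $V_g$ may
iterate negative while total variance stays positive definite, so
observed-scale $h^2$ can fall outside $[0,1]$ — required for unbiased
comparison across spike-in series. Convergence is $|\Delta \ell| < 10^{-8}$
within 100 iterations; non-converged sets are flagged and dropped from the
series correlation (the conservative default where the study's behaviour is
not described). Standard errors come from the AI matrix by the delta
method; tests use the standard GREML sampling approximation
$se(h^2) \approx \sqrt{2m}/n$ as an independent tolerance oracle.

`spike_in_series()` grows nested cohorts in steps of 10 pairs (a 953-pair
pool gives 97 sets, the arithmetic the counting test pins down) and
summarises the trend by Spearman rank correlation. The negative control —
adding pseudo-control pairs with arbitrary labels — dilutes $V_g$ and
drives the correlation strongly negative, which the simulation reproduces
(rho ≈ −0.99 in the shipped analysis run).

`blup_snp_effects()` computes individual BLUPs
$\hat g = V_g A (V_g A + V_e I)^{-1} \tilde y$ (phenotype residualised on
covariates) and SNP solutions $u = W^\top A^{+} \hat g / m$, so training
scores reproduce $\hat g$ exactly; $A^{+}$ keeps the transform defined when
$m < n$. The BLUP-ridge identity (penalty $m V_e / V_g$) is the test
oracle. `risk_scores()` applies $u$ to standardised target dosages using
training frequencies; missing SNPs contribute zero and an overlap below
50% is an error. Group comparisons are Welch t-tests.

## Gene sets and pleiotropy

Gene windows are ±5 kb, 1-based inclusive with boundaries included (BED
input converted from 0-based half-open on read). Length-matched gene
permutation samples one of the 100 nearest-length pool genes per target
gene, without replacement within a permutation; genes above 92 Mb and X/Y
genes are excluded upstream. AH SNPs are selected at a two-sample
sex-difference z test $p < 10^{-3}$ on any anthropometric trait (the z form
is validated against the two-stratum Cochran's Q to $10^{-10}$), and their
matched nulls are drawn from the 100 SNPs nearest in combined-sex trait
association p on the same trait, excluding the selected SNPs themselves
(the default; excluding all AH-eligible SNPs is a documented alternative).
SC gene scoring Fisher-transforms per-panel correlations with a module's
first principal component, averages with sample-size weights, and
classifies at $|\bar r| > 0.3$.

## Power

`tdt_power()` enumerates the nine parental mating types under
Hardy-Weinberg and multiplicative genotype relative risk $\gamma$,
conditions on an affected child (prevalence cancels), and refers the TDT to
a non-central chi-square, $\lambda = n(E[b]-E[c])^2/E[b+c]$; the
multiplicative-model transmission probability $\gamma/(1+\gamma)$ falls out
of the enumeration and is asserted in tests. Simulation mode draws
replicate trio sets from the same conditional configuration distribution
and pushes them through the TDT statistic; an independent rejection-sampling
trio simulator under multiplicative penetrance is the cross-check oracle in
the test suite. `ttest_power()` is the standard non-central-t two-sample
power. Headline values at the study's design points: TDT power 0.801
(2,000 trios, $\gamma = 1.35$, MAF 0.30, $\alpha = 5\times10^{-8}$) and
t-test power 0.810 (953 per group, $d = 0.13$, $\alpha = 0.05$).

## Numerical choices and problem sizes

* Logistic convergence $|\Delta\ell| < 10^{-8}$, 50 iterations; REML
  $10^{-8}$, 100 iterations; PCA eigenvector signs fixed by the
  largest-magnitude loading; clumping ties by (chromosome, position, id).
* The test suite runs everything at deliberately modest sizes chosen to
  keep a full run in minutes while leaving each assertion's statistical
  tolerance meaningful: calibration on 2,000 null trios + 1,000
  case-control samples over 2,000 SNPs; REML recovery at n = 2,000,
  m = 1,000 across $h^2 \in \{0, 0.2, 0.5, 0.8\}$ (3 analytic SE ≈ 0.067);
  qualitative sex-specificity experiments at 50 replicates with 50
  permutations and ~100-SNP scopes; BLUP transfer with 750 training and
  250 + 250 test pairs per sex.

## Known limitations

* Exact invariance of estimates to adding a covariate orthogonal to
  phenotype and genotypes is a linear-least-squares property; for IRLS and
  REML the estimates move by $O(1/n)$ (the restricted likelihood loses a
  degree of freedom). Tests assert that bound, not machine precision.
* With a single trait and independent SNPs, the analytic power of the
  sex-difference screen at a 4-combined-SE effect is 0.761; recovery tests
  assert that analytic value.
* The observed-scale heritability is reported as-is; no liability-scale or
  ascertainment correction is applied (matching the analysis this package
  reproduces).
* TDT p-values are discrete at small informative counts; calibration
  checks use rejection fractions with binomial bands rather than
  Kolmogorov-Smirnov tests where ties matter.
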