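test_that("GRM matches the brute-force double loop and hand cases", {
  # one SNP at p = 0.5, both individuals heterozygous -> centred dosage 0
  g0 <- toy_table(matrix(c(1L, 1L), ncol = 1))
  A0 <- compute_grm(g0)$A
  expect_equal(A0[1, 2], 0, tolerance = 1e-12)

  # duplicated individual: off-diagonal equals the diagonal
  set.seed(61)
  d <- matrix(stats::rbinom(20 * 15, 2, 0.3), 20, 15)
  d[2, ] <- d[1, ]
  g <- toy_table(d)
  A <- compute_grm(g)$A
  expect_equal(A[1, 2], A[1, 1], tolerance = 1e-12)

  # brute-force double-loop oracle, 10 individuals x 20 SNPs
  d2 <- matrix(stats::rbinom(10 * 20, 2, 0.4), 10, 20)
  g2 <- toy_table(d2)
  grm <- compute_grm(g2)
  p <- a1_frequency(g2)
  keep <- p > 0 & p < 1
  x <- d2[, keep, drop = FALSE]
  pk <- p[keep]
  brute <- matrix(0, 10, 10)
  for (i in 1:10) for (k in 1:10) {
    brute[i, k] <- mean((x[i, ] - 2 * pk) * (x[k, ] - 2 * pk) /
                          (2 * pk * (1 - pk)))
  }
  expect_equal(unname(grm$A), brute, tolerance = 1e-12)
  expect_equal(grm$A, t(grm$A), tolerance = 1e-12)
})

test_that("GRM excludes monomorphic SNPs and X by default", {
  d <- cbind(rep(2L, 8), stats::rbinom(8, 2, 0.5), stats::rbinom(8, 2, 0.5))
  g <- toy_table(d, sex = rep("female", 8), chrom = c("1", "1", "X"))
  expect_warning(grm <- compute_grm(g), "monomorphic")
  expect_equal(grm$m, 1)
})

test_that("relatedness filter removes related pairs deterministically", {
  spec <- architecture_spec(c("1" = 3000), maf_range = c(0.1, 0.5), seed = 62)
  g <- simulate_population(spec, 400)
  grm <- compute_grm(g)
  kept <- grm_relatedness_filter(grm, 0.1)
  expect_gte(length(kept), 396)  # <= 1% removed in an unrelated cohort

  # a parent-offspring pair (off-diagonal ~0.5): exactly one removed
  tr <- simulate_trios(spec, 1)
  fam <- subset_genotypes(tr, tr$meta$role %in% c("father", "proband"))
  both <- genotype_table(g$snp_info, rbind(g$dosages[1:50, ], fam$dosages),
                         rbind(g$meta[1:50, ], fam$meta))
  grm2 <- compute_grm(both)
  kept2 <- grm_relatedness_filter(grm2, 0.1)
  expect_equal(length(kept2), 51)
  expect_equal(sum(fam$meta$id %in% kept2), 1)

  # cutoff above the maximum off-diagonal: identity
  expect_equal(grm_relatedness_filter(grm2, 1), grm2$ids)
})

test_that("REML recovers simulated heritability within 3 analytic SE", {
  n <- 800
  m <- 500
  se_analytic <- sqrt(2 * m) / n  # GREML sampling-variance approximation
  for (h2 in c(0, 0.5)) {
    spec <- architecture_spec(c("1" = m), seed = 63 + 10 * h2)
    g <- simulate_population(spec, n)
    W <- ssgwas:::standardized_dosages(g$dosages, a1_frequency(g))
    set.seed(63 + 10 * h2)
    gv <- drop(W %*% stats::rnorm(m))
    gv <- if (h2 > 0) gv / stats::sd(gv) * sqrt(h2) else 0 * gv
    y <- gv + stats::rnorm(n, sd = sqrt(1 - h2))
    est <- reml_h2(compute_grm(g), y)
    expect_true(est$converged)
    expect_lt(abs(est$h2_obs - h2), 3 * se_analytic)
    expect_gt(est$se_h2, 0)
  }
})

test_that("REML is unconstrained and handles the noiseless boundary", {
  spec <- architecture_spec(c("1" = 400), seed = 64)
  g <- simulate_population(spec, 500)
  W <- ssgwas:::standardized_dosages(g$dosages, a1_frequency(g))
  set.seed(64)
  gv <- drop(W %*% stats::rnorm(400))
  gv <- gv / stats::sd(gv)
  est1 <- reml_h2(compute_grm(g), gv)  # phenotype = exact genetic value
  expect_gt(est1$h2_obs, 0.97)

  # pure noise: the unconstrained estimate may dip below zero
  ests <- vapply(1:5, function(i) {
    set.seed(640 + i)
    reml_h2(compute_grm(g), stats::rnorm(500))$h2_obs
  }, numeric(1))
  expect_true(all(abs(ests) < 3 * sqrt(2 * 400) / 500))
})

test_that("REML shifts only O(1/n) when an orthogonal covariate is added", {
  spec <- architecture_spec(c("1" = 300), seed = 65)
  g <- simulate_population(spec, 600)
  W <- ssgwas:::standardized_dosages(g$dosages, a1_frequency(g))
  set.seed(65)
  gv <- drop(W %*% stats::rnorm(300))
  y <- gv / stats::sd(gv) * sqrt(0.5) + stats::rnorm(600, sd = sqrt(0.5))
  Q <- qr.Q(qr(cbind(y, W)))
  c0 <- stats::rnorm(600)
  c0 <- c0 - Q %*% crossprod(Q, c0)
  grm <- compute_grm(g)
  e1 <- reml_h2(grm, y)
  e2 <- reml_h2(grm, y, covariates = c0)
  expect_lt(abs(e2$h2_obs - e1$h2_obs), 0.01)
})

test_that("spike-in steps: arithmetic of nested sets", {
  expect_equal(length(spike_in_steps(953, 10)), 97)
  expect_equal(spike_in_steps(20, 10), c(0L, 10L, 20L))
  expect_equal(spike_in_steps(25, 10), c(0L, 10L, 20L, 25L))
  expect_equal(spike_in_steps(7, 10), c(0L, 7L))
})

test_that("pseudo-control-only spike-in dilutes heritability (negative rho)", {
  cz <- data.frame(snp = 1:60, beta_male = 1, beta_female = 1)
  spec <- architecture_spec(c("1" = 300), causal = cz, h2_liability = 0.6,
                            threshold_female = stats::qnorm(1 - 1 / 42),
                            seed = 66)
  tr <- simulate_trios(spec, 450, proband_sex_fraction_female = 0.4)
  coh <- case_pseudo_control_cohort(tr)
  males <- coh$meta$sex == "male"
  base <- subset_genotypes(coh, males)
  # noise pool: female pseudo-controls relabelled case/control
  pool <- subset_genotypes(coh, !males & coh$meta$role == "pseudo-control")
  pool$meta$affection <- rep(c(1L, 2L), length.out = nrow(pool$meta))
  s <- spike_in_series(base, pool, pairs_per_step = 20)
  expect_equal(nrow(s$series), length(spike_in_steps(
    length(unique(pool$meta$family)), 20)))
  expect_lt(s$rho, 0)
  expect_error(spike_in_series(base, coh, 10), "disjoint")
})

test_that("BLUP reproduces training BLUPs, shrinks, and equals ridge", {
  spec <- architecture_spec(c("1" = 100), seed = 67)
  g <- simulate_population(spec, 50)
  W <- ssgwas:::standardized_dosages(g$dosages, a1_frequency(g))
  set.seed(67)
  gv <- drop(W %*% stats::rnorm(100))
  y <- gv / stats::sd(gv) * sqrt(0.5) + stats::rnorm(50, sd = sqrt(0.5))
  grm <- compute_grm(g)
  est <- reml_h2(grm, y)
  eff <- blup_snp_effects(grm, g, y, est)
  # training scores reproduce individual BLUPs
  sc <- risk_scores(eff, g)
  expect_lt(max(abs(sc$score - eff$ghat)), 1e-6)
  # ridge equivalence with penalty m * Ve / Vg
  lam <- grm$m * est$V_e / est$V_g
  u_ridge <- solve(crossprod(W) + diag(lam, 100), crossprod(W, y - mean(y)))
  expect_lt(max(abs(eff$effects$u - u_ridge)), 1e-6)

  # null phenotype: solutions shrink towards zero
  set.seed(68)
  y0 <- stats::rnorm(50)
  est0 <- reml_h2(grm, y0)
  if (est0$converged && est0$V_g > 0) {
    eff0 <- blup_snp_effects(grm, g, y0, est0)
    expect_lt(mean(abs(eff0$effects$u)), 0.5 * mean(abs(eff$effects$u)))
  }
  # refusal when Vg <= 0
  est_bad <- est
  est_bad$V_g <- -0.01
  expect_error(blup_snp_effects(grm, g, y, est_bad), "V_g")
})

test_that("risk scores are invariant to SNP order and zero for zero effects", {
  spec <- architecture_spec(c("1" = 80), seed = 69)
  g <- simulate_population(spec, 60)
  W <- ssgwas:::standardized_dosages(g$dosages, a1_frequency(g))
  set.seed(69)
  y <- drop(W %*% stats::rnorm(80)) + stats::rnorm(60)
  grm <- compute_grm(g)
  est <- reml_h2(grm, y)
  eff <- blup_snp_effects(grm, g, y, est)
  target <- simulate_population(spec, 30, id_prefix = "tgt")
  s1 <- risk_scores(eff, target)
  perm <- sample(n_snps(target))
  s2 <- risk_scores(eff, subset_genotypes(target, snps = perm))
  expect_equal(s1$score, s2$score, tolerance = 1e-12)

  eff$effects$u[] <- 0
  expect_true(all(risk_scores(eff, target)$score == 0))

  # insufficient overlap is a hard error
  small <- subset_genotypes(target, snps = 1:10)
  expect_error(risk_scores(eff, small), "50%")
})

test_that("group comparison: Welch test with degenerate-group handling", {
  s <- data.frame(score = c(1, 1, 1, 1), g = c("a", "a", "b", "b"))
  gc <- group_compare(s, s$g)
  expect_equal(gc$t, 0)
  expect_equal(gc$p, 1)
  expect_error(group_compare(data.frame(score = 1:3), c("a", "b", "b")),
               "two members")
  set.seed(70)
  s2 <- data.frame(score = c(stats::rnorm(40), stats::rnorm(40, 1)))
  grp <- rep(c("a", "b"), each = 40)
  gc2 <- group_compare(s2, grp)
  expect_equal(gc2$p, stats::t.test(s2$score[grp == "b"],
                                    s2$score[grp == "a"])$p.value)
})
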