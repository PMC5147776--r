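test_that("population dosages follow binomial expectations, X hemizygous", {
  spec <- architecture_spec(c("1" = 1), maf_range = c(0.5, 0.5), seed = 1)
  g <- simulate_population(spec, 10000)
  expect_lt(abs(mean(g$dosages) - 1.0), 0.03)

  spec_x <- architecture_spec(c(X = 1), maf_range = c(0.3, 0.3), seed = 2)
  gx <- simulate_population(spec_x, 8000, sex_ratio = 0)
  expect_true(all(gx$dosages %in% 0:1))
  expect_lt(abs(mean(gx$dosages) - 0.3), 0.02)
})

test_that("simulation is bit-identical under the same seed", {
  spec <- architecture_spec(c("1" = 30, X = 10), seed = 9)
  expect_identical(simulate_population(spec, 200), simulate_population(spec, 200))
  expect_identical(simulate_trios(spec, 50), simulate_trios(spec, 50))
  expect_identical(simulate_anthro_sumstats(100, 0.1, seed = 3),
                   simulate_anthro_sumstats(100, 0.1, seed = 3))
  p1 <- simulate_expression_panels(50, c(10, 20), seed = 4)
  p2 <- simulate_expression_panels(50, c(10, 20), seed = 4)
  expect_identical(p1, p2)
})

test_that("cohort allele frequencies stay within 3 binomial SD of the panel", {
  spec <- architecture_spec(c("1" = 200), maf_range = c(0.1, 0.5), seed = 5)
  g <- simulate_population(spec, 1000)
  f <- a1_frequency(g)
  p <- spec$snp_info$freq
  sd3 <- 3 * sqrt(p * (1 - p) / (2 * 1000))
  expect_gt(mean(abs(f - p) <= sd3), 0.98)
})

test_that("null-architecture trios transmit at the Mendelian 1/2", {
  spec <- architecture_spec(c("1" = 60), maf_range = c(0.3, 0.5), seed = 6)
  tr <- simulate_trios(spec, 400)
  res <- tdt_scan(tr)
  expect_gt(sum(res$n_eff), 5000)
  expect_lt(abs(sum(res$b) / sum(res$n_eff) - 0.5), 0.02)
})

test_that("ascertainment over-transmits the risk allele, matching a direct oracle", {
  cz <- data.frame(snp = 1, beta_male = 0.5, beta_female = 0.5)
  spec <- architecture_spec(c("1" = 10), causal = cz, h2_liability = 0.2,
                            seed = 8)
  tr <- simulate_trios(spec, 2000)
  rec <- tdt_scan(tr, snps = 1)
  # b/c are oriented to the cohort minor allele; recover risk-allele counts
  f_cohort <- a1_frequency(tr)[1]
  b_risk <- if (f_cohort > 0.5) rec$c else rec$b
  c_risk <- rec$n_eff - b_risk
  expect_lt(stats::binom.test(b_risk, rec$n_eff, 0.5,
                              alternative = "greater")$p.value, 0.01)

  # independent oracle: direct simulation of ascertained children at the SNP
  scale <- ssgwas:::causal_scale(spec, "male")
  set.seed(99)
  n_sim <- 4e5
  p <- spec$snp_info$freq[1]
  f <- stats::rbinom(n_sim, 2, p)
  m <- stats::rbinom(n_sim, 2, p)
  tf <- stats::rbinom(n_sim, 1, f / 2)
  tm <- stats::rbinom(n_sim, 1, m / 2)
  child <- tf + tm
  liab <- scale$beta * (child - scale$mean_dose) +
    stats::rnorm(n_sim, sd = sqrt(1 - spec$h2_liability))
  aff <- liab > spec$threshold_male
  n_het <- (f == 1) + (m == 1)
  th <- child - (f == 2) - (m == 2)
  t_frac_oracle <- sum(th[aff]) / sum(n_het[aff])
  expect_lt(abs(b_risk / rec$n_eff - t_frac_oracle), 0.03)
})

test_that("a higher female threshold yields higher female proband load", {
  cz <- data.frame(snp = 1:20, beta_male = 1, beta_female = 1)
  spec <- architecture_spec(c("1" = 40), causal = cz, h2_liability = 0.5,
                            threshold_male = 1, threshold_female = 1.5,
                            seed = 10)
  tr <- simulate_trios(spec, 2000, proband_sex_fraction_female = 0.5)
  kids <- tr$meta$role == "proband"
  gk <- subset_genotypes(tr, kids)
  load_of <- function(sex) {
    sc <- ssgwas:::causal_scale(spec, sex)
    rows <- gk$meta$sex == sex
    ssgwas:::causal_score(gk$dosages[rows, cz$snp, drop = FALSE], sc)
  }
  tt <- stats::t.test(load_of("female"), load_of("male"),
                      alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("trio budget exhaustion fails loudly, naming the threshold", {
  spec <- architecture_spec(c("1" = 5), threshold_male = 6,
                            threshold_female = 6, seed = 3)
  expect_error(simulate_trios(spec, 50, budget = 2), "threshold")
})

test_that("pseudo-controls complement transmissions in all 27 configurations", {
  cfgs <- expand.grid(f = 0:2, m = 0:2, c = 0:2)
  feasible <- with(cfgs, c >= (f == 2) + (m == 2) &
                     c <= pmin(f, 1) + pmin(m, 1))
  good <- cfgs[feasible, ]
  tr <- toy_trios(matrix(good$f, ncol = 1), matrix(good$m, ncol = 1),
                  matrix(good$c, ncol = 1))
  pc <- make_pseudo_controls(tr)
  expect_equal(unname(drop(pc$dosages)), good$f + good$m - good$c)
  # the spec's worked examples
  expect_equal(pc$dosages[good$f == 1 & good$m == 1 & good$c == 2], 0L)
  expect_equal(pc$dosages[good$f == 2 & good$m == 0 & good$c == 1], 1L)
})

test_that("Mendelian-inconsistent trio genotypes give NA pseudo-controls", {
  tr <- toy_trios(matrix(c(0L, 2L), ncol = 1), matrix(c(0L, 0L), ncol = 1),
                  matrix(c(2L, 1L), ncol = 1))
  expect_message(pc <- make_pseudo_controls(tr), "Mendelian")
  expect_true(is.na(pc$dosages[1, 1]))
  expect_equal(pc$dosages[2, 1], 1L)
})

test_that("X-chromosome pseudo-controls respect hemizygosity", {
  # boy: pseudo-control carries the untransmitted maternal allele
  tr <- toy_trios(matrix(c(1L, 1L), ncol = 1), matrix(c(1L, 1L), ncol = 1),
                  matrix(c(1L, 2L), ncol = 1),
                  child_sex = c("male", "female"), chrom = "X")
  pc <- make_pseudo_controls(tr)
  expect_equal(pc$dosages[1, 1], 0L)   # mother het, transmitted the A allele
  expect_equal(pc$dosages[2, 1], 1L)   # girl: father's allele + untransmitted
  expect_equal(pc$meta$sex, c("male", "female"))
})

test_that("anthropometric sumstats: null calibration and heterogeneity recovery", {
  ss0 <- simulate_anthro_sumstats(100000, frac_heterogeneous = 0,
                                  traits = "height", seed = 11)
  pd <- sex_difference_p(ss0$beta_m, ss0$se_m, ss0$beta_f, ss0$se_f)
  hit <- mean(pd < 1e-3)
  expect_lt(abs(hit - 1e-3), 3 * sqrt(1e-3 * (1 - 1e-3) / 1e5))

  ss <- simulate_anthro_sumstats(20000, frac_heterogeneous = 0.05, seed = 12)
  ah <- ah_select(ss)
  truth <- unique(ss$snp[ss$true_het])
  recovered <- mean(truth %in% ah$snp)
  # analytic two-sample z power at a 4-combined-SE difference
  zc <- stats::qnorm(1 - 5e-4)
  pow <- stats::pnorm(-zc + 4) + stats::pnorm(-zc - 4)
  expect_lt(abs(recovered - pow),
            3 * sqrt(pow * (1 - pow) / length(truth)))
})

test_that("expression panels: sex bias induces the closed-form correlation", {
  ep0 <- simulate_expression_panels(300, c(40, 60), 0, seed = 13)
  r0 <- vapply(seq_len(300), function(i) {
    stats::cor(ep0$panels[[1]]$expr[i, ],
               as.numeric(ep0$panels[[1]]$sex == "male"))
  }, numeric(1))
  expect_lt(mean(abs(r0)), 2 / sqrt(40))

  delta <- 1.5
  ep <- simulate_expression_panels(200, c(200, 200), 0.2, seed = 14,
                                   bias_delta = delta)
  biased <- ep$truth$bias != 0
  r <- vapply(which(biased), function(i) {
    stats::cor(ep$panels[[1]]$expr[i, ],
               as.numeric(ep$panels[[1]]$sex == "male"))
  }, numeric(1))
  r_expect <- delta / sqrt(delta^2 + 4)
  expect_lt(abs(mean(abs(r)) - r_expect), 0.05)
})
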