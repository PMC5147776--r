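test_that("TDT arithmetic matches the closed form on constructed counts", {
  # 20 trios: father het, mother AA-hom (dose 0); child dose = transmitted
  make_counts <- function(n_trans, n_tot) {
    f <- matrix(1L, n_tot, 1)
    m <- matrix(0L, n_tot, 1)
    c_ <- matrix(c(rep(1L, n_trans), rep(0L, n_tot - n_trans)), ncol = 1)
    toy_trios(f, m, c_)
  }
  r1 <- tdt(make_counts(10, 20), "s001")
  expect_equal(r1$b, 10)
  expect_equal(r1$c, 10)
  expect_equal(r1$p, 1)
  expect_equal(r1$beta, 0)

  r2 <- tdt(make_counts(15, 20), "s001")
  expect_equal(r2$b, 15)
  expect_equal(r2$c, 5)
  expect_equal((r2$b - r2$c)^2 / (r2$b + r2$c), 5)
  expect_equal(r2$p, stats::pchisq(5, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r2$p, 0.02535, tolerance = 1e-3)
  expect_equal(r2$beta, log(3), tolerance = 1e-10)
  expect_equal(r2$se, sqrt(1 / 15 + 1 / 5), tolerance = 1e-10)

  # untestable SNP: no informative parents
  r0 <- tdt(toy_trios(matrix(0L, 4, 1), matrix(2L, 4, 1), matrix(1L, 4, 1)),
            "s001")
  expect_equal(r0$n_eff, 0)
  expect_true(is.na(r0$p))
})

test_that("TDT equals a brute-force transmission count on random small trios", {
  set.seed(31)
  for (rep in 1:4) {
    n <- 40
    f <- matrix(stats::rbinom(n * 6, 2, 0.4), n, 6)
    m <- matrix(stats::rbinom(n * 6, 2, 0.4), n, 6)
    tf <- matrix(stats::rbinom(n * 6, 1, f / 2), n, 6)
    tm <- matrix(stats::rbinom(n * 6, 1, m / 2), n, 6)
    tr <- toy_trios(f, m, tf + tm)
    res <- tdt_scan(tr)
    fr <- a1_frequency(tr)
    for (j in 1:6) {
      b <- cc <- 0
      for (i in 1:n) {
        # every heterozygous parent contributes one transmission
        if (f[i, j] == 1) {
          b <- b + tf[i, j]
          cc <- cc + 1 - tf[i, j]
        }
        if (m[i, j] == 1) {
          b <- b + tm[i, j]
          cc <- cc + 1 - tm[i, j]
        }
      }
      if (fr[j] > 0.5) {
        tmp <- b
        b <- cc
        cc <- tmp
      }
      expect_equal(res$b[j], b)
      expect_equal(res$c[j], cc)
    }
  }
})

test_that("X-linked TDT counts only heterozygous mothers", {
  # fathers hemizygous (never informative); informative mothers only
  f <- matrix(c(1L, 1L, 0L, 1L), ncol = 1)
  m <- matrix(c(1L, 1L, 1L, 0L), ncol = 1)
  ch <- matrix(c(1L, 0L, 1L, 1L), ncol = 1)   # boys: maternal allele only
  tr <- toy_trios(f, m, ch, child_sex = c("male", "male", "male", "female"),
                  chrom = "X")
  r <- tdt(tr, "s001")
  # three het mothers; trio 4's mother is hom (forced), father allele to girl
  expect_equal(r$n_eff, 3)
  # a1 transmissions from het mothers: boys' doses 1, 0, 1 -> 2 of 3; but
  # the cohort a1 frequency is 9/17 > 0.5, so counts are flipped to the
  # minor allele: b = 1, c = 2
  expect_equal(r$b, 1)
  expect_equal(r$c, 2)
})

test_that("one proband per family is used in multiplex families", {
  f <- matrix(1L, 2, 1)
  m <- matrix(1L, 2, 1)
  ch <- matrix(c(2L, 0L), ncol = 1)
  tr <- toy_trios(f, m, ch)
  tr$meta$family <- rep("famA", 6)  # two affected children, one family
  r <- tdt(tr, "s001")
  expect_equal(r$n_eff, 2)  # only the first-listed proband's two transmissions
  expect_equal(r$b, 2)
})

test_that("logistic association matches the 2x2 closed form", {
  # cases 40/100 exposed (dose 1), controls 20/100
  d <- matrix(c(rep(1L, 40), rep(0L, 60), rep(1L, 20), rep(0L, 80)), ncol = 1)
  g <- toy_table(d, affection = rep(c(2L, 1L), each = 100),
                 role = rep(c("case", "control"), each = 100))
  r <- logistic_assoc(g, "s001")
  or <- (40 / 60) / (20 / 80)
  expect_equal(r$beta, log(or), tolerance = 1e-6)
  expect_equal(r$beta, 0.9808, tolerance = 1e-4)
  se <- sqrt(1 / 40 + 1 / 60 + 1 / 20 + 1 / 80)
  expect_equal(r$se, se, tolerance = 1e-6)
  expect_equal(r$se, 0.3228, tolerance = 1e-3)
  expect_true(r$converged)
})

test_that("logistic beta equals collapsed 2x2 log-odds on random binary SNPs", {
  set.seed(32)
  for (rep in 1:5) {
    n <- 300
    d <- matrix(stats::rbinom(n, 1, stats::runif(1, 0.2, 0.7)), ncol = 1)
    y <- stats::rbinom(n, 1, 0.4 + 0.2 * d[, 1])
    g <- toy_table(d, affection = y + 1L,
                   role = ifelse(y == 1, "case", "control"))
    tab <- table(factor(d[, 1], 0:1), factor(y, 0:1))
    if (any(tab == 0)) next
    lo <- log(tab[2, 2] * tab[1, 1] / (tab[2, 1] * tab[1, 2]))
    r <- logistic_assoc(g, 1)
    fr <- a1_frequency(g)[1]
    expect_equal(r$beta, if (fr > 0.5) -lo else lo, tolerance = 1e-6)
  }
})

test_that("an orthogonal covariate barely moves the logistic estimate", {
  set.seed(33)
  n <- 500
  d <- matrix(stats::rbinom(n, 2, 0.3), ncol = 1)
  y <- stats::rbinom(n, 1, stats::plogis(-0.5 + 0.3 * d[, 1]))
  g <- toy_table(d, affection = y + 1L,
                 role = ifelse(y == 1, "case", "control"))
  Q <- qr.Q(qr(cbind(1, d[, 1])))
  c0 <- stats::rnorm(n)
  c0 <- c0 - Q %*% crossprod(Q, c0)
  r1 <- logistic_assoc(g, 1)
  r2 <- logistic_assoc(g, 1, covariates = matrix(c0, ncol = 1))
  # exact invariance is an OLS property; IRLS reweighting leaves an O(1/n) shift
  expect_lt(abs(r2$beta - r1$beta), 1e-3)
})

test_that("separated fits are flagged and excluded from meta-analysis", {
  d <- matrix(rep(c(0L, 2L), each = 20), ncol = 1)
  g <- toy_table(d, affection = rep(c(1L, 2L), each = 20),
                 role = rep(c("control", "case"), each = 20))
  r <- logistic_assoc(g, 1)
  expect_false(r$converged)
  m <- fixed_effects_meta(list(cc = r,
                               other = data.frame(snp = "s001", beta = 0.1,
                                                  se = 0.05)))
  expect_equal(m$k, 1)
  expect_equal(m$beta_meta, 0.1)
})

test_that("X dosage coding: hemizygous males, sex covariate when mixed", {
  d <- matrix(c(1L, 0L, 2L, 1L), ncol = 1)
  g <- toy_table(d, sex = c("male", "male", "female", "female"), chrom = "X")
  expect_equal(unname(encode_x(g, "s001")), c(1L, 0L, 2L, 1L))
  g$dosages[1, 1] <- 2L
  expect_error(encode_x(g, "s001"), "i001")

  # all-female X behaves exactly like an autosome
  df <- matrix(stats::rbinom(80, 2, 0.4), ncol = 2)
  ga <- toy_table(df, sex = rep("female", 40), chrom = c("X", "1"),
                  affection = rep(c(1L, 2L), 20),
                  role = rep(c("control", "case"), 20))
  expect_equal(unname(encode_x(ga, 1)), unname(ga$dosages[, 1]))
})

test_that("principal components separate simulated subpopulations", {
  set.seed(34)
  m <- 120
  p1 <- stats::runif(m, 0.1, 0.5)
  p2 <- pmin(0.9, p1 + 0.4)
  d <- rbind(
    sapply(seq_len(m), function(j) stats::rbinom(80, 2, p1[j])),
    sapply(seq_len(m), function(j) stats::rbinom(80, 2, p2[j]))
  )
  g <- toy_table(d)
  pcs <- pca_covariates(g, 5)
  lab <- rep(0:1, each = 80)
  expect_gt(abs(stats::cor(pcs[, 1], lab)), 0.9)
  expect_lt(max(abs(crossprod(pcs) - diag(5))), 1e-8)

  # homogeneous population: no component tracks a random label
  dh <- sapply(seq_len(m), function(j) stats::rbinom(160, 2, p1[j]))
  pc_h <- pca_covariates(toy_table(dh), 5)
  lab_r <- sample(rep(0:1, each = 80))
  expect_lt(max(abs(stats::cor(pc_h, lab_r))), 0.12)
})
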