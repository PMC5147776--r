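test_that("gene windows include the 5 kb boundary exactly", {
  genes <- data.frame(gene = "G1", chrom = "1", start = 10000L, end = 20000L,
                      length = 10001L)
  snps <- data.frame(id = c("a", "b", "c", "d"), chrom = "1",
                     pos = c(5001L, 4999L, 25000L, 25001L))
  w <- snps_in_gene_windows(genes, snps, flank = 5000)
  expect_identical(w$G1, c("a", "c"))
  # flank 0: strictly intragenic
  w0 <- snps_in_gene_windows(genes, data.frame(id = c("x", "y"), chrom = "1",
                                               pos = c(10000L, 9999L)),
                             flank = 0)
  expect_identical(w0$G1, "x")
  expect_error(snps_in_gene_windows(genes[0, ], snps), "empty")
})

test_that("window assignment equals a brute-force per-SNP scan", {
  set.seed(81)
  genes <- data.frame(
    gene = sprintf("g%02d", 1:15), chrom = sample(c("1", "2"), 15, TRUE),
    start = sample.int(9e5, 15)
  )
  genes$end <- genes$start + sample.int(5e4, 15)
  genes$length <- genes$end - genes$start + 1L
  snps <- data.frame(id = sprintf("s%03d", 1:500),
                     chrom = sample(c("1", "2"), 500, TRUE),
                     pos = sample.int(1e6, 500))
  w <- snps_in_gene_windows(genes, snps, flank = 5000)
  for (i in seq_len(nrow(genes))) {
    hit <- character(0)
    for (j in seq_len(nrow(snps))) {
      if (snps$chrom[j] == genes$chrom[i] &&
          snps$pos[j] >= genes$start[i] - 5000 &&
          snps$pos[j] <= genes$end[i] + 5000) hit <- c(hit, snps$id[j])
    }
    expect_identical(w[[genes$gene[i]]], hit)
  }
  # de-duplicated union
  expect_false(anyDuplicated(gene_set_snps(genes, snps)) > 0)
})

test_that("gene BED round-trips with the 0-based half-open convention", {
  genes <- data.frame(gene = c("A", "B"), chrom = c("1", "2"),
                      start = c(101L, 501L), end = c(200L, 900L),
                      length = c(100L, 400L))
  path <- withr::local_tempfile(fileext = ".bed")
  write_gene_bed(genes, path)
  bed <- utils::read.table(path, sep = "\t")
  expect_equal(bed[[2]], c(100L, 500L))  # 0-based starts on disk
  expect_equal(read_gene_bed(path), genes)
})

test_that("length matching ranks the nearest-length pool genes first", {
  pool <- data.frame(gene = c("p1", "p2", "p3", "p4"),
                     chrom = "1", start = 1L,
                     end = c(9000L, 10050L, 25000L, 40000L))
  pool$length <- pool$end - pool$start + 1L
  genes <- rbind(pool, data.frame(gene = "t", chrom = "1", start = 1L,
                                  end = 10000L, length = 10000L))
  expect_warning(
    sets <- length_matched_null_sets("t", pool, genes, n_perm = 30, seed = 1,
                                     n_candidates = 2),
    NA
  )
  # candidates are the two nearest lengths: p2 (10050) and p1 (9000)
  expect_true(all(unlist(sets) %in% c("p1", "p2")))
  expect_true(all(lengths(sets) == 1))

  # pool of exactly n_candidates: candidates = the whole pool
  sets2 <- length_matched_null_sets("t", pool, genes, n_perm = 50, seed = 2,
                                    n_candidates = 4)
  expect_setequal(unique(unlist(sets2)), pool$gene)
  # permuted sets conserve the target-set size
  t2 <- c("t", "p4")
  sets3 <- suppressWarnings(
    length_matched_null_sets(t2, pool[1:3, ], genes, n_perm = 20, seed = 3,
                             n_candidates = 2)
  )
  expect_true(all(lengths(sets3) == 2))
  # without replacement within one permutation
  expect_true(all(vapply(sets3, anyDuplicated, integer(1)) == 0))
})

test_that("AH selection applies the two-sample z cutoff", {
  ss <- data.frame(
    snp = c("a", "b"), trait = "height",
    beta_m = c(0.1, 0.05), se_m = 0.02,
    beta_f = c(0.0, 0.05), se_f = 0.02,
    p_comb = c(0.5, 0.5), stringsAsFactors = FALSE
  )
  expect_equal(sex_difference_p(0.1, 0.02, 0.0, 0.02),
               2 * stats::pnorm(-0.1 / sqrt(2 * 4e-4)), tolerance = 1e-12)
  expect_equal(sex_difference_p(0.1, 0.02, 0.0, 0.02), 4.1e-4,
               tolerance = 1e-2)
  sel <- ah_select(ss)
  expect_identical(sel$snp, "a")
  # equal betas can never be selected
  expect_equal(sex_difference_p(0.3, 0.1, 0.3, 0.2), 1)
})

test_that("sex-difference z equals the two-stratum Cochran's Q", {
  set.seed(82)
  for (rep in 1:10) {
    bm <- stats::rnorm(1)
    bf <- stats::rnorm(1)
    sm <- stats::runif(1, 0.05, 0.3)
    sf <- stats::runif(1, 0.05, 0.3)
    pz <- sex_difference_p(bm, sm, bf, sf)
    pq <- cochran_q(data.frame(snp = "s", beta = bm, se = sm),
                    data.frame(snp = "s", beta = bf, se = sf))$p_Q
    expect_equal(pz, pq, tolerance = 1e-10)
  }
})

test_that("matched null sets exclude AH targets and match association p", {
  ss <- simulate_anthro_sumstats(5000, frac_heterogeneous = 0.05, seed = 83)
  ah <- ah_select(ss)
  expect_gt(nrow(ah), 50)
  nulls <- matched_assoc_null_sets(ah, ss, n_perm = 20, seed = 4)
  for (ns in nulls) {
    expect_length(ns, nrow(ah))
    expect_length(intersect(ns, ah$snp), 0)
    expect_equal(anyDuplicated(ns), 0)
  }
  # the null sets preserve the marginal combined-p distribution of the target
  pool_p <- ss$p_comb[match(unlist(nulls), ss$snp)]
  expect_gt(suppressWarnings(
    stats::ks.test(ah$p_comb, pool_p)$p.value), 0.05)
  # deterministic given seed
  expect_identical(nulls, matched_assoc_null_sets(ah, ss, n_perm = 20,
                                                  seed = 4))
})

test_that("set enrichment compares true and matched null sets", {
  records <- data.frame(snp = sprintf("s%03d", 1:60),
                        p = c(rep(1e-5, 20), stats::runif(40, 0.5, 1)))
  nulls <- lapply(1:10, function(i) sprintf("s%03d", 21:40))
  se <- set_enrichment(sprintf("s%03d", 1:20), nulls, records)
  expect_equal(se$observed_fraction, 1)
  expect_equal(se$empirical_p, 0)
  # a set identical to one null set ties with it
  se2 <- set_enrichment(sprintf("s%03d", 21:40), nulls, records)
  expect_equal(se2$observed_fraction, se2$permuted_fractions[1])
  expect_equal(se2$empirical_p, 1)
})

test_that("SC scoring: Fisher-weighted averaging and classification", {
  # r = 0.5 (n = 10) and r = 0.3 (n = 30): zbar = 0.36947, rbar = 0.3536
  zbar <- (10 * atanh(0.5) + 30 * atanh(0.3)) / 40
  expect_equal(zbar, 0.36947, tolerance = 1e-4)
  expect_equal(tanh(zbar), 0.3536, tolerance = 1e-3)

  ep <- simulate_expression_panels(120, c(60, 90), 0.25, seed = 84,
                                   bias_delta = 1.5)
  pcs <- lapply(ep$panels, function(p) {
    v <- as.numeric(p$sex == "male")
    (v - mean(v)) / stats::sd(v)
  })
  sc <- sc_gene_scores(ep, pcs, r_cut = 0.3)
  truth <- ep$truth[match(sc$gene, ep$truth$gene), ]
  up <- truth$bias > 0
  down <- truth$bias < 0
  expect_gt(mean(sc$class[up] == "male-correlated"), 0.8)
  expect_gt(mean(sc$class[down] == "male-anticorrelated"), 0.8)
  expect_gt(mean(sc$class[truth$bias == 0] == "unclassified"), 0.95)

  # single panel: weights collapse to the plain correlation
  ep1 <- ep
  ep1$panels <- ep$panels[1]
  sc1 <- sc_gene_scores(ep1, pcs[1])
  r_direct <- drop(stats::cor(t(ep$panels[[1]]$expr), pcs[[1]]))
  expect_equal(sc1$r_bar, unname(r_direct), tolerance = 1e-10)

  # order invariance across panels
  ep_rev <- ep
  ep_rev$panels <- rev(ep$panels)
  sc_rev <- sc_gene_scores(ep_rev, rev(pcs))
  expect_equal(sc$r_bar, sc_rev$r_bar, tolerance = 1e-12)

  # constant-expression gene is dropped with a message
  ep2 <- ep
  ep2$panels[[1]]$expr[1, ] <- 5
  ep2$panels[[2]]$expr[1, ] <- 5
  expect_message(sc2 <- sc_gene_scores(ep2, pcs), "constant")
  expect_false(ep$truth$gene[1] %in% sc2$gene)
})

test_that("module PC1 separates the sexes when the module is sex-biased", {
  ep <- simulate_expression_panels(60, c(80, 80), 0.5, seed = 85,
                                   bias_delta = 2)
  biased_genes <- ep$truth$gene[ep$truth$bias != 0]
  pc1 <- module_pc1(ep$panels[[1]]$expr, biased_genes)
  sex_num <- as.numeric(ep$panels[[1]]$sex == "male")
  expect_gt(abs(stats::cor(pc1, sex_num)), 0.8)
})
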