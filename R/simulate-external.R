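#' Simulate sex-stratified anthropometric summary statistics
#'
#' Emulates large-consortium sex-stratified GWAS summary statistics for
#' anthropometric traits (height, weight, BMI, hip, waist, ...): per SNP and
#' trait, male and female effect estimates with standard errors. A fraction of
#' SNPs is truly sex-heterogeneous: on one randomly chosen trait their male
#' and female effects differ by `diff_scale` combined standard errors
#' (combined SE = sqrt(se_m^2 + se_f^2), the scale of the two-sample
#' sex-difference z test). All other SNP-trait pairs share one effect.
#' Ground-truth heterogeneity labels are retained for recovery tests.
#'
#' @param n_snps number of SNPs.
#' @param frac_heterogeneous fraction of SNPs with a true sex difference.
#' @param traits trait labels.
#' @param seed integer seed.
#' @param se_m,se_f per-sex standard errors of the effect estimates.
#' @param shared_effect_sd SD of the shared true effects across SNPs.
#' @param diff_scale true male-female difference at heterogeneous SNPs, in
#'   combined-SE units.
#' @return A data.frame of class `sex_strat_sumstats`, one row per SNP x
#'   trait: `snp, chrom, pos, trait, beta_m, se_m, beta_f, se_f, p_m, p_f,
#'   beta_comb, se_comb, p_comb, true_het`.
#' @export
simulate_anthro_sumstats <- function(n_snps, frac_heterogeneous = 0.05,
                                     traits = c("height", "weight", "BMI",
                                                "HIP", "WC"),
                                     seed = 1L,
                                     se_m = 0.01, se_f = 0.01,
                                     shared_effect_sd = 0.02,
                                     diff_scale = 4) {
  stopifnot(n_snps > 0, frac_heterogeneous >= 0, frac_heterogeneous <= 1,
            length(traits) >= 1)
  with_substream(seed, "anthro_sumstats", {
    n_het <- round(n_snps * frac_heterogeneous)
    het_snp <- sample.int(n_snps, n_het)
    het_trait <- sample(traits, n_het, replace = TRUE)
    se_comb <- sqrt(se_m^2 + se_f^2)
    out <- lapply(traits, function(tr) {
      b_shared <- stats::rnorm(n_snps, 0, shared_effect_sd)
      b_m <- b_shared
      b_f <- b_shared
      hit <- het_snp[het_trait == tr]
      if (length(hit)) {
        half <- diff_scale * se_comb / 2
        sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
        b_m[hit] <- b_shared[hit] + sgn * half
        b_f[hit] <- b_shared[hit] - sgn * half
      }
      bm <- stats::rnorm(n_snps, b_m, se_m)
      bf <- stats::rnorm(n_snps, b_f, se_f)
      w_m <- 1 / se_m^2
      w_f <- 1 / se_f^2
      bc <- (bm * w_m + bf * w_f) / (w_m + w_f)
      sec <- 1 / sqrt(w_m + w_f)
      data.frame(
        snp = sprintf("gsnp%06d", seq_len(n_snps)),
        chrom = as.character(1 + (seq_len(n_snps) - 1) %% 22),
        pos = seq_len(n_snps) * 1000L,
        trait = tr,
        beta_m = bm, se_m = se_m, beta_f = bf, se_f = se_f,
        p_m = 2 * stats::pnorm(-abs(bm / se_m)),
        p_f = 2 * stats::pnorm(-abs(bf / se_f)),
        beta_comb = bc, se_comb = sec,
        p_comb = 2 * stats::pnorm(-abs(bc / sec)),
        true_het = seq_len(n_snps) %in% hit,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    class(out) <- c("sex_strat_sumstats", "data.frame")
    out
  })
}

#' Simulate fetal-brain-like expression panels with sex-biased genes
#'
#' Each panel is a gene-by-sample matrix of Gaussian expression values with
#' balanced sample sexes; a fraction of genes carries a mean shift between
#' male and female samples (half shifted up in males, half down), emulating a
#' sex-correlated expression signature. Panels differ in sample size to
#' exercise sample-size-weighted averaging downstream.
#'
#' @param n_genes number of genes (shared across panels).
#' @param n_samples_per_panel integer vector of per-panel sample counts
#'   (at least two panels).
#' @param sex_biased_gene_fraction fraction of genes with a true sex bias.
#' @param seed integer seed.
#' @param bias_delta mean male-female shift at biased genes, in residual-SD
#'   units (at balanced sexes the induced gene-sex correlation is
#'   delta/sqrt(delta^2 + 4)).
#' @return An object of class `expression_panels`: `panels`, a list with
#'   elements `expr` (genes x samples), `sex`, `n`; and `truth`, a data.frame
#'   `gene, bias` (+1 male-up, -1 male-down, 0 unbiased).
#' @export
simulate_expression_panels <- function(n_genes, n_samples_per_panel,
                                       sex_biased_gene_fraction = 0.1,
                                       seed = 1L, bias_delta = 1) {
  stopifnot(n_genes > 0, length(n_samples_per_panel) >= 2,
            all(n_samples_per_panel >= 4),
            sex_biased_gene_fraction >= 0, sex_biased_gene_fraction <= 1)
  with_substream(seed, "expression_panels", {
    n_bias <- round(n_genes * sex_biased_gene_fraction)
    bias <- rep(0, n_genes)
    if (n_bias > 0) {
      idx <- sample.int(n_genes, n_bias)
      bias[idx] <- rep_len(c(1, -1), n_bias)
    }
    genes <- sprintf("gene%05d", seq_len(n_genes))
    panels <- lapply(seq_along(n_samples_per_panel), function(k) {
      n <- n_samples_per_panel[k]
      sex <- rep_len(c("male", "female"), n)
      male <- as.numeric(sex == "male") - 0.5
      expr <- matrix(stats::rnorm(n_genes * n), n_genes, n) +
        outer(bias * bias_delta, male)
      rownames(expr) <- genes
      colnames(expr) <- sprintf("p%d_s%03d", k, seq_len(n))
      list(expr = expr, sex = sex, n = n)
    })
    structure(
      list(panels = panels,
           truth = data.frame(gene = genes, bias = bias,
                              stringsAsFactors = FALSE)),
      class = "expression_panels"
    )
  })
}
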