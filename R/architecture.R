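#' Genetic architecture under a sex-specific liability-threshold model
#'
#' Describes the simulated genome and disease model: a SNP panel across
#' chromosomes 1-22 and X, a set of causal SNPs with per-sex liability-scale
#' effects, a liability heritability, and per-sex liability thresholds in
#' standard-deviation units. Disease liability for an individual is
#' `g + e`, where the polygenic value `g` is the causal-dosage score
#' standardised (within sex, from the expected dosage variances) to variance
#' `h2_liability`, and `e` is Gaussian with variance `1 - h2_liability`; an
#' individual is affected when liability exceeds its sex's threshold.
#' A higher female threshold therefore reproduces male-biased prevalence and
#' forces ascertained females to carry more polygenic load.
#'
#' Default thresholds are the normal quantiles of prevalences of 1/42 in
#' males and 1/189 in females, the reported rates for autism spectrum
#' disorder, giving roughly a 4.5:1 male:female prevalence ratio.
#'
#' Allele frequencies and positions are drawn once at construction (substream
#' "panel" of `seed`), so every cohort simulated from one spec shares the same
#' SNP panel.
#'
#' @param n_snps_by_chrom named integer vector of SNP counts, names in
#'   `c(1:22, "X")`.
#' @param maf_range length-2 numeric, allele-frequency range in (0, 0.5].
#' @param causal `NULL` (null architecture) or a data.frame with columns
#'   `snp` (index into the panel), `beta_male`, `beta_female` (per-allele
#'   liability-scale effects; relative sizes matter, the absolute scale is set
#'   by `h2_liability`).
#' @param h2_liability liability-scale heritability in [0, 1].
#' @param threshold_male,threshold_female liability cutoffs (z units).
#' @param x_male_beta_scale multiplier applied to male per-allele effects at
#'   X-linked causal SNPs (1 = no dosage-compensation scaling).
#' @param seed integer root seed; all simulation draws descend from it.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(n_snps_by_chrom = c("1" = 100),
                              maf_range = c(0.05, 0.5),
                              causal = NULL,
                              h2_liability = 0.5,
                              threshold_male = stats::qnorm(1 - 1 / 42),
                              threshold_female = stats::qnorm(1 - 1 / 189),
                              x_male_beta_scale = 1,
                              seed = 1L) {
  stopifnot(
    length(n_snps_by_chrom) >= 1, all(n_snps_by_chrom >= 0),
    !is.null(names(n_snps_by_chrom)),
    all(names(n_snps_by_chrom) %in% c(as.character(1:22), "X")),
    length(maf_range) == 2, all(is.finite(maf_range)),
    maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
    is.finite(h2_liability), h2_liability >= 0, h2_liability <= 1,
    is.finite(threshold_male), is.finite(threshold_female)
  )
  m <- sum(n_snps_by_chrom)
  chrom <- rep(names(n_snps_by_chrom), n_snps_by_chrom)
  snp_info <- with_substream(seed, "panel", {
    pos <- unlist(lapply(n_snps_by_chrom, function(k) {
      sort(sample.int(2.4e8, k))
    }), use.names = FALSE)
    data.frame(
      id = sprintf("snp%06d", seq_len(m)),
      chrom = chrom,
      pos = as.integer(pos),
      a1 = "A", a2 = "G",
      freq = stats::runif(m, maf_range[1], maf_range[2]),
      stringsAsFactors = FALSE
    )
  })
  if (!is.null(causal)) {
    stopifnot(
      is.data.frame(causal),
      all(c("snp", "beta_male", "beta_female") %in% names(causal)),
      all(causal$snp >= 1 & causal$snp <= m),
      !anyDuplicated(causal$snp),
      all(is.finite(causal$beta_male)), all(is.finite(causal$beta_female))
    )
  }
  structure(
    list(
      n_snps_by_chrom = n_snps_by_chrom, maf_range = maf_range,
      snp_info = snp_info, causal = causal, h2_liability = h2_liability,
      threshold_male = threshold_male, threshold_female = threshold_female,
      x_male_beta_scale = x_male_beta_scale, seed = as.integer(seed)
    ),
    class = "architecture_spec"
  )
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf(
    "architecture_spec: %d SNPs on %d chromosome(s), %d causal\n",
    nrow(x$snp_info), length(x$n_snps_by_chrom),
    if (is.null(x$causal)) 0L else nrow(x$causal)
  ))
  cat(sprintf(
    "  h2_liability = %.3f, thresholds male %.3f / female %.3f (prev %.4f / %.4f)\n",
    x$h2_liability, x$threshold_male, x$threshold_female,
    1 - stats::pnorm(x$threshold_male), 1 - stats::pnorm(x$threshold_female)
  ))
  invisible(x)
}

# Per-sex causal-score coefficients and centering, standardised so that the
# expected variance of the polygenic value is exactly h2_liability. Returns
# NULL for a sex with no genetic variance (score is identically 0 and the
# residual then has unit variance).
causal_scale <- function(spec, sex) {
  cz <- spec$causal
  if (is.null(cz) || nrow(cz) == 0) return(NULL)
  si <- spec$snp_info[cz$snp, ]
  p <- si$freq
  on_x <- si$chrom == "X"
  beta <- if (sex == "male") cz$beta_male else cz$beta_female
  if (sex == "male") beta[on_x] <- beta[on_x] * spec$x_male_beta_scale
  mean_dose <- ifelse(on_x & sex == "male", p, 2 * p)
  var_dose <- ifelse(on_x & sex == "male", p * (1 - p), 2 * p * (1 - p))
  v <- sum(beta^2 * var_dose)
  if (v <= 0) return(NULL)
  s <- sqrt(spec$h2_liability / v)
  list(snp = cz$snp, beta = beta * s, mean_dose = mean_dose)
}

# Polygenic liability value for a dosage matrix restricted to causal columns
# (individuals x causal SNPs, column order = spec$causal$snp order).
causal_score <- function(causal_dosages, scale) {
  if (is.null(scale)) return(rep(0, nrow(causal_dosages)))
  drop(sweep(causal_dosages, 2, scale$mean_dose) %*% scale$beta)
}

liability_resid_sd <- function(spec, scale) {
  if (is.null(scale)) 1 else sqrt(1 - spec$h2_liability)
}
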