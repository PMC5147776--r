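#' Fixed-effects (inverse-variance) meta-analysis across strata
#'
#' Combines per-SNP association records from several strata (e.g. trio and
#' case-control designs, or male and female analyses) with weights
#' `w_i = 1/se_i^2`: `beta_meta = sum(w_i beta_i) / sum(w_i)`,
#' `se_meta = 1/sqrt(sum(w_i))`, two-sided p from the normal. Cochran's Q
#' (`sum w_i (beta_i - beta_meta)^2`, chi-square with k-1 df) quantifies
#' between-stratum heterogeneity; with a single usable stratum the combined
#' estimate is that stratum's and Q is undefined.
#'
#' Records with missing/non-finite `se` or a `converged = FALSE` flag are
#' excluded per SNP. Effect alleles are assumed harmonised (all records
#' oriented to the cohort minor allele, as the association functions emit).
#'
#' @param records named list of per-stratum data.frames with columns
#'   `snp, beta, se` (optionally `converged`).
#' @return A data.frame with columns `snp, beta_meta, se_meta, p_meta, k, Q,
#'   p_Q` and per-stratum `beta_<name>`, `se_<name>`.
#' @export
fixed_effects_meta <- function(records) {
  stopifnot(is.list(records), length(records) >= 1, !is.null(names(records)))
  strata <- names(records)
  clean <- lapply(records, function(r) {
    usable <- is.finite(r$beta) & is.finite(r$se) & r$se > 0
    if (!is.null(r$converged)) usable <- usable & r$converged
    r[usable, c("snp", "beta", "se")]
  })
  snps <- unique(unlist(lapply(clean, `[[`, "snp")))
  B <- SE <- matrix(NA_real_, length(snps), length(strata),
                    dimnames = list(snps, strata))
  for (s in strata) {
    i <- match(clean[[s]]$snp, snps)
    B[i, s] <- clean[[s]]$beta
    SE[i, s] <- clean[[s]]$se
  }
  W <- 1 / SE^2
  w_sum <- rowSums(W, na.rm = TRUE)
  beta_meta <- rowSums(W * B, na.rm = TRUE) / w_sum
  se_meta <- 1 / sqrt(w_sum)
  k <- rowSums(!is.na(B))
  Q <- rowSums(W * (B - beta_meta)^2, na.rm = TRUE)
  Q[k < 2] <- NA_real_
  out <- data.frame(
    snp = snps,
    beta_meta = beta_meta, se_meta = se_meta,
    p_meta = 2 * stats::pnorm(-abs(beta_meta / se_meta)),
    k = k, Q = Q,
    p_Q = stats::pchisq(Q, df = pmax(k - 1, 1), lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  for (s in strata) {
    out[[paste0("beta_", s)]] <- B[, s]
    out[[paste0("se_", s)]] <- SE[, s]
  }
  rownames(out) <- NULL
  out
}

#' Cochran's Q for male-female heterogeneity
#'
#' Two-stratum Q: the inverse-variance weighted sum of squared deviations of
#' the sex-specific effect estimates from their fixed-effects mean, referred
#' to a chi-square with 1 df.
#'
#' @param male,female data.frames with columns `snp, beta, se` (vectors of
#'   equal length also accepted via one-row frames).
#' @return A data.frame `snp, Q, p_Q`; undefined (NA, flagged in
#'   `testable`) where either stratum is unusable.
#' @export
cochran_q <- function(male, female) {
  m <- fixed_effects_meta(list(male = male, female = female))
  data.frame(snp = m$snp, Q = m$Q, p_Q = m$p_Q, testable = m$k == 2,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR q-values, monotone non-decreasing in p.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values (same length; empty in, empty out).
#' @export
bh_qvalues <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  stopifnot(all(is.na(pvals) | (pvals > 0 & pvals <= 1)))
  stats::p.adjust(pvals, method = "BH")
}

#' Greedy LD clumping of association results
#'
#' Orders SNPs by ascending p (ties broken by chromosome, position, id) and
#' greedily selects index SNPs; a SNP is absorbed into an earlier index SNP
#' on the same chromosome within `window_bp` with dosage `r^2 > r2_max`.
#'
#' @param records data.frame with columns `snp` and a p-value column `p`
#'   (or `p_meta`).
#' @param g a [genotype_table()] supplying positions and dosages for r^2.
#' @param r2_max r-squared ceiling above which a SNP is absorbed.
#' @param window_bp physical window around the index SNP.
#' @param k number of index SNPs to return.
#' @return Character vector of up to `k` index SNP ids (shorter, with a
#'   warning, if fewer independent SNPs exist).
#' @export
ld_clump <- function(records, g, r2_max = 0.2, window_bp = 5e5, k = 20) {
  p <- if ("p" %in% names(records)) records$p else records$p_meta
  ok <- !is.na(p)
  records <- records[ok, , drop = FALSE]
  p <- p[ok]
  j <- match(records$snp, g$snp_info$id)
  if (anyNA(j)) stop("records contain SNPs absent from the genotype table")
  chrom <- g$snp_info$chrom[j]
  pos <- g$snp_info$pos[j]
  ord <- order(p, chrom, pos, records$snp)
  idx <- integer(0)
  absorbed <- rep(FALSE, length(ord))
  d_imp <- g$dosages[, j, drop = FALSE]
  mu <- colMeans(d_imp, na.rm = TRUE)
  for (jj in seq_len(ncol(d_imp))) {
    nas <- is.na(d_imp[, jj])
    if (any(nas)) d_imp[nas, jj] <- mu[jj]
  }
  for (oi in seq_along(ord)) {
    i <- ord[oi]
    if (absorbed[i]) next
    idx <- c(idx, i)
    if (length(idx) >= k) break
    near <- which(!absorbed & chrom == chrom[i] &
                    abs(pos - pos[i]) <= window_bp)
    near <- setdiff(near, i)
    if (length(near)) {
      r2 <- suppressWarnings(
        stats::cor(d_imp[, i], d_imp[, near, drop = FALSE])^2
      )
      absorbed[near[!is.na(r2) & r2 > r2_max]] <- TRUE
    }
  }
  if (length(idx) < k) {
    warning(sprintf("only %d LD-independent SNPs available (requested %d)",
                    length(idx), k))
  }
  records$snp[idx]
}

#' Binomial sign test on effect directions across sexes
#'
#' For the top SNPs of one sex, the fraction whose minor-allele effect has
#' the same sign in the other sex's results, with an exact two-sided binomial
#' p-value against `expected_fraction` (in the permutation workflow, the mean
#' same-direction fraction over sex-permuted runs). The two-sided p sums all
#' outcomes with probability at most that of the observed count. SNPs with a
#' zero or missing beta in either sex are excluded from the count.
#'
#' @param top data.frame of the ascertaining sex's records (`snp`, `beta`),
#'   already restricted to the top LD-independent SNPs.
#' @param other data.frame of the other sex's records (`snp`, `beta`).
#' @param expected_fraction null same-direction probability.
#' @return A list with `fraction_same`, `n_used`, `n_same`, `p`.
#' @export
sign_test <- function(top, other, expected_fraction = 0.5) {
  b_other <- other$beta[match(top$snp, other$snp)]
  if (anyNA(match(top$snp, other$snp))) {
    stop("top SNPs missing from the other-sex results")
  }
  use <- !is.na(top$beta) & !is.na(b_other) & top$beta != 0 & b_other != 0
  n_excl <- sum(!use)
  if (n_excl > 0) {
    message(sprintf("sign_test: excluded %d SNP(s) with zero/missing beta",
                    n_excl))
  }
  same <- sign(top$beta[use]) == sign(b_other[use])
  n <- sum(use)
  x <- sum(same)
  p <- if (n > 0) {
    stats::binom.test(x, n, p = expected_fraction)$p.value
  } else NA_real_
  list(fraction_same = if (n > 0) x / n else NA_real_,
       n_used = n, n_same = x, p = p)
}
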