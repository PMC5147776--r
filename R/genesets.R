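#' Read / write gene intervals (BED)
#'
#' Gene intervals are handled internally with 1-based inclusive coordinates;
#' BED files (0-based half-open) are converted on read and write.
#'
#' @param path BED file (chrom, start, end, name).
#' @return A data.frame `gene, chrom, start, end, length`.
#' @export
read_gene_bed <- function(path) {
  b <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  out <- data.frame(gene = b[[4]], chrom = as.character(b[[1]]),
                    start = b[[2]] + 1L, end = b[[3]],
                    stringsAsFactors = FALSE)
  out$length <- out$end - out$start + 1L
  out
}

#' @rdname read_gene_bed
#' @param genes a gene-interval data.frame (1-based inclusive).
#' @export
write_gene_bed <- function(genes, path) {
  utils::write.table(
    data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Autosomal gene filter for set analyses
#'
#' Drops duplicated gene names, X/Y genes, and genes longer than
#' `max_length` (oversized genes cannot be length-matched).
#'
#' @param genes gene-interval data.frame.
#' @param max_length maximum gene length (default 92 Mb).
#' @return The filtered data.frame.
#' @export
filter_gene_intervals <- function(genes, max_length = 9.2e7) {
  keep <- !duplicated(genes$gene) &
    !genes$chrom %in% c("X", "Y") &
    (genes$end - genes$start + 1) <= max_length
  genes[keep, , drop = FALSE]
}

#' Assign SNPs to gene windows
#'
#' A SNP belongs to a gene iff `start - flank <= pos <= end + flank`
#' (1-based inclusive, boundaries included).
#'
#' @param genes gene-interval data.frame (`gene, chrom, start, end`).
#' @param snps SNP data.frame (`id, chrom, pos`).
#' @param flank flanking width in bp (default 5000).
#' @return Named list: per gene, the character vector of SNP ids in its
#'   window.
#' @export
snps_in_gene_windows <- function(genes, snps, flank = 5000) {
  if (nrow(genes) == 0) stop("empty gene list")
  out <- lapply(seq_len(nrow(genes)), function(i) {
    hit <- snps$chrom == genes$chrom[i] &
      snps$pos >= genes$start[i] - flank &
      snps$pos <= genes$end[i] + flank
    snps$id[hit]
  })
  names(out) <- genes$gene
  out
}

#' Union of a gene set's window SNPs, de-duplicated
#' @inheritParams snps_in_gene_windows
#' @return Character vector of unique SNP ids.
#' @export
gene_set_snps <- function(genes, snps, flank = 5000) {
  unique(unlist(snps_in_gene_windows(genes, snps, flank), use.names = FALSE))
}

#' Length-matched permuted gene sets
#'
#' For each target gene, the candidate list is the 100 pool genes closest in
#' length (ties by id order, target ids excluded from the pool); each
#' permutation samples one candidate per target gene, without replacement
#' within the permutation.
#'
#' @param target character vector of target gene ids (present in `genes`).
#' @param pool gene-interval data.frame to draw matches from (target ids are
#'   removed automatically).
#' @param genes gene-interval data.frame providing the targets' lengths.
#' @param n_perm number of permuted sets (default 100).
#' @param seed integer seed.
#' @param n_candidates candidate-list size (default 100; a smaller pool is
#'   used whole, with a warning).
#' @return A list of `n_perm` character vectors, each of `length(target)`.
#' @export
length_matched_null_sets <- function(target, pool, genes, n_perm = 100,
                                     seed = 1L, n_candidates = 100) {
  tlen <- genes$length[match(target, genes$gene)]
  if (anyNA(tlen)) stop("target gene(s) missing from the interval table")
  pool <- pool[!pool$gene %in% target, , drop = FALSE]
  if (nrow(pool) < n_candidates) {
    warning(sprintf("pool (%d genes) smaller than the candidate-list size %d",
                    nrow(pool), n_candidates))
  }
  ord_pool <- pool[order(pool$gene), , drop = FALSE]
  candidates <- lapply(tlen, function(L) {
    d <- abs(ord_pool$length - L)
    ord_pool$gene[order(d)[seq_len(min(n_candidates, nrow(ord_pool)))]]
  })
  with_substream(seed, "length_matched_sets", {
    lapply(seq_len(n_perm), function(b) {
      used <- character(0)
      out <- character(length(candidates))
      for (i in seq_along(candidates)) {
        avail <- setdiff(candidates[[i]], used)
        if (length(avail) == 0) avail <- setdiff(ord_pool$gene, used)
        out[i] <- avail[sample.int(length(avail), 1)]
        used <- c(used, out[i])
      }
      out
    })
  })
}

#' Sex-difference p-value from stratified summary statistics
#'
#' Two-sample z test of male vs female effect estimates:
#' `z = (beta_m - beta_f) / sqrt(se_m^2 + se_f^2)` against the standard
#' normal (equivalent to the two-stratum Cochran's Q).
#'
#' @param beta_m,se_m,beta_f,se_f stratified estimates and standard errors.
#' @return Two-sided p-values.
#' @export
sex_difference_p <- function(beta_m, se_m, beta_f, se_f) {
  z <- (beta_m - beta_f) / sqrt(se_m^2 + se_f^2)
  2 * stats::pnorm(-abs(z))
}

#' Select anthropometric-heterogeneous (AH) SNPs
#'
#' SNPs whose male and female effects on any anthropometric trait differ at
#' `p_diff < p_cut` (two-sample z), de-duplicated across traits (each SNP
#' keeps the trait with its smallest sex-difference p). SNPs missing one
#' sex's estimate at a trait are skipped for that trait.
#'
#' @param sumstats a `sex_strat_sumstats` data.frame
#'   (see [simulate_anthro_sumstats()]).
#' @param p_cut sex-difference p-value cutoff (default 1e-3).
#' @return A data.frame `snp, trait, p_diff, p_comb` of selected SNPs.
#' @export
ah_select <- function(sumstats, p_cut = 1e-3) {
  usable <- is.finite(sumstats$beta_m) & is.finite(sumstats$beta_f) &
    is.finite(sumstats$se_m) & is.finite(sumstats$se_f)
  n_skip <- sum(!usable)
  if (n_skip > 0) {
    message(sprintf("ah_select: skipped %d SNP-trait pair(s) missing one sex",
                    n_skip))
  }
  ss <- sumstats[usable, , drop = FALSE]
  p_diff <- sex_difference_p(ss$beta_m, ss$se_m, ss$beta_f, ss$se_f)
  sel <- which(p_diff < p_cut)
  if (length(sel) == 0) {
    return(data.frame(snp = character(0), trait = character(0),
                      p_diff = numeric(0), p_comb = numeric(0)))
  }
  out <- data.frame(snp = ss$snp[sel], trait = ss$trait[sel],
                    p_diff = p_diff[sel], p_comb = ss$p_comb[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_diff), ]
  out <- out[!duplicated(out$snp), ]
  rownames(out) <- NULL
  out
}

#' Association-matched permuted SNP sets
#'
#' Controls for SNP ascertainment via trait association: for each AH SNP, the
#' candidate list is the 100 pool SNPs (same trait, AH-selected SNPs
#' excluded) with the nearest combined-sex trait-association p-value; each
#' permutation samples one candidate per target SNP without replacement.
#'
#' @param target an [ah_select()] result (`snp, trait, p_comb`).
#' @param sumstats the full `sex_strat_sumstats` pool.
#' @param n_perm number of permuted sets.
#' @param seed integer seed.
#' @param n_candidates candidate-list size (default 100).
#' @return A list of `n_perm` character vectors of SNP ids.
#' @export
matched_assoc_null_sets <- function(target, sumstats, n_perm = 100,
                                    seed = 1L, n_candidates = 100) {
  candidates <- lapply(seq_len(nrow(target)), function(i) {
    pool <- sumstats[sumstats$trait == target$trait[i] &
                       !sumstats$snp %in% target$snp, , drop = FALSE]
    if (nrow(pool) < n_candidates) {
      warning("pool smaller than the candidate-list size")
    }
    d <- abs(pool$p_comb - target$p_comb[i])
    pool$snp[order(d, pool$snp)[seq_len(min(n_candidates, nrow(pool)))]]
  })
  with_substream(seed, "matched_assoc_sets", {
    lapply(seq_len(n_perm), function(b) {
      used <- character(0)
      out <- character(length(candidates))
      for (i in seq_along(candidates)) {
        avail <- setdiff(candidates[[i]], used)
        if (length(avail) == 0) {
          avail <- setdiff(unique(sumstats$snp), c(used, target$snp))
        }
        out[i] <- avail[sample.int(length(avail), 1)]
        used <- c(used, out[i])
      }
      out
    })
  })
}

#' Permutation enrichment of a SNP set
#'
#' Compares the FDR-threshold enrichment fraction (q < `q_threshold`,
#' q-values recomputed within each set's scope) of the true SNP set against
#' matched null sets; the empirical p is the proportion of null sets whose
#' fraction is at least the observed one.
#'
#' @param set_snps character vector of the true set's SNP ids.
#' @param null_sets list of permuted SNP-id sets.
#' @param records association records (`snp` + `p`/`p_meta`) covering all
#'   sets.
#' @param q_threshold FDR threshold (default 0.8).
#' @return An `enrichment_result`.
#' @export
set_enrichment <- function(set_snps, null_sets, records, q_threshold = 0.8) {
  frac_of <- function(ids) {
    enrichment_fraction(records[records$snp %in% ids, , drop = FALSE],
                        q_threshold)
  }
  observed <- frac_of(set_snps)
  permuted <- vapply(null_sets, frac_of, numeric(1))
  structure(
    list(observed_fraction = observed, permuted_fractions = permuted,
         empirical_p = empirical_p(observed, permuted, "greater"),
         q_threshold = q_threshold, snp_scope = "SNP set"),
    class = "enrichment_result"
  )
}

#' First principal component of a module's expression
#'
#' Summary profile (one value per sample) of a gene module: the first right
#' singular vector of the row-centred module submatrix, unit norm, sign fixed
#' so the largest-magnitude loading is positive.
#'
#' @param expr gene-by-sample expression matrix.
#' @param module_genes rownames of the module's genes (default: all rows).
#' @return Numeric vector, one entry per sample.
#' @export
module_pc1 <- function(expr, module_genes = rownames(expr)) {
  sub <- expr[rownames(expr) %in% module_genes, , drop = FALSE]
  sub <- sweep(sub, 1, rowMeans(sub))
  sv <- svd(sub, nu = 0, nv = 1)
  v <- sv$v[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

#' Sex-correlated (SC) gene scoring across expression panels
#'
#' Per gene and panel, the Pearson correlation with the panel's module first
#' principal component; correlations are Fisher-transformed (`atanh`),
#' averaged across panels with sample-size weights, back-transformed
#' (`tanh`), and classified: male-correlated (`r_bar > r_cut`),
#' male-anti-correlated (`r_bar < -r_cut`), otherwise unclassified.
#' Constant-expression genes have no defined correlation and are dropped
#' with a message.
#'
#' @param panels an `expression_panels` object
#'   (see [simulate_expression_panels()]).
#' @param module_pc1_per_panel list of per-panel PC1 vectors (one value per
#'   sample), e.g. from [module_pc1()].
#' @param r_cut classification threshold on the averaged correlation
#'   (default 0.3).
#' @return A data.frame `gene, r_bar, class` with class in
#'   `male-correlated / male-anticorrelated / unclassified`.
#' @export
sc_gene_scores <- function(panels, module_pc1_per_panel, r_cut = 0.3) {
  pl <- panels$panels
  stopifnot(length(module_pc1_per_panel) == length(pl))
  genes <- rownames(pl[[1]]$expr)
  Z <- matrix(NA_real_, length(genes), length(pl))
  wts <- vapply(pl, `[[`, numeric(1), "n")
  for (k in seq_along(pl)) {
    pc1 <- module_pc1_per_panel[[k]]
    sds <- apply(pl[[k]]$expr, 1, stats::sd)
    r <- rep(NA_real_, length(genes))
    ok <- sds > 0
    r[ok] <- suppressWarnings(drop(stats::cor(t(pl[[k]]$expr[ok, , drop = FALSE]),
                                              pc1)))
    Z[, k] <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  }
  defined <- rowSums(!is.na(Z)) > 0
  if (any(!defined)) {
    message(sprintf("sc_gene_scores: dropped %d constant-expression gene(s)",
                    sum(!defined)))
  }
  zbar <- vapply(seq_len(nrow(Z)), function(i) {
    ok <- !is.na(Z[i, ])
    sum(Z[i, ok] * wts[ok]) / sum(wts[ok])
  }, numeric(1))
  r_bar <- tanh(zbar)
  out <- data.frame(
    gene = genes, r_bar = r_bar,
    class = ifelse(r_bar > r_cut, "male-correlated",
                   ifelse(r_bar < -r_cut, "male-anticorrelated",
                          "unclassified")),
    stringsAsFactors = FALSE
  )[defined, , drop = FALSE]
  rownames(out) <- NULL
  out
}
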