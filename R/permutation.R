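#' Power-matched sex-permutation plans
#'
#' Builds the pipeline's central null: pseudo-sex assignments permuted within
#' technical batch x study design, with the pseudo-male set in every stratum
#' exactly matching that stratum's true male count — so a pseudo-male dataset
#' has the same size (power) as the true male dataset while mixing the sexes.
#' Trios permute as whole families (the unit is the proband); case-control
#' individuals permute individually, within their case/control role so
#' permuted analyses keep the true case:control balance.
#'
#' @param g a [genotype_table()] with batch/design metadata.
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed; plans are deterministic given it.
#' @return A list of class `permutation_plans`: each element is a data.frame
#'   `unit, stratum, pseudo_sex` (units are family ids for trios, individual
#'   ids otherwise); attribute `targets` records per-stratum male counts.
#' @export
make_permutation_plans <- function(g, n_perm = 100, seed = 1L) {
  meta <- g$meta
  if (any(is.na(meta$batch)) || any(is.na(meta$design))) {
    stop("every individual needs batch and design labels")
  }
  is_trio <- meta$design == "trio"
  kids <- meta[is_trio & meta$role == "proband", , drop = FALSE]
  cc <- meta[!is_trio & meta$role %in% c("case", "control"), , drop = FALSE]
  units <- rbind(
    data.frame(unit = kids$family, sex = kids$sex,
               stratum = paste(kids$batch, "trio", sep = ":"),
               stringsAsFactors = FALSE),
    if (nrow(cc)) data.frame(unit = cc$id, sex = cc$sex,
                             stratum = paste(cc$batch, "cc", cc$role, sep = ":"),
                             stringsAsFactors = FALSE)
  )
  if (nrow(units) == 0) stop("no permutable units (probands or case-control)")
  strata <- split(seq_len(nrow(units)), units$stratum)
  targets <- vapply(strata, function(i) sum(units$sex[i] == "male"), integer(1))
  if (any(vapply(strata, length, integer(1)) < targets)) {
    stop("stratum smaller than its male target: corrupt metadata")
  }
  plans <- with_substream(seed, "sex_permutation", {
    lapply(seq_len(n_perm), function(b) {
      pseudo <- rep("female", nrow(units))
      for (s in names(strata)) {
        i <- strata[[s]]
        pick <- i[sample.int(length(i), targets[[s]])]
        pseudo[pick] <- "male"
      }
      data.frame(unit = units$unit, stratum = units$stratum,
                 pseudo_sex = pseudo, stringsAsFactors = FALSE)
    })
  })
  attr(plans, "targets") <- targets
  class(plans) <- "permutation_plans"
  plans
}

#' Write / read permutation plans as TSV
#' @param plans a `permutation_plans` object.
#' @param path TSV path.
#' @return The path (write) or plans (read).
#' @export
write_permutation_plans <- function(plans, path) {
  rows <- do.call(rbind, lapply(seq_along(plans), function(b) {
    cbind(permutation = b, plans[[b]])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_permutation_plans
#' @export
read_permutation_plans <- function(path) {
  rows <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  plans <- lapply(split(rows, rows$permutation), function(d) {
    rownames(d) <- NULL
    d[, c("unit", "stratum", "pseudo_sex")]
  })
  class(plans) <- "permutation_plans"
  plans
}

# Pseudo-sex per analysis unit under a plan; NULL plan returns true sexes.
unit_sex <- function(g, plan = NULL) {
  meta <- g$meta
  is_trio <- meta$design == "trio"
  key <- ifelse(is_trio, meta$family, meta$id)
  sex <- meta$sex
  if (!is.null(plan)) {
    i <- match(key, plan$unit)
    sex <- ifelse(is.na(i), sex, plan$pseudo_sex[i])
  }
  sex
}

#' Sex-stratified association pipeline
#'
#' Runs the per-SNP association machinery in each sex stratum — TDT on trios
#' whose proband belongs to the stratum, covariate-adjusted logistic
#' regression on the stratum's case-control individuals — then combines the
#' two designs by fixed-effects meta-analysis within sex, meta-analyses the
#' sexes into combined results, and computes the male-female Cochran's Q.
#' With a permutation `plan` the strata are pseudo-sexes: trios move as whole
#' families, case-control individuals individually; genotypes and principal
#' components are unchanged (sex permutation does not alter genotypes, so PCs
#' are computed once on the full cohort).
#'
#' @param g a [genotype_table()] holding trios and/or case-control samples.
#' @param snps optional SNP id/index subset (analysis scope).
#' @param covariates optional per-individual covariate matrix with rownames
#'   matching individual ids (rows are subset per stratum).
#' @param plan optional one permutation plan from
#'   [make_permutation_plans()].
#' @return A list with data.frames `male`, `female` (per-sex meta of designs),
#'   `combined`, and `het` (Cochran's Q male vs female).
#' @export
sex_stratified_assoc <- function(g, snps = NULL, covariates = NULL,
                                 plan = NULL) {
  if (!is.null(snps)) g <- subset_genotypes(g, snps = snps)
  sex_of <- unit_sex(g, plan)
  per_sex <- list()
  for (sx in c("male", "female")) {
    recs <- list()
    in_sex <- sex_of == sx
    tri <- g$meta$design == "trio"
    if (any(in_sex & tri & g$meta$role == "proband")) {
      fams <- unique(g$meta$family[in_sex & tri & g$meta$role == "proband"])
      gt <- subset_genotypes(g, tri & g$meta$family %in% fams)
      recs$tdt <- tdt_scan(gt)
    }
    cc_rows <- in_sex & !tri & g$meta$role %in% c("case", "control") &
      !is.na(g$meta$affection)
    if (any(cc_rows)) {
      gcc <- subset_genotypes(g, cc_rows)
      if (length(unique(gcc$meta$affection)) == 2) {
        cov_cc <- NULL
        if (!is.null(covariates)) {
          cov_cc <- covariates[match(gcc$meta$id, rownames(covariates)), ,
                               drop = FALSE]
        }
        recs$cc <- logistic_scan(gcc, covariates = cov_cc)
      }
    }
    if (length(recs) == 0) {
      per_sex[[sx]] <- NULL
      next
    }
    m <- fixed_effects_meta(recs)
    per_sex[[sx]] <- data.frame(snp = m$snp, beta = m$beta_meta,
                                se = m$se_meta, p = m$p_meta,
                                stringsAsFactors = FALSE)
  }
  combined <- fixed_effects_meta(per_sex)
  het <- if (all(c("male", "female") %in% names(per_sex))) {
    cochran_q(per_sex$male, per_sex$female)
  } else NULL
  list(male = per_sex$male, female = per_sex$female,
       combined = combined, het = het)
}

#' FDR-threshold enrichment fraction
#'
#' The comparative association-signal metric: the fraction of SNPs in scope
#' whose Benjamini-Hochberg q-value (computed within that scope) falls below
#' `q_threshold` (default 0.8). The FDR level is a comparison metric, not a
#' significance claim.
#'
#' @param records data.frame with a `p` (or `p_meta`) column, already
#'   restricted to the scope of interest.
#' @param q_threshold FDR q-value cutoff.
#' @return The fraction in [0, 1].
#' @export
enrichment_fraction <- function(records, q_threshold = 0.8) {
  p <- if (is.data.frame(records)) {
    if ("p" %in% names(records)) records$p else records$p_meta
  } else records
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("empty SNP scope for enrichment")
  mean(bh_qvalues(p) < q_threshold)
}

#' Empirical p-value against a permutation distribution
#'
#' The proportion of permuted values at least as extreme as the observed one
#' in the stated direction. With `add_one = TRUE` the (r+1)/(n+1) variant is
#' used so a zero count is not reported as exactly 0.
#'
#' @param observed observed statistic.
#' @param permuted vector of permuted statistics.
#' @param direction "greater" (enrichment) or "less".
#' @param add_one use the (r+1)/(n+1) correction.
#' @return The empirical p-value.
#' @export
empirical_p <- function(observed, permuted, direction = c("greater", "less"),
                        add_one = FALSE) {
  direction <- match.arg(direction)
  stopifnot(length(permuted) >= 1)
  r <- if (direction == "greater") sum(permuted >= observed)
       else sum(permuted <= observed)
  if (add_one) (r + 1) / (length(permuted) + 1) else r / length(permuted)
}

#' Sex-specific association enrichment versus sex permutations
#'
#' The observed enrichment fraction (q < `q_threshold` within `snps`) of one
#' sex's association results, compared with the same quantity from each
#' sex-permuted pipeline run; the empirical p is the proportion of permuted
#' fractions at least as large.
#'
#' @param g a [genotype_table()].
#' @param sex "male" or "female": which stratum's signal to test.
#' @param plans [make_permutation_plans()] output.
#' @param snps SNP scope (ids or indices), e.g. autosomal or X SNPs.
#' @param q_threshold FDR threshold (default 0.8).
#' @param covariates optional covariate matrix (see
#'   [sex_stratified_assoc()]).
#' @return A list of class `enrichment_result`: `observed_fraction`,
#'   `permuted_fractions`, `empirical_p`, `q_threshold`, `snp_scope`.
#' @export
permutation_enrichment <- function(g, sex, plans, snps = NULL,
                                   q_threshold = 0.8, covariates = NULL) {
  obs <- sex_stratified_assoc(g, snps = snps, covariates = covariates)[[sex]]
  observed <- enrichment_fraction(obs, q_threshold)
  permuted <- vapply(plans, function(pl) {
    r <- sex_stratified_assoc(g, snps = snps, covariates = covariates,
                              plan = pl)[[sex]]
    enrichment_fraction(r, q_threshold)
  }, numeric(1))
  structure(
    list(observed_fraction = observed, permuted_fractions = permuted,
         empirical_p = empirical_p(observed, permuted, "greater"),
         q_threshold = q_threshold,
         snp_scope = if (is.null(snps)) "all" else "subset"),
    class = "enrichment_result"
  )
}

# Top-k heterogeneity fraction for one pipeline run: clump the sex-specific
# results, take the top-k index SNPs, and compute the fraction whose
# Cochran's Q q-value (BH within the top-k set) falls below the FDR level.
top_het_fraction <- function(res, g, sex, q_fdr_level, k, r2_max, window_bp) {
  recs <- res[[sex]]
  if (is.null(recs) || is.null(res$het)) return(NA_real_)
  top <- suppressWarnings(
    ld_clump(recs, g, r2_max = r2_max, window_bp = window_bp, k = k)
  )
  pq <- res$het$p_Q[match(top, res$het$snp)]
  pq <- pq[!is.na(pq)]
  if (length(pq) == 0) return(NA_real_)
  mean(bh_qvalues(pq) < q_fdr_level)
}

#' Top-SNP heterogeneity excess versus sex permutations
#'
#' For one sex, takes the top `k` LD-independent SNPs of the sex-specific
#' association results (within the SNP scope), computes the fraction whose
#' male-female Cochran's Q q-value (BH within the top-k set) falls below
#' `q_fdr_level`, and compares it with the identical pipeline applied to each
#' sex-permuted plan. The FDR level is chosen per analysis to adjust for
#' ascertaining SNPs by association (X: male 0.2, female 0.01; autosomes:
#' male 0.2, female 0.001).
#'
#' @param g a [genotype_table()].
#' @param sex ascertaining sex.
#' @param q_fdr_level FDR level applied to the top-k Q q-values.
#' @param plans [make_permutation_plans()] output.
#' @param snps SNP scope (e.g. X-chromosome SNP ids).
#' @param k number of top LD-independent SNPs (20 for X, 100 for autosomes).
#' @param r2_max,window_bp clumping parameters.
#' @param covariates optional covariate matrix.
#' @return An `enrichment_result` (observed and permuted heterogeneity
#'   fractions, empirical p).
#' @export
permuted_het_excess <- function(g, sex, q_fdr_level, plans, snps = NULL,
                                k = 20, r2_max = 0.2, window_bp = 5e5,
                                covariates = NULL) {
  obs_res <- sex_stratified_assoc(g, snps = snps, covariates = covariates)
  observed <- top_het_fraction(obs_res, g, sex, q_fdr_level, k,
                               r2_max, window_bp)
  permuted <- vapply(plans, function(pl) {
    r <- sex_stratified_assoc(g, snps = snps, covariates = covariates,
                              plan = pl)
    top_het_fraction(r, g, sex, q_fdr_level, k, r2_max, window_bp)
  }, numeric(1))
  structure(
    list(observed_fraction = observed, permuted_fractions = permuted,
         empirical_p = empirical_p(observed, permuted[!is.na(permuted)],
                                   "greater"),
         q_threshold = q_fdr_level,
         snp_scope = if (is.null(snps)) "all" else "subset"),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: observed %.4f vs %d permutations (empirical p = %.3f, q < %g, scope %s)\n",
    x$observed_fraction, length(x$permuted_fractions), x$empirical_p,
    x$q_threshold, x$snp_scope
  ))
  invisible(x)
}
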