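#' Genetic relationship matrix
#'
#' Standard GRM from standardised genotypes:
#' `A[i,k] = (1/m) sum_j (x_ij - 2 p_j)(x_kj - 2 p_j) / (2 p_j (1 - p_j))`
#' over autosomal SNPs (by default), with allele frequencies computed in the
#' cohort, missing dosages mean-imputed per SNP, and monomorphic SNPs
#' excluded with a warning.
#'
#' @param g a [genotype_table()] (MAF-filtered upstream).
#' @param autosomes_only restrict to autosomal SNPs (default TRUE).
#' @return An object of class `grm`: `A` (n x n), `m` (SNP count), `ids`,
#'   and the standardisation constants (`snp`, `freq`).
#' @export
compute_grm <- function(g, autosomes_only = TRUE) {
  keep <- if (autosomes_only) g$snp_info$chrom != "X" else
    rep(TRUE, ncol(g$dosages))
  gs <- subset_genotypes(g, snps = keep)
  p <- a1_frequency(gs)
  poly <- !is.na(p) & p > 0 & p < 1
  if (any(!poly)) {
    warning(sprintf("excluding %d monomorphic SNP(s) from the GRM",
                    sum(!poly)))
  }
  gs <- subset_genotypes(gs, snps = poly)
  p <- p[poly]
  W <- standardized_dosages(gs$dosages, p)
  m <- ncol(W)
  A <- tcrossprod(W) / m
  structure(
    list(A = A, m = m, ids = gs$meta$id,
         snp = gs$snp_info$id, freq = p),
    class = "grm"
  )
}

# Center at 2p and scale by sqrt(2p(1-p)); missing -> 0 after centering.
standardized_dosages <- function(d, p) {
  W <- sweep(d, 2, 2 * p)
  W[is.na(W)] <- 0
  sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
}

#' GRM-based relatedness filter
#'
#' Greedy removal of individuals until no GRM off-diagonal exceeds `cutoff`
#' (default 0.1): at each step the individual involved in the most
#' above-cutoff pairs is dropped (ties broken by index order), so the result
#' is deterministic. This is the GRM-off-diagonal analogue of an IBD
#' (PI-HAT) relatedness filter.
#'
#' @param grm a [compute_grm()] result.
#' @param cutoff maximum allowed off-diagonal relatedness.
#' @return Character vector of retained individual ids.
#' @export
grm_relatedness_filter <- function(grm, cutoff = 0.1) {
  A <- grm$A
  n <- nrow(A)
  keep <- rep(TRUE, n)
  off <- A
  diag(off) <- 0
  repeat {
    counts <- rowSums(off[keep, keep, drop = FALSE] > cutoff)
    if (all(counts == 0)) break
    worst <- which(keep)[which.max(counts)]
    keep[worst] <- FALSE
  }
  grm$ids[keep]
}

#' Subset a GRM to a set of individuals
#' @param grm a [compute_grm()] result.
#' @param ids individual ids to keep.
#' @return A `grm`.
#' @export
subset_grm <- function(grm, ids) {
  i <- match(ids, grm$ids)
  if (anyNA(i)) stop("unknown individual id(s) in GRM subset")
  structure(list(A = grm$A[i, i, drop = FALSE], m = grm$m, ids = grm$ids[i],
                 snp = grm$snp, freq = grm$freq), class = "grm")
}

# Diagonalised REML machinery: with A = U D U', rotate y and X so the
# variance V = Vg A + Ve I is diagonal, making every REML quantity O(n q^2).
reml_pieces <- function(d, yr, Xr, Vg, Ve) {
  v <- Vg * d + Ve
  if (min(v) <= 0) return(NULL)
  vinv <- 1 / v
  Xv <- Xr * vinv
  C <- crossprod(Xr, Xv)                       # X' V^-1 X
  Cinv <- tryCatch(chol2inv(chol(C)), error = function(e) NULL)
  if (is.null(Cinv)) return(NULL)
  Pvec <- function(z) {
    vz <- vinv * z
    vz - Xv %*% (Cinv %*% crossprod(Xv, z))
  }
  w <- drop(Pvec(yr))                          # P y
  # tr(P M) for M diagonal(md): sum(md * vinv) - tr(Cinv X' V^-1 M V^-1 X)
  trP <- function(md) {
    sum(md * vinv) - sum(Cinv * crossprod(Xr * (md * vinv^2), Xr))
  }
  ll <- -0.5 * (sum(log(v)) + determinant(C, logarithm = TRUE)$modulus[1] +
                  sum(yr * w))
  list(v = v, w = w, Pvec = Pvec, trP = trP, ll = as.numeric(ll))
}

#' Unconstrained observed-scale REML heritability
#'
#' Restricted maximum likelihood for the one-component model
#' `y = X b + g + e`, `g ~ (0, A Vg)`, `e ~ (0, I Ve)`, fitted by
#' average-information updates with expectation-maximisation fallback.
#' The fit is unconstrained: `Vg` may go negative (as long as the total
#' variance stays positive definite), so `h2_obs = Vg / (Vg + Ve)` can fall
#' outside [0, 1] — the behaviour needed for unbiased comparison of
#' heritability series. Standard errors come from the average-information
#' matrix via the delta method.
#'
#' @param grm a [compute_grm()] result (or subset).
#' @param phenotype numeric vector aligned with `grm$ids`.
#' @param covariates optional matrix of quantitative covariates (an intercept
#'   is always added).
#' @param max_iter maximum REML iterations (default 100).
#' @param tol convergence tolerance on the log-likelihood change.
#' @return An object of class `heritability_estimate`: `V_g, V_e, h2_obs,
#'   se_h2, se_Vg, loglik, converged, n_iter, n, m`.
#' @export
reml_h2 <- function(grm, phenotype, covariates = NULL, max_iter = 100,
                    tol = 1e-8) {
  y <- as.numeric(phenotype)
  n <- length(y)
  stopifnot(n == nrow(grm$A), all(is.finite(y)))
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  eg <- eigen(grm$A, symmetric = TRUE)
  d <- eg$values
  yr <- drop(crossprod(eg$vectors, y))
  Xr <- crossprod(eg$vectors, X)

  vp <- stats::var(y)
  Vg <- vp / 2
  Ve <- vp / 2
  pieces <- reml_pieces(d, yr, Xr, Vg, Ve)
  converged <- FALSE
  AI <- NULL
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    w <- pieces$w
    Dw <- d * w
    t1 <- drop(pieces$Pvec(Dw))
    t2 <- drop(pieces$Pvec(w))
    AI <- 0.5 * matrix(c(sum(Dw * t1), sum(Dw * t2),
                         sum(Dw * t2), sum(w * t2)), 2, 2)
    score <- -0.5 * c(pieces$trP(d) - sum(w * Dw),
                      pieces$trP(rep(1, length(d))) - sum(w * w))
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    new_pieces <- NULL
    if (!is.null(step) && all(is.finite(step))) {
      new_pieces <- reml_pieces(d, yr, Xr, Vg + step[1], Ve + step[2])
      if (!is.null(new_pieces) && new_pieces$ll >= pieces$ll - 1e-10) {
        Vg <- Vg + step[1]
        Ve <- Ve + step[2]
      } else {
        new_pieces <- NULL
      }
    }
    if (is.null(new_pieces)) {
      # EM fallback: guaranteed-ascent, positivity-preserving updates
      Vg_em <- Vg + Vg^2 * (sum(w * Dw) - pieces$trP(d)) / n
      Ve_em <- Ve + Ve^2 * (sum(w * w) - pieces$trP(rep(1, length(d)))) / n
      new_pieces <- reml_pieces(d, yr, Xr, Vg_em, Ve_em)
      if (is.null(new_pieces)) break
      Vg <- Vg_em
      Ve <- Ve_em
    }
    delta <- new_pieces$ll - pieces$ll
    pieces <- new_pieces
    if (abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }
  Sigma <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  tot <- Vg + Ve
  grad <- c(Ve, -Vg) / tot^2
  se_h2 <- sqrt(drop(t(grad) %*% Sigma %*% grad))
  structure(
    list(V_g = Vg, V_e = Ve, h2_obs = Vg / tot,
         se_h2 = se_h2, se_Vg = sqrt(Sigma[1, 1]),
         loglik = pieces$ll, converged = converged, n_iter = iter,
         n = n, m = grm$m),
    class = "heritability_estimate"
  )
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf(
    "h2_obs = %.4f (se %.4f), Vg = %.4f, Ve = %.4f; n = %d, m = %d; %s in %d iter\n",
    x$h2_obs, x$se_h2, x$V_g, x$V_e, x$n, x$m,
    if (x$converged) "converged" else "NOT converged", x$n_iter
  ))
  invisible(x)
}

#' Spike-in step sizes
#'
#' Numbers of pairs added at each step of the stepwise spike-in series:
#' `0, step, 2*step, ...` up to the full pool, with a final partial step if
#' the pool size is not a multiple of `step`. A pool of 953 pairs in steps of
#' 10 yields 97 nested sets.
#'
#' @param n_pairs pool size.
#' @param step pairs added per step (default 10).
#' @return Integer vector of cumulative pair counts, starting at 0.
#' @export
spike_in_steps <- function(n_pairs, step = 10) {
  s <- seq(0L, n_pairs, by = step)
  if (s[length(s)] < n_pairs) s <- c(s, n_pairs)
  as.integer(s)
}

#' Stepwise spike-in heritability series
#'
#' Starting from a base proband/pseudo-control cohort, adds pairs from the
#' pool in nested steps of `pairs_per_step`, re-estimates observed-scale
#' heritability for every set, and reports the Spearman rank correlation
#' between the number of pairs added and the h2 estimate. Non-converged sets
#' are recorded as missing and dropped from the correlation.
#'
#' @param base a [genotype_table()] of probands and pseudo-controls
#'   (affection 2/1), disjoint from the pool.
#' @param pool a [genotype_table()] of proband/pseudo-control pairs to add,
#'   grouped by `family`.
#' @param pairs_per_step pairs added per step (default 10).
#' @param covariates_k number of principal-component covariates computed per
#'   set (0 to skip).
#' @return A list of class `spike_in_series`: `series` (data.frame
#'   `n_added, h2, se, converged`), `rho`, `p` (Spearman), and the
#'   [spike_in_steps()] used.
#' @export
spike_in_series <- function(base, pool, pairs_per_step = 10,
                            covariates_k = 0) {
  if (any(pool$meta$id %in% base$meta$id)) {
    stop("pool pairs must be disjoint from the base set")
  }
  fams <- unique(pool$meta$family)
  steps <- spike_in_steps(length(fams), pairs_per_step)
  series <- lapply(steps, function(s) {
    g <- if (s == 0) base else {
      bind_genotype_tables(
        base, subset_genotypes(pool, pool$meta$family %in% fams[seq_len(s)])
      )
    }
    grm <- compute_grm(g)
    covs <- if (covariates_k > 0) pca_covariates(g, covariates_k) else NULL
    est <- reml_h2(grm, g$meta$affection - 1L, covariates = covs)
    data.frame(n_added = s,
               h2 = if (est$converged) est$h2_obs else NA_real_,
               se = est$se_h2, converged = est$converged)
  })
  series <- do.call(rbind, series)
  usable <- !is.na(series$h2)
  ct <- if (sum(usable) >= 3) {
    suppressWarnings(stats::cor.test(series$n_added[usable],
                                     series$h2[usable], method = "spearman"))
  } else NULL
  structure(
    list(series = series,
         rho = if (is.null(ct)) NA_real_ else unname(ct$estimate),
         p = if (is.null(ct)) NA_real_ else ct$p.value,
         steps = steps),
    class = "spike_in_series"
  )
}

#' BLUP SNP effects from a fitted heritability model
#'
#' Individual genetic values by best linear unbiased prediction,
#' `ghat = Vg A (Vg A + Ve I)^-1 y_resid` (phenotype residualised on the
#' covariates), transformed to per-SNP solutions
#' `u = (1/m) W' A^+ ghat` with `W` the standardised genotype matrix, so that
#' `W u = ghat` on the training set (`A^+` is the pseudo-inverse, keeping the
#' transform defined for rank-deficient GRMs).
#'
#' @param grm the training [compute_grm()] result.
#' @param g the training [genotype_table()] (same individuals).
#' @param phenotype numeric vector.
#' @param estimate a converged [reml_h2()] fit with `V_g > 0`.
#' @param covariates optional covariate matrix used in the fit.
#' @return An object of class `snp_effects`: data.frame `snp, a1, u, freq`
#'   plus training descriptors, and `ghat` for the training individuals.
#' @export
blup_snp_effects <- function(grm, g, phenotype, estimate, covariates = NULL) {
  if (!estimate$converged) stop("heritability estimate did not converge")
  if (estimate$V_g <= 0) {
    stop("V_g <= 0: BLUP SNP effects are undefined for a non-positive genetic variance")
  }
  y <- as.numeric(phenotype)
  X <- cbind(rep(1, length(y)), covariates)
  y_res <- stats::lm.fit(X, y)$residuals
  A <- grm$A
  V <- estimate$V_g * A + diag(estimate$V_e, nrow(A))
  ghat <- estimate$V_g * (A %*% solve(V, y_res))
  eg <- eigen(A, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  Aplus_ghat <- eg$vectors[, pos, drop = FALSE] %*%
    (crossprod(eg$vectors[, pos, drop = FALSE], ghat) / eg$values[pos])
  keep <- match(grm$snp, g$snp_info$id)
  W <- standardized_dosages(g$dosages[, keep, drop = FALSE], grm$freq)
  u <- drop(crossprod(W, Aplus_ghat)) / grm$m
  structure(
    list(effects = data.frame(snp = grm$snp,
                              a1 = g$snp_info$a1[keep],
                              u = u, freq = grm$freq,
                              stringsAsFactors = FALSE),
         ghat = drop(ghat), train_ids = grm$ids, m = grm$m),
    class = "snp_effects"
  )
}

#' Polygenic risk scores from BLUP SNP solutions
#'
#' Per-individual sum of standardised dosage times the SNP solution over the
#' SNPs shared with the training panel (standardisation uses the training
#' frequencies). Missing dosages and SNPs absent from the target contribute 0
#' and are counted; an overlap below 50% of the training SNPs is an error.
#'
#' @param effects a [blup_snp_effects()] result.
#' @param target a [genotype_table()] disjoint from the training set.
#' @return A data.frame of class `risk_score_set`: `id, score`, plus the
#'   individual metadata columns; attribute `n_snps_used`.
#' @export
risk_scores <- function(effects, target) {
  eff <- effects$effects
  j <- match(eff$snp, target$snp_info$id)
  overlap <- mean(!is.na(j))
  if (overlap < 0.5) {
    stop(sprintf("only %.0f%% of training SNPs present in target (< 50%%)",
                 100 * overlap))
  }
  shared <- !is.na(j)
  W <- standardized_dosages(target$dosages[, j[shared], drop = FALSE],
                            eff$freq[shared])
  score <- drop(W %*% eff$u[shared])
  out <- cbind(data.frame(id = target$meta$id, score = score,
                          stringsAsFactors = FALSE),
               target$meta[, c("sex", "role", "affection", "batch")])
  rownames(out) <- NULL
  attr(out, "n_snps_used") <- sum(shared)
  class(out) <- c("risk_score_set", "data.frame")
  out
}

#' Welch two-sample comparison of risk scores
#'
#' @param scores a [risk_scores()] result (or any data.frame with `score`).
#' @param grouping two-level factor/vector aligned with `scores`.
#' @return A list `mean_difference, t, p, n` (group sizes). Identical groups
#'   give `t = 0, p = 1`; a single-member group is an error.
#' @export
group_compare <- function(scores, grouping) {
  grouping <- as.factor(grouping)
  stopifnot(nlevels(grouping) == 2)
  s <- split(scores$score, grouping)
  if (any(lengths(s) < 2)) stop("each group needs at least two members")
  md <- mean(s[[2]]) - mean(s[[1]])
  if (stats::var(s[[1]]) + stats::var(s[[2]]) == 0) {
    return(list(mean_difference = md, t = 0, p = 1, n = lengths(s)))
  }
  tt <- stats::t.test(s[[2]], s[[1]])
  list(mean_difference = md, t = unname(tt$statistic), p = tt$p.value,
       n = lengths(s))
}
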