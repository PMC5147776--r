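#' Transmission disequilibrium test across SNPs
#'
#' For every SNP, counts minor-allele transmissions (`b`) and
#' non-transmissions (`c`) from heterozygous parents to affected probands,
#' and refers `(b - c)^2 / (b + c)` to a chi-square with 1 df (no continuity
#' correction). The log odds `beta = ln(b/c)` with `se = sqrt(1/b + 1/c)` is
#' reported for the minor allele (minor defined within the cohort). On the X
#' chromosome fathers are hemizygous and never informative; only heterozygous
#' mothers contribute, with sons receiving the maternal allele only and
#' daughters the paternal allele plus the maternal transmission.
#'
#' One proband per family is used (the first-listed affected child).
#' Mendelian-inconsistent trio genotypes are excluded per SNP. SNPs with
#' `b + c = 0` are flagged untestable (`p` is `NA`).
#'
#' @param trios a trio [genotype_table()].
#' @param snps optional subset of SNP ids or indices.
#' @return A data.frame with columns `snp, test, beta, se, p, b, c, n_eff,
#'   freq` (minor-allele frequency).
#' @export
tdt_scan <- function(trios, snps = NULL) {
  if (!is.null(snps)) trios <- subset_genotypes(trios, snps = snps)
  ti <- trio_indices(trios)
  keep1 <- !duplicated(ti$family)  # one proband per family
  F_ <- trios$dosages[ti$father[keep1], , drop = FALSE]
  M_ <- trios$dosages[ti$mother[keep1], , drop = FALSE]
  C_ <- trios$dosages[ti$child[keep1], , drop = FALSE]
  sex <- trios$meta$sex[ti$child[keep1]]
  on_x <- trios$snp_info$chrom == "X"

  n_het <- (F_ == 1L) + (M_ == 1L)
  forced <- (F_ == 2L) + (M_ == 2L)
  th <- C_ - forced
  valid <- !is.na(th) & !is.na(n_het) & th >= 0L & th <= n_het
  if (any(on_x)) {
    n_het[, on_x] <- matrix((M_[, on_x] == 1L), nrow(M_))
    girls <- sex == "female"
    x_forced <- (M_[, on_x, drop = FALSE] == 2L) +
      F_[, on_x, drop = FALSE] * girls
    thx <- C_[, on_x, drop = FALSE] - x_forced
    okx <- !is.na(thx) & thx >= 0L & thx <= n_het[, on_x, drop = FALSE]
    okx <- okx & (is.na(F_[, on_x, drop = FALSE]) |
                    F_[, on_x, drop = FALSE] <= 1L)
    okx[is.na(okx)] <- FALSE
    th[, on_x] <- thx
    valid[, on_x] <- okx
  }
  th[!valid] <- 0L
  n_het[!valid] <- 0L
  b1 <- colSums(th)            # transmissions of allele a1
  c1 <- colSums(n_het) - b1

  f <- a1_frequency(trios)
  flip <- !is.na(f) & f > 0.5
  b <- ifelse(flip, c1, b1)
  cc <- ifelse(flip, b1, c1)
  tot <- b + cc
  stat <- ifelse(tot > 0, (b - cc)^2 / tot, NA_real_)
  p <- ifelse(tot > 0, stats::pchisq(stat, 1, lower.tail = FALSE), NA_real_)
  beta <- ifelse(b > 0 & cc > 0, log(b / cc), NA_real_)
  se <- ifelse(b > 0 & cc > 0, sqrt(1 / b + 1 / cc), NA_real_)
  data.frame(
    snp = trios$snp_info$id, test = "TDT",
    beta = beta, se = se, p = p, b = b, c = cc, n_eff = tot,
    freq = pmin(f, 1 - f), stringsAsFactors = FALSE
  )
}

#' @rdname tdt_scan
#' @param snp a single SNP id or index.
#' @return `tdt()` returns the single association record (one-row data.frame).
#' @export
tdt <- function(trios, snp) {
  tdt_scan(trios, snps = snp)
}

#' X-chromosome dosage coding
#'
#' Returns the analysis dosage vector for an X-linked SNP: males coded 0/1 by
#' their single allele, females 0/1/2. A male dosage of 2 is a hard error.
#'
#' @param g a [genotype_table()].
#' @param snp SNP id or index.
#' @return Integer dosage vector, one entry per individual.
#' @export
encode_x <- function(g, snp) {
  j <- if (is.character(snp)) match(snp, g$snp_info$id) else snp
  if (is.na(j)) stop("unknown SNP: ", snp)
  if (g$snp_info$chrom[j] != "X") stop("encode_x: SNP not on the X chromosome")
  dose <- g$dosages[, j]
  male <- g$meta$sex == "male"
  bad <- male & !is.na(dose) & dose > 1L
  if (any(bad)) {
    stop("male X dosage of 2 for individual(s): ",
         paste(g$meta$id[bad], collapse = ", "))
  }
  dose
}

# Logistic fit via stats::glm.fit (IRLS); returns beta, se, p for column 2
# of the design (the dosage), plus convergence/separation flags.
logistic_fit <- function(y, x, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, dose = x)
  if (!is.null(covariates)) X <- cbind(X, covariates)
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 50))
  )
  beta <- fit$coefficients["dose"]
  separated <- !is.na(beta) && abs(beta) > 20
  converged <- isTRUE(fit$converged) && !separated
  se <- p <- NA_real_
  if (!is.na(beta)) {
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    cov <- try(chol2inv(chol(XtWX)), silent = TRUE)
    if (!inherits(cov, "try-error")) {
      se <- sqrt(cov[2, 2])
      p <- 2 * stats::pnorm(-abs(beta / se))
    }
  }
  list(beta = unname(beta), se = se, p = p, n = length(y),
       converged = converged, separated = separated)
}

#' Case-control logistic association
#'
#' Fits `affection ~ dosage + covariates` by maximum likelihood (IRLS) per
#' SNP and reports the Wald log-odds per minor-allele copy. X-linked SNPs use
#' the hemizygous male coding; when both sexes are present at an X SNP, sex
#' is added as a covariate. Non-converged or separated fits are flagged
#' (`converged = FALSE`) so downstream meta-analysis can drop them.
#'
#' @param g a [genotype_table()] with affection 1/2.
#' @param snps optional subset of SNP ids or indices.
#' @param covariates optional numeric matrix (e.g. [pca_covariates()]).
#' @return A data.frame with columns `snp, test, beta, se, p, n_eff, freq,
#'   converged`.
#' @export
logistic_scan <- function(g, snps = NULL, covariates = NULL) {
  if (!is.null(snps)) {
    if (!is.null(covariates)) covariates <- as.matrix(covariates)
    g <- subset_genotypes(g, snps = snps)
  }
  y <- g$meta$affection - 1L
  if (length(unique(stats::na.omit(y))) < 2) {
    stop("phenotype must contain both cases and controls")
  }
  f <- a1_frequency(g)
  flip <- !is.na(f) & f > 0.5
  on_x <- g$snp_info$chrom == "X"
  mixed_sex <- length(unique(g$meta$sex)) > 1
  sex_cov <- as.numeric(g$meta$sex == "male")
  m <- ncol(g$dosages)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    cov_j <- covariates
    if (on_x[j] && mixed_sex) cov_j <- cbind(cov_j, sex = sex_cov)
    fit <- logistic_fit(y, g$dosages[, j], cov_j)
    out[[j]] <- data.frame(
      snp = g$snp_info$id[j], test = "logistic",
      beta = if (flip[j]) -fit$beta else fit$beta,
      se = fit$se, p = fit$p, n_eff = fit$n,
      freq = min(f[j], 1 - f[j]), converged = fit$converged,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname logistic_scan
#' @param snp a single SNP id or index.
#' @export
logistic_assoc <- function(g, snp, covariates = NULL) {
  logistic_scan(g, snps = snp, covariates = covariates)
}

#' Principal-component covariates from autosomal genotypes
#'
#' Top-k eigenvectors of the individual-by-individual covariance of
#' standardised autosomal genotypes (missing dosages mean-imputed), the
#' standard population-stratification covariates. Vectors are unit-norm with
#' the sign fixed so each vector's largest-magnitude entry is positive.
#'
#' @param g a [genotype_table()].
#' @param k number of components (default 10).
#' @return An n-by-k matrix; fewer columns (with a warning) if the rank is
#'   below `k`.
#' @export
pca_covariates <- function(g, k = 10) {
  auto <- g$snp_info$chrom != "X"
  d <- g$dosages[, auto, drop = FALSE]
  p <- a1_frequency(subset_genotypes(g, snps = auto))
  W <- sweep(d, 2, 2 * p)
  W[is.na(W)] <- 0
  sd_j <- sqrt(2 * p * (1 - p))
  keep <- sd_j > 0
  W <- sweep(W[, keep, drop = FALSE], 2, sd_j[keep], "/")
  K <- tcrossprod(W) / ncol(W)
  eig <- eigen(K, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-8
  r <- sum(pos)
  if (r < k) {
    warning(sprintf("rank %d below requested k = %d; returning %d components",
                    r, k, r))
    k <- r
  }
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  rownames(V) <- g$meta$id
  V
}
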