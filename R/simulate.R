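#' @keywords internal
# Binomial dosage draws for a block of individuals; males hemizygous on X.
draw_dosages <- function(n, snp_info, sex) {
  m <- nrow(snp_info)
  if (n == 0 || m == 0) {
    return(matrix(integer(0), n, m))
  }
  p <- snp_info$freq
  if (any(!is.finite(p))) stop("non-finite allele frequency in SNP panel")
  d <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  on_x <- snp_info$chrom == "X"
  males <- which(sex == "male")
  if (any(on_x) && length(males)) {
    px <- p[on_x]
    d[males, on_x] <- matrix(
      stats::rbinom(length(males) * sum(on_x), 1L, rep(px, each = length(males))),
      length(males), sum(on_x)
    )
  }
  storage.mode(d) <- "integer"
  d
}

# One transmitted-allele draw per entry of a parental dosage matrix/vector
# (autosomal or maternal-X): heterozygotes transmit either allele at 1/2.
transmit <- function(parent_dose) {
  t <- stats::rbinom(length(parent_dose), 1L, as.vector(parent_dose) / 2)
  if (is.matrix(parent_dose)) t <- matrix(t, nrow(parent_dose))
  t
}

# Mendelian child dosages given parental matrices and child sex; X-aware.
mendelian_child <- function(f_dose, m_dose, snp_info, child_sex) {
  on_x <- snp_info$chrom == "X"
  tf <- transmit(f_dose)
  tm <- transmit(m_dose)
  child <- tf + tm
  if (any(on_x)) {
    boys <- child_sex == "male"
    # sons inherit Y from the father: only the maternal X allele counts
    child[boys, on_x] <- tm[boys, on_x]
    # daughters inherit the father's single X allele as-is
    girls <- !boys
    child[girls, on_x] <- f_dose[girls, on_x, drop = FALSE] + tm[girls, on_x]
  }
  storage.mode(child) <- "integer"
  child
}

batch_labels <- function(n, n_batches) {
  rep_len(sprintf("batch%d", seq_len(n_batches)), n)
}

#' Simulate an unascertained population cohort
#'
#' Draws dosages binomially per SNP at its panel frequency (Hardy-Weinberg,
#' no LD), with males hemizygous on the X. The result is the substrate for
#' case-control ascertainment and for heritability/score analyses with
#' externally supplied phenotypes.
#'
#' @param spec an [architecture_spec()].
#' @param n_individuals number of individuals.
#' @param sex_ratio fraction of the cohort that is female.
#' @param n_batches number of technical-batch labels, assigned round-robin.
#' @param id_prefix prefix for individual ids.
#' @return A [genotype_table()] with role "control" and unknown affection.
#' @export
simulate_population <- function(spec, n_individuals, sex_ratio = 0.5,
                                n_batches = 2, id_prefix = "pop") {
  stopifnot(inherits(spec, "architecture_spec"), n_individuals > 0,
            sex_ratio >= 0, sex_ratio <= 1)
  n_f <- round(n_individuals * sex_ratio)
  sex <- rep(c("female", "male"), c(n_f, n_individuals - n_f))
  d <- with_substream(spec$seed, paste0("population/", id_prefix),
                      draw_dosages(n_individuals, spec$snp_info, sex))
  meta <- new_meta(
    id = sprintf("%s%06d", id_prefix, seq_len(n_individuals)),
    sex = sex, role = "control",
    batch = batch_labels(n_individuals, n_batches),
    design = "case-control", affection = NA_integer_
  )
  genotype_table(spec$snp_info, d, meta)
}

# Rejection-sample causal-SNP dosages for individuals of one sex with the
# requested affection status. Returns a list(causal = matrix, draws = count).
sample_ascertained <- function(spec, sex, affected, n_target, budget_draws) {
  scale <- causal_scale(spec, sex)
  thr <- if (sex == "male") spec$threshold_male else spec$threshold_female
  cz_info <- if (is.null(spec$causal)) spec$snp_info[0, ] else
    spec$snp_info[spec$causal$snp, ]
  acc <- matrix(integer(0), 0, nrow(cz_info))
  draws <- 0
  while (nrow(acc) < n_target) {
    prev <- 1 - stats::pnorm(thr)
    p_hit <- if (affected) prev else 1 - prev
    chunk <- max(1000L, ceiling(2 * (n_target - nrow(acc)) / max(p_hit, 1e-6)))
    chunk <- min(chunk, max(1L, budget_draws - draws))
    if (chunk <= 0) break
    cz <- draw_dosages(chunk, cz_info, rep(sex, chunk))
    g <- causal_score(cz, scale)
    liab <- g + stats::rnorm(chunk, sd = liability_resid_sd(spec, scale))
    keep <- if (affected) liab > thr else liab <= thr
    acc <- rbind(acc, cz[keep, , drop = FALSE])
    draws <- draws + chunk
    if (draws >= budget_draws && nrow(acc) < n_target) {
      stop(sprintf(
        "ascertainment budget exhausted for %s %s (threshold %.3f): %d of %d after %d draws",
        if (affected) "affected" else "unaffected", sex, thr,
        nrow(acc), n_target, draws
      ))
    }
  }
  list(causal = acc[seq_len(n_target), , drop = FALSE], draws = draws)
}

# Fill the full panel for individuals whose causal dosages are fixed.
fill_full_dosages <- function(spec, causal_dosages, sex) {
  n <- length(sex)
  d <- draw_dosages(n, spec$snp_info, sex)
  if (!is.null(spec$causal) && nrow(spec$causal)) {
    d[, spec$causal$snp] <- causal_dosages
  }
  d
}

#' Simulate an ascertained case-control cohort
#'
#' Cases are sampled from individuals whose liability exceeds their sex's
#' threshold, controls from those below it, by rejection sampling.
#'
#' @param spec an [architecture_spec()].
#' @param n_cases,n_controls counts.
#' @param case_sex_ratio,control_sex_ratio fraction female in each group.
#' @param n_batches technical batches, round-robin.
#' @param budget rejection-sampling budget, in draws per requested individual.
#' @param id_prefix prefix for individual ids.
#' @return A [genotype_table()] with roles case/control and affection 2/1.
#' @export
simulate_case_control <- function(spec, n_cases, n_controls,
                                  case_sex_ratio = 0.16,
                                  control_sex_ratio = 0.37,
                                  n_batches = 2, budget = 2000,
                                  id_prefix = "cc") {
  stopifnot(inherits(spec, "architecture_spec"), n_cases >= 0, n_controls >= 0)
  cells <- list(
    list(sex = "female", aff = TRUE,  n = round(n_cases * case_sex_ratio)),
    list(sex = "male",   aff = TRUE,  n = n_cases - round(n_cases * case_sex_ratio)),
    list(sex = "female", aff = FALSE, n = round(n_controls * control_sex_ratio)),
    list(sex = "male",   aff = FALSE, n = n_controls - round(n_controls * control_sex_ratio))
  )
  with_substream(spec$seed, paste0("case_control/", id_prefix), {
    parts <- lapply(cells, function(cell) {
      if (cell$n == 0) return(NULL)
      s <- sample_ascertained(spec, cell$sex, cell$aff, cell$n,
                              budget_draws = budget * max(cell$n, 1))
      d <- fill_full_dosages(spec, s$causal, rep(cell$sex, cell$n))
      list(d = d, sex = rep(cell$sex, cell$n), aff = cell$aff)
    })
    parts <- Filter(Negate(is.null), parts)
    d <- do.call(rbind, lapply(parts, `[[`, "d"))
    sex <- unlist(lapply(parts, `[[`, "sex"))
    aff <- unlist(lapply(parts, function(p) rep(p$aff, length(p$sex))))
    n <- nrow(d)
    meta <- new_meta(
      id = sprintf("%s%06d", id_prefix, seq_len(n)),
      sex = sex, role = ifelse(aff, "case", "control"),
      batch = batch_labels(n, n_batches),
      design = "case-control", affection = ifelse(aff, 2L, 1L)
    )
    genotype_table(spec$snp_info, d, meta)
  })
}

#' Simulate ascertained trio families
#'
#' Parents are drawn from the population; the child's genotype follows
#' Mendelian transmission (X-aware); the trio is retained only if the child's
#' liability (polygenic value plus Gaussian residual) exceeds its sex's
#' threshold. Child sexes are fixed before ascertainment so the requested
#' proband sex mix is exact. A higher female threshold therefore yields female
#' probands with a larger mean polygenic load, and over-transmission of risk
#' alleles from heterozygous parents at causal SNPs.
#'
#' @param spec an [architecture_spec()].
#' @param n_trios number of affected-child trios.
#' @param proband_sex_fraction_female fraction of probands that are female
#'   (default 0.16, a male-biased cohort typical of autism family studies).
#' @param n_batches technical batches, assigned per trio round-robin.
#' @param budget rejection-sampling budget, candidate children per requested
#'   trio.
#' @param id_prefix prefix for family ids.
#' @return A [genotype_table()] with rows grouped father, mother, proband per
#'   family; probands have affection 2, parents 1.
#' @export
simulate_trios <- function(spec, n_trios, proband_sex_fraction_female = 0.16,
                           n_batches = 2, budget = 500, id_prefix = "fam") {
  stopifnot(inherits(spec, "architecture_spec"), n_trios > 0,
            proband_sex_fraction_female >= 0, proband_sex_fraction_female <= 1)
  n_f <- round(n_trios * proband_sex_fraction_female)
  targets <- c(female = n_f, male = n_trios - n_f)
  cz_info <- if (is.null(spec$causal)) spec$snp_info[0, ] else
    spec$snp_info[spec$causal$snp, ]
  ncz <- nrow(cz_info)
  on_x <- cz_info$chrom == "X"

  with_substream(spec$seed, paste0("trios/", id_prefix), {
    acc <- list()
    for (child_sex in c("female", "male")) {
      n_target <- targets[[child_sex]]
      if (n_target == 0) {
        acc[[child_sex]] <- NULL
        next
      }
      scale <- causal_scale(spec, child_sex)
      thr <- if (child_sex == "male") spec$threshold_male else spec$threshold_female
      prev <- 1 - stats::pnorm(thr)
      F_acc <- M_acc <- C_acc <- matrix(integer(0), 0, ncz)
      draws <- 0
      budget_draws <- budget * n_target
      while (nrow(C_acc) < n_target) {
        chunk <- max(1000L, ceiling(2 * (n_target - nrow(C_acc)) / max(prev, 1e-6)))
        chunk <- min(chunk, max(1L, budget_draws - draws))
        f <- draw_dosages(chunk, cz_info, rep("male", chunk))
        m <- draw_dosages(chunk, cz_info, rep("female", chunk))
        child <- mendelian_child(f, m, cz_info, rep(child_sex, chunk))
        g <- causal_score(child, scale)
        liab <- g + stats::rnorm(chunk, sd = liability_resid_sd(spec, scale))
        keep <- liab > thr
        F_acc <- rbind(F_acc, f[keep, , drop = FALSE])
        M_acc <- rbind(M_acc, m[keep, , drop = FALSE])
        C_acc <- rbind(C_acc, child[keep, , drop = FALSE])
        draws <- draws + chunk
        if (draws >= budget_draws && nrow(C_acc) < n_target) {
          stop(sprintf(
            "trio ascertainment budget exhausted for %s probands (threshold %.3f): %d of %d after %d candidate children",
            child_sex, thr, nrow(C_acc), n_target, draws
          ))
        }
      }
      acc[[child_sex]] <- list(
        f = F_acc[seq_len(n_target), , drop = FALSE],
        m = M_acc[seq_len(n_target), , drop = FALSE],
        c = C_acc[seq_len(n_target), , drop = FALSE]
      )
    }

    child_sex <- rep(c("female", "male"), targets)
    f_cz <- do.call(rbind, lapply(acc, `[[`, "f"))
    m_cz <- do.call(rbind, lapply(acc, `[[`, "m"))
    c_cz <- do.call(rbind, lapply(acc, `[[`, "c"))

    # fill the non-causal panel, then pin the ascertained causal columns
    f_full <- draw_dosages(n_trios, spec$snp_info, rep("male", n_trios))
    m_full <- draw_dosages(n_trios, spec$snp_info, rep("female", n_trios))
    c_full <- mendelian_child(f_full, m_full, spec$snp_info, child_sex)
    if (ncz > 0) {
      f_full[, spec$causal$snp] <- f_cz
      m_full[, spec$causal$snp] <- m_cz
      c_full[, spec$causal$snp] <- c_cz
    }

    fam <- sprintf("%s%05d", id_prefix, seq_len(n_trios))
    batch <- batch_labels(n_trios, n_batches)
    ord <- as.vector(rbind(seq_len(n_trios),
                           n_trios + seq_len(n_trios),
                           2 * n_trios + seq_len(n_trios)))
    d <- rbind(f_full, m_full, c_full)[ord, , drop = FALSE]
    meta <- new_meta(
      id = c(rbind(paste0(fam, "_f"), paste0(fam, "_m"), paste0(fam, "_c"))),
      sex = c(rbind(rep("male", n_trios), rep("female", n_trios), child_sex)),
      role = c(rbind(rep("father", n_trios), rep("mother", n_trios),
                     rep("proband", n_trios))),
      batch = rep(batch, each = 3),
      design = "trio",
      affection = c(rbind(rep(1L, n_trios), rep(1L, n_trios), rep(2L, n_trios))),
      family = rep(fam, each = 3)
    )
    genotype_table(spec$snp_info, d, meta)
  })
}

# Split a trio table into aligned father/mother/child index triplets.
trio_indices <- function(g) {
  meta <- g$meta
  kids <- which(meta$role == "proband")
  fams <- meta$family[kids]
  fa <- match(paste0(fams, ":father"), paste0(meta$family, ":", meta$role))
  mo <- match(paste0(fams, ":mother"), paste0(meta$family, ":", meta$role))
  if (anyNA(fa) || anyNA(mo)) stop("incomplete trios: missing parent rows")
  list(father = fa, mother = mo, child = kids, family = fams)
}

#' Construct pseudo-controls from trios
#'
#' For each proband, a pseudo-control genotype is formed from the parental
#' alleles NOT transmitted to the proband; pseudo-controls are perfectly
#' ancestry-matched controls. On the autosomes proband + pseudo-control
#' dosages sum to father + mother at every SNP. On the X, a male
#' pseudo-control carries the untransmitted maternal allele and a female
#' pseudo-control the paternal allele plus the untransmitted maternal allele.
#' Mendelian-inconsistent (or missing) trio genotypes yield `NA` at that SNP
#' and are counted in a message.
#'
#' @param trios a trio [genotype_table()].
#' @return A [genotype_table()] of pseudo-controls (one per proband, same sex
#'   and family, role "pseudo-control", affection 1).
#' @export
make_pseudo_controls <- function(trios) {
  ti <- trio_indices(trios)
  d <- trios$dosages
  F_ <- d[ti$father, , drop = FALSE]
  M_ <- d[ti$mother, , drop = FALSE]
  C_ <- d[ti$child, , drop = FALSE]
  sex <- trios$meta$sex[ti$child]
  on_x <- trios$snp_info$chrom == "X"

  lo <- function(x) (x == 2L) * 1L
  hi <- function(x) pmin(x, 1L)
  P <- F_ + M_ - C_
  ok <- C_ >= (lo(F_) + lo(M_)) & C_ <= (hi(F_) + hi(M_))
  if (any(on_x)) {
    boys <- sex == "male"
    if (any(boys)) {
      Mb <- M_[boys, on_x, drop = FALSE]
      Cb <- C_[boys, on_x, drop = FALSE]
      P[boys, on_x] <- Mb - Cb
      ok[boys, on_x] <- Cb >= lo(Mb) & Cb <= hi(Mb)
    }
    girls <- !boys
    if (any(girls)) {
      Fg <- F_[girls, on_x, drop = FALSE]
      Mg <- M_[girls, on_x, drop = FALSE]
      Cg <- C_[girls, on_x, drop = FALSE]
      tm <- Cg - Fg
      P[girls, on_x] <- Fg + Mg - tm
      ok[girls, on_x] <- tm >= lo(Mg) & tm <= hi(Mg) & Fg <= 1L
    }
  }
  ok[is.na(ok)] <- FALSE
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    message(sprintf(
      "make_pseudo_controls: %d Mendelian-inconsistent or missing trio genotype(s) set to NA",
      n_bad
    ))
    P[!ok] <- NA_integer_
  }
  storage.mode(P) <- "integer"
  meta <- new_meta(
    id = paste0(ti$family, "_pc"),
    sex = sex, role = "pseudo-control",
    batch = trios$meta$batch[ti$child], design = "trio",
    affection = 1L, family = ti$family
  )
  genotype_table(trios$snp_info, P, meta)
}

#' Proband / pseudo-control cohort for genetic-load analyses
#'
#' Binds probands (affection 2) with their pseudo-controls (affection 1),
#' the case/control contrast used for heritability and risk scoring.
#'
#' @param trios a trio [genotype_table()].
#' @return A [genotype_table()].
#' @export
case_pseudo_control_cohort <- function(trios) {
  pseudo <- make_pseudo_controls(trios)
  probands <- subset_genotypes(trios, trios$meta$role == "proband")
  bind_genotype_tables(probands, pseudo)
}
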