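#' Trio-design TDT configuration distribution
#'
#' Exact enumeration of the 27 (father, mother, child) genotype
#' configurations under Hardy-Weinberg parental frequencies and a
#' multiplicative genotype relative risk `grr` per risk allele, conditioned
#' on an affected child (disease prevalence cancels in the conditional
#' distribution). For every configuration the informative-transmission
#' contributions are determined: transmissions from heterozygous parents are
#' the child's allele count minus the forced transmissions from homozygous
#' parents.
#'
#' @param grr genotype relative risk per risk-allele copy (> 0).
#' @param maf risk-allele frequency.
#' @return A data.frame `gf, gm, gc, prob, b, c` with `prob` summing to 1.
#' @keywords internal
tdt_config_table <- function(grr, maf) {
  stopifnot(grr > 0, maf > 0, maf < 1)
  p <- maf
  hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  trans <- function(g, a) {
    # P(transmit a copies of the risk allele | parent dosage g)
    c(`0` = c(1, 0.5, 0)[g + 1], `1` = c(0, 0.5, 1)[g + 1])[as.character(a)]
  }
  grid <- expand.grid(gf = 0:2, gm = 0:2, tf = 0:1, tm = 0:1)
  grid$gc <- grid$tf + grid$tm
  w <- hw[grid$gf + 1] * hw[grid$gm + 1] *
    mapply(trans, grid$gf, grid$tf) * mapply(trans, grid$gm, grid$tm) *
    grr^grid$gc
  cfg <- stats::aggregate(w, by = grid[, c("gf", "gm", "gc")], FUN = sum)
  names(cfg)[4] <- "prob"
  cfg <- cfg[cfg$prob > 0, ]
  cfg$prob <- cfg$prob / sum(cfg$prob)
  n_het <- (cfg$gf == 1) + (cfg$gm == 1)
  forced <- (cfg$gf == 2) + (cfg$gm == 2)
  cfg$b <- cfg$gc - forced
  cfg$c <- n_het - cfg$b
  cfg
}

#' Power of the transmission disequilibrium test
#'
#' Under a multiplicative genotype relative risk model, `analytic` mode
#' computes the expected informative transmissions per affected trio by exact
#' enumeration of the parental mating types conditioned on an affected child,
#' and refers the TDT statistic to a non-central chi-square with 1 df
#' (non-centrality `n (E[b] - E[c])^2 / E[b + c]`) beyond the two-sided
#' alpha critical value. `simulation` mode draws `n_sims` replicate trio
#' datasets from the same conditional configuration distribution, computes
#' the TDT statistic for each, and reports the rejection fraction.
#'
#' @param n_trios number of affected trios.
#' @param grr genotype relative risk per risk-allele copy.
#' @param maf risk-allele frequency.
#' @param alpha two-sided significance threshold (default 5e-8,
#'   genome-wide).
#' @param method "analytic" or "simulation".
#' @param n_sims simulation replicates.
#' @param seed seed for simulation mode.
#' @return Power in [0, 1].
#' @export
tdt_power <- function(n_trios, grr, maf, alpha = 5e-8,
                      method = c("analytic", "simulation"),
                      n_sims = 1e5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(n_trios > 0, alpha > 0, alpha < 1)
  cfg <- tdt_config_table(grr, maf)
  if (method == "analytic") {
    Eb <- sum(cfg$prob * cfg$b)
    Ec <- sum(cfg$prob * cfg$c)
    if (Eb + Ec == 0) return(alpha)
    ncp <- n_trios * (Eb - Ec)^2 / (Eb + Ec)
    crit <- stats::qchisq(1 - alpha, df = 1)
    stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
  } else {
    if (alpha * n_sims < 1) {
      warning(sprintf(
        "alpha = %g below the resolution of %g simulations; estimate will be coarse",
        alpha, n_sims
      ))
    }
    with_substream(seed, "tdt_power_sim", {
      counts <- stats::rmultinom(n_sims, n_trios, cfg$prob)
      b <- colSums(counts * cfg$b)
      cc <- colSums(counts * cfg$c)
      tot <- b + cc
      stat <- ifelse(tot > 0, (b - cc)^2 / tot, 0)
      mean(stats::pchisq(stat, 1, lower.tail = FALSE) <= alpha)
    })
  }
}

#' Power of a two-sided two-sample t-test
#'
#' Standard non-central-t power for detecting a standardised mean difference
#' `d` with `n` individuals per group.
#'
#' @param n per-group sample size (>= 2).
#' @param d standardised mean difference (Cohen's d).
#' @param alpha two-sided significance level (default 0.05).
#' @return Power in [0, 1].
#' @export
ttest_power <- function(n, d, alpha = 0.05) {
  stopifnot(n >= 2, d >= 0, alpha > 0, alpha < 1)
  if (d == 0) return(alpha)
  stats::power.t.test(n = n, delta = d, sd = 1, sig.level = alpha,
                      type = "two.sample", alternative = "two.sided")$power
}

#' Power-query interface
#'
#' A thin record/dispatcher over [tdt_power()] and [ttest_power()].
#'
#' @param design "tdt" or "ttest".
#' @param n trios (tdt) or per-group size (ttest).
#' @param effect genotype relative risk (tdt) or standardised difference
#'   (ttest).
#' @param maf risk-allele frequency (tdt only).
#' @param alpha significance level.
#' @param method "analytic" or "simulation" (tdt only).
#' @param n_sims,seed simulation controls.
#' @return `power_query()` returns the query; `compute_power()` the power.
#' @export
power_query <- function(design = c("tdt", "ttest"), n, effect, maf = NULL,
                        alpha = if (design[1] == "tdt") 5e-8 else 0.05,
                        method = "analytic", n_sims = 1e5, seed = 1L) {
  design <- match.arg(design)
  stopifnot(alpha > 0, alpha < 1, effect > 0 || design == "ttest")
  structure(list(design = design, n = n, effect = effect, maf = maf,
                 alpha = alpha, method = method, n_sims = n_sims,
                 seed = seed),
            class = "power_query")
}

#' @rdname power_query
#' @param q a `power_query`.
#' @export
compute_power <- function(q) {
  stopifnot(inherits(q, "power_query"))
  if (q$design == "tdt") {
    tdt_power(q$n, q$effect, q$maf, q$alpha, method = q$method,
              n_sims = q$n_sims, seed = q$seed)
  } else {
    ttest_power(q$n, q$effect, q$alpha)
  }
}
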