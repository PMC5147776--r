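#!/usr/bin/env Rscript
# Sex-stratified association analysis: TDT on trios, PC-adjusted logistic
# regression on the case-control cohort, fixed-effects meta-analysis within
# and across sexes, male-female Cochran's Q, and FDR q-values. Writes the
# per-SNP tables the permutation and gene-set scripts reuse.

suppressPackageStartupMessages(library(ssgwas))
cfg <- read_run_config("results/data/run_config.yaml")

trios <- read_genotypes("results/data/trios")
cc <- read_genotypes("results/data/cc")
trios <- apply_common_filters(trios, cfg$maf_floor, cfg$call_rate_floor)
cc <- apply_common_filters(cc, cfg$maf_floor, cfg$call_rate_floor)
shared <- intersect(trios$snp_info$id, cc$snp_info$id)
trios <- subset_genotypes(trios, snps = shared)
cc <- subset_genotypes(cc, snps = shared)
g <- bind_genotype_tables(trios, cc)

pcs <- pca_covariates(cc, k = 10)
res <- sex_stratified_assoc(g, covariates = pcs)

for (s in c("male", "female")) {
  r <- res[[s]]
  r$q <- bh_qvalues(r$p)
  utils::write.table(r[order(r$p), ], sprintf("results/assoc_%s.tsv", s),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
comb <- res$combined
comb$q <- bh_qvalues(comb$p_meta)
utils::write.table(comb[order(comb$p_meta), ], "results/assoc_combined.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(res$het, "results/cochran_q.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

n_sig <- sum(comb$p_meta < cfg$alpha_gwas, na.rm = TRUE)
message(sprintf("combined-sex scan: %d SNPs at P < %g", n_sig, cfg$alpha_gwas))
for (s in c("male", "female")) {
  top <- res[[s]][order(res[[s]]$p), ][1:5, ]
  message(sprintf("top %s-specific SNPs:", s))
  print(top, row.names = FALSE)
}
q_sig <- res$het[!is.na(res$het$p_Q) & res$het$p_Q < 1e-3, ]
message(sprintf("%d SNPs with male-female heterogeneity P < 1e-3 (%d on X)",
                nrow(q_sig),
                sum(grepl("^snp", q_sig$snp) &
                      g$snp_info$chrom[match(q_sig$snp, g$snp_info$id)] == "X")))
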