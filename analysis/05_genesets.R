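#!/usr/bin/env Rscript
# Gene-set and pleiotropy analyses: +-5 kb gene windows, length-matched gene
# permutation, anthropometric-heterogeneous (AH) SNP selection with
# association-matched SNP permutation, and sex-correlated (SC) gene scoring
# from the expression panels.

suppressPackageStartupMessages(library(ssgwas))
cfg <- read_run_config("results/data/run_config.yaml")
n_perm <- 50L

comb <- read_assoc_tsv("results/assoc_combined.tsv")
names(comb)[names(comb) == "p_meta"] <- "p"
trios <- apply_common_filters(read_genotypes("results/data/trios"),
                              cfg$maf_floor, cfg$call_rate_floor)

# 1) gene-window sets with length-matched permutation
genes <- filter_gene_intervals(read_gene_bed("results/data/genes.bed"))
set.seed(cfg$seed + 30)
target <- sample(genes$gene, 40)
snp_df <- trios$snp_info
true_snps <- gene_set_snps(genes[genes$gene %in% target, ], snp_df,
                           flank = cfg$gene_flank)
null_genes <- length_matched_null_sets(target, genes, genes, n_perm = n_perm,
                                       seed = cfg$seed + 31)
null_snps <- lapply(null_genes, function(gs) {
  gene_set_snps(genes[genes$gene %in% gs, ], snp_df, flank = cfg$gene_flank)
})
en_genes <- set_enrichment(true_snps, null_snps, comb,
                           q_threshold = cfg$q_enrichment)
message(sprintf(
  "random gene set (%d genes, %d SNPs): enrichment %.3f vs null mean %.3f (P = %.2f)",
  length(target), length(true_snps), en_genes$observed_fraction,
  mean(en_genes$permuted_fractions), en_genes$empirical_p
))

# 2) AH SNPs: sex-heterogeneous anthropometric associations, with
#    association-matched null SNP sets (shared SNP namespace with the panel)
ss <- utils::read.table("results/data/anthro_sumstats.tsv", header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
ah <- ah_select(ss, p_cut = cfg$ah_p_cut)
message(sprintf("AH selection: %d SNPs at sex-difference P < %g",
                nrow(ah), cfg$ah_p_cut))
rec_map <- comb[seq_len(min(2000, nrow(comb))), ]
rec_map$snp <- sprintf("gsnp%06d", seq_len(nrow(rec_map)))
nulls <- matched_assoc_null_sets(ah, ss, n_perm = n_perm,
                                 seed = cfg$seed + 32)
en_ah <- set_enrichment(ah$snp, nulls, rec_map,
                        q_threshold = cfg$q_enrichment)
message(sprintf("AH set: enrichment %.3f vs matched-null mean %.3f (P = %.2f)",
                en_ah$observed_fraction, mean(en_ah$permuted_fractions),
                en_ah$empirical_p))

# 3) SC genes from the expression panels
panels <- list(panels = lapply(1:3, function(k) {
  expr <- utils::read.table(sprintf("results/data/expression_panel%d.tsv", k),
                            header = TRUE, sep = "\t", row.names = 1)
  samp <- utils::read.table(
    sprintf("results/data/expression_panel%d_samples.tsv", k),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE
  )
  list(expr = as.matrix(expr), sex = samp$sex, n = nrow(samp))
}))
class(panels) <- "expression_panels"
truth <- utils::read.table("results/data/expression_truth.tsv", header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
module <- truth$gene[truth$bias != 0]
pcs <- lapply(panels$panels, function(p) module_pc1(p$expr, module))
# orient each PC1 so "male-ness" is positive
pcs <- lapply(seq_along(pcs), function(k) {
  v <- pcs[[k]]
  if (stats::cor(v, as.numeric(panels$panels[[k]]$sex == "male")) < 0) -v else v
})
sc <- sc_gene_scores(panels, pcs, r_cut = 0.3)
utils::write.table(sc, "results/sc_gene_scores.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
tab <- table(sc$class)
message("SC classification: ",
        paste(sprintf("%s = %d", names(tab), tab), collapse = ", "))
recov <- mean(truth$gene[truth$bias > 0] %in%
                sc$gene[sc$class == "male-correlated"])
message(sprintf("male-biased genes recovered as male-correlated: %.0f%%",
                100 * recov))
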