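#!/usr/bin/env Rscript
# Build the synthetic study cohorts used by the downstream analysis scripts:
# a male-biased trio cohort and a case-control cohort ascertained under the
# sex-specific liability-threshold model, plus sex-stratified anthropometric
# summary statistics and fetal-brain-like expression panels. Scaled to run on
# a laptop; every later script reads from results/data/.

suppressPackageStartupMessages(library(ssgwas))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
cfg <- run_config(seed = 20260920L)
write_run_config(cfg, "results/data/run_config.yaml")

# Architecture: 2,000 autosomal + 150 X SNPs; 60 shared-effect autosomal
# causal SNPs and 15 male-limited X causal SNPs; liability h2 = 0.5;
# thresholds from the 1/42 (male) and 1/189 (female) prevalences.
causal <- rbind(
  data.frame(snp = seq(10, 600, by = 10), beta_male = 1, beta_female = 1),
  data.frame(snp = 2000 + seq(10, 150, by = 10), beta_male = 1,
             beta_female = 0)
)
spec <- architecture_spec(
  n_snps_by_chrom = c("1" = 700, "2" = 700, "7" = 300, "17" = 300, X = 150),
  causal = causal, h2_liability = 0.5, seed = cfg$seed
)
print(spec)

trios <- simulate_trios(spec, n_trios = 1600,
                        proband_sex_fraction_female = 0.16, n_batches = 3)
cc <- simulate_case_control(spec, n_cases = 450, n_controls = 400,
                            n_batches = 3)
print(trios)
print(cc)

write_plink_bed(trios, "results/data/trios")
write_plink_bed(cc, "results/data/cc")

ss <- simulate_anthro_sumstats(n_snps = 2000, frac_heterogeneous = 0.04,
                               seed = cfg$seed + 1)
utils::write.table(ss, "results/data/anthro_sumstats.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("anthro sumstats: %d SNP x trait rows, %.1f%% of SNPs truly heterogeneous",
                nrow(ss), 100 * length(unique(ss$snp[ss$true_het])) /
                  length(unique(ss$snp))))

panels <- simulate_expression_panels(n_genes = 400,
                                     n_samples_per_panel = c(60, 90, 120),
                                     sex_biased_gene_fraction = 0.15,
                                     seed = cfg$seed + 2)
for (k in seq_along(panels$panels)) {
  p <- panels$panels[[k]]
  utils::write.table(
    cbind(data.frame(gene = rownames(p$expr)), as.data.frame(p$expr)),
    sprintf("results/data/expression_panel%d.tsv", k),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(sample = colnames(p$expr), sex = p$sex),
    sprintf("results/data/expression_panel%d_samples.tsv", k),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
}
utils::write.table(panels$truth, "results/data/expression_truth.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# Gene intervals tiling the autosomes, for the window/permutation analyses
set.seed(cfg$seed + 3)
genes <- do.call(rbind, lapply(c("1", "2", "7", "17"), function(ch) {
  start <- sort(sample.int(2.3e8, 150))
  data.frame(gene = sprintf("gene_%s_%03d", ch, seq_along(start)),
             chrom = ch, start = start,
             end = start + sample(c(2e4, 1e5, 5e5), length(start), TRUE))
}))
genes$length <- genes$end - genes$start + 1L
write_gene_bed(genes, "results/data/genes.bed")
message(sprintf("wrote %d gene intervals", nrow(genes)))
message("cohorts written under results/data/")
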