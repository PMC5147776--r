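# Shared fixture builders: everything is generated in code at test time.

# A genotype table built directly from a dosage matrix (one batch, CC design).
toy_table <- function(dosages, sex = rep("male", nrow(dosages)),
                      chrom = rep("1", ncol(dosages)),
                      affection = rep(NA_integer_, nrow(dosages)),
                      role = rep("control", nrow(dosages))) {
  m <- ncol(dosages)
  snp_info <- data.frame(
    id = sprintf("s%03d", seq_len(m)), chrom = chrom,
    pos = seq_len(m) * 1000L, a1 = "A", a2 = "G",
    freq = NA_real_, stringsAsFactors = FALSE
  )
  meta <- data.frame(
    id = sprintf("i%03d", seq_len(nrow(dosages))), sex = sex, role = role,
    batch = "batch1", design = "case-control", affection = affection,
    family = NA_character_, stringsAsFactors = FALSE
  )
  storage.mode(dosages) <- "integer"
  genotype_table(snp_info, dosages, meta)
}

# A trio table from explicit father/mother/child dosage matrices
# (rows = trios), with chosen child sexes.
toy_trios <- function(f, m, c, child_sex = rep("male", nrow(f)),
                      chrom = rep("1", ncol(f))) {
  n <- nrow(f)
  ncol_ <- ncol(f)
  snp_info <- data.frame(
    id = sprintf("s%03d", seq_len(ncol_)), chrom = chrom,
    pos = seq_len(ncol_) * 1000L, a1 = "A", a2 = "G",
    freq = NA_real_, stringsAsFactors = FALSE
  )
  fam <- sprintf("fam%03d", seq_len(n))
  d <- rbind(f, m, c)[as.vector(rbind(seq_len(n), n + seq_len(n),
                                      2 * n + seq_len(n))), , drop = FALSE]
  storage.mode(d) <- "integer"
  meta <- data.frame(
    id = c(rbind(paste0(fam, "_f"), paste0(fam, "_m"), paste0(fam, "_c"))),
    sex = c(rbind(rep("male", n), rep("female", n), child_sex)),
    role = c(rbind(rep("father", n), rep("mother", n), rep("proband", n))),
    batch = "batch1", design = "trio",
    affection = c(rbind(rep(1L, n), rep(1L, n), rep(2L, n))),
    family = rep(fam, each = 3), stringsAsFactors = FALSE
  )
  genotype_table(snp_info, d, meta)
}
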