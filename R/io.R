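#' Cohort allele-1 frequency per SNP
#'
#' Frequency of allele `a1` within the cohort, counting male X chromosomes
#' once. Missing dosages are excluded from the denominator.
#'
#' @param g a [genotype_table()].
#' @return Numeric vector, one frequency per SNP.
#' @export
a1_frequency <- function(g) {
  d <- g$dosages
  on_x <- g$snp_info$chrom == "X"
  male <- g$meta$sex == "male"
  copies <- matrix(2, nrow(d), ncol(d))
  if (any(on_x) && any(male)) copies[male, on_x] <- 1
  copies[is.na(d)] <- 0
  cnt <- colSums(d, na.rm = TRUE)
  tot <- colSums(copies)
  ifelse(tot > 0, cnt / tot, NA_real_)
}

# ---- FAM / sidecar ---------------------------------------------------------

fam_frame <- function(g) {
  meta <- g$meta
  fam <- ifelse(is.na(meta$family), meta$id, meta$family)
  fa <- mo <- rep("0", nrow(meta))
  is_child <- meta$role %in% c("proband", "pseudo-control") & !is.na(meta$family)
  if (any(is_child)) {
    key <- paste0(meta$family, ":", meta$role)
    fa_idx <- match(paste0(meta$family[is_child], ":father"), key)
    mo_idx <- match(paste0(meta$family[is_child], ":mother"), key)
    fa[is_child] <- ifelse(is.na(fa_idx), "0", meta$id[fa_idx])
    mo[is_child] <- ifelse(is.na(mo_idx), "0", meta$id[mo_idx])
  }
  data.frame(
    family = fam, id = meta$id, father = fa, mother = mo,
    sex = ifelse(meta$sex == "male", 1L, 2L),
    phenotype = ifelse(is.na(meta$affection), -9L, meta$affection),
    stringsAsFactors = FALSE
  )
}

write_sidecar <- function(g, path) {
  utils::write.table(
    g$meta[, c("id", "sex", "role", "batch", "design", "family")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
}

read_sidecar_into <- function(meta, path) {
  if (!file.exists(path)) return(meta)
  sc <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "NA")
  i <- match(meta$id, sc$id)
  for (col in c("role", "batch", "design", "family")) {
    hit <- !is.na(i)
    meta[[col]][hit] <- sc[[col]][i[hit]]
  }
  meta
}

# ---- BED/BIM/FAM -----------------------------------------------------------

#' Write a genotype table as PLINK BED/BIM/FAM
#'
#' Standard SNP-major binary BED with the 6-column FAM (family, individual,
#' father, mother, sex 1=male/2=female, phenotype 1=control/2=case/-9), plus a
#' `<prefix>.sample_info.tsv` sidecar carrying batch/design/role metadata the
#' PLINK formats cannot hold. Male X dosages are written as the corresponding
#' homozygous code (the hemizygous convention).
#'
#' @param g a [genotype_table()].
#' @param prefix path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return `prefix`, invisibly.
#' @export
write_plink_bed <- function(g, prefix) {
  si <- g$snp_info
  utils::write.table(
    data.frame(si$chrom, si$id, 0, si$pos, si$a1, si$a2),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  utils::write.table(
    fam_frame(g), paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  write_sidecar(g, paste0(prefix, ".sample_info.tsv"))

  n <- nrow(g$dosages)
  # 2-bit codes by A1 count: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code_of <- c(`2` = 0L, `1` = 2L, `0` = 3L)
  male <- g$meta$sex == "male"
  on_x <- si$chrom == "X"
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  n_bytes <- ceiling(n / 4)
  pad <- n_bytes * 4 - n
  shift <- rep(c(1L, 4L, 16L, 64L), n_bytes)[seq_len(n)]
  byte_of <- rep(seq_len(n_bytes), each = 4)[seq_len(n)]
  for (j in seq_len(ncol(g$dosages))) {
    dose <- g$dosages[, j]
    if (on_x[j]) dose[male] <- dose[male] * 2L  # hemizygous as homozygous
    code <- code_of[as.character(dose)]
    code[is.na(dose)] <- 1L
    bytes <- vapply(split(code * shift, byte_of), sum, numeric(1))
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

read_bim <- function(path) {
  bim <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  data.frame(id = bim$id, chrom = as.character(bim$chrom), pos = bim$pos,
             a1 = bim$a1, a2 = bim$a2, freq = NA_real_,
             stringsAsFactors = FALSE)
}

read_fam_meta <- function(path) {
  fam <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           col.names = c("family", "id", "father", "mother",
                                         "sex", "phenotype"))
  bad_sex <- !fam$sex %in% c(1L, 2L)
  if (any(bad_sex)) {
    warning(sprintf("excluding %d individual(s) with unknown sex code",
                    sum(bad_sex)))
  }
  role <- ifelse(fam$phenotype == 2, "case", "control")
  meta <- new_meta(
    id = fam$id,
    sex = ifelse(fam$sex == 1L, "male", "female"),
    role = role, batch = "batch1", design = "case-control",
    affection = ifelse(fam$phenotype %in% c(1L, 2L), fam$phenotype,
                       NA_integer_)
  )
  list(meta = meta, keep = !bad_sex)
}

read_plink_bed <- function(prefix) {
  si <- read_bim(paste0(prefix, ".bim"))
  fm <- read_fam_meta(paste0(prefix, ".fam"))
  meta <- fm$meta
  n <- nrow(meta)
  m <- nrow(si)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = file.size(paste0(prefix, ".bed")))
  if (length(raw) < 3 || raw[1] != 0x6c || raw[2] != 0x1b || raw[3] != 0x01) {
    stop("not a SNP-major PLINK BED file (bad magic bytes): ",
         prefix, ".bed")
  }
  n_bytes <- ceiling(n / 4)
  if (length(raw) - 3 != n_bytes * m) {
    stop(sprintf(
      "BED payload (%d bytes) does not match FAM x BIM dimensions (%d x %d)",
      length(raw) - 3, n, m
    ))
  }
  body <- as.integer(raw[-(1:3)])
  codes <- matrix(0L, n_bytes * 4, m)
  for (k in 0:3) {
    codes[seq(k + 1, n_bytes * 4, by = 4), ] <- body %% 4
    body <- body %/% 4
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # codes: 0 -> 2 copies of A1, 2 -> 1, 3 -> 0, 1 -> NA
  dose <- matrix(NA_integer_, n, m)
  dose[codes == 0L] <- 2L
  dose[codes == 2L] <- 1L
  dose[codes == 3L] <- 0L
  male <- meta$sex == "male"
  on_x <- si$chrom == "X"
  if (any(on_x) && any(male)) {
    xm <- dose[male, on_x, drop = FALSE]
    het <- !is.na(xm) & xm == 1L
    if (any(het)) {
      warning(sprintf("%d heterozygous male X call(s) set to missing",
                      sum(het)))
      xm[het] <- NA_integer_
    }
    xm[!is.na(xm)] <- xm[!is.na(xm)] %/% 2L
    dose[male, on_x] <- xm
  }
  meta <- read_sidecar_into(meta, paste0(prefix, ".sample_info.tsv"))
  g <- genotype_table(si, dose, meta)
  if (!all(fm$keep)) g <- subset_genotypes(g, fm$keep)
  g
}

# ---- PED/MAP ---------------------------------------------------------------

#' Write a genotype table as PLINK PED/MAP
#'
#' @param g a [genotype_table()].
#' @param prefix path prefix; `.ped` and `.map` are appended, plus the
#'   `.sample_info.tsv` sidecar.
#' @return `prefix`, invisibly.
#' @export
write_plink_ped <- function(g, prefix) {
  si <- g$snp_info
  utils::write.table(
    data.frame(si$chrom, si$id, 0, si$pos),
    paste0(prefix, ".map"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  write_sidecar(g, paste0(prefix, ".sample_info.tsv"))
  fam <- fam_frame(g)
  male <- g$meta$sex == "male"
  on_x <- si$chrom == "X"
  lines <- vapply(seq_len(nrow(g$dosages)), function(i) {
    dose <- g$dosages[i, ]
    if (male[i] && any(on_x)) dose[on_x] <- dose[on_x] * 2L
    al1 <- ifelse(is.na(dose), "0", ifelse(dose >= 1, si$a1, si$a2))
    al2 <- ifelse(is.na(dose), "0", ifelse(dose == 2, si$a1, si$a2))
    paste(c(fam$family[i], fam$id[i], fam$father[i], fam$mother[i],
            fam$sex[i], fam$phenotype[i], rbind(al1, al2)), collapse = " ")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

read_plink_ped <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos"))
  lines <- readLines(paste0(prefix, ".ped"))
  toks <- strsplit(trimws(lines), "[ \t]+")
  m <- nrow(map)
  n <- length(toks)
  stopifnot(all(lengths(toks) == 6 + 2 * m))
  fam6 <- t(vapply(toks, function(x) x[1:6], character(6)))
  alle <- t(vapply(toks, function(x) x[-(1:6)], character(2 * m)))
  a1_col <- alle[, seq(1, 2 * m, by = 2), drop = FALSE]
  a2_col <- alle[, seq(2, 2 * m, by = 2), drop = FALSE]
  # allele labels per SNP: a1 = first non-missing allele seen, a2 = other
  si <- data.frame(id = map$id, chrom = as.character(map$chrom),
                   pos = map$pos, a1 = NA_character_, a2 = NA_character_,
                   freq = NA_real_, stringsAsFactors = FALSE)
  dose <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    obs <- c(a1_col[, j], a2_col[, j])
    alleles <- sort(unique(obs[obs != "0"]))
    if (length(alleles) > 2) stop("more than two alleles at ", map$id[j])
    if (length(alleles) == 0) alleles <- c("A", "G")
    if (length(alleles) == 1) alleles <- c(alleles, ".")
    si$a1[j] <- alleles[1]
    si$a2[j] <- alleles[2]
    miss <- a1_col[, j] == "0" | a2_col[, j] == "0"
    dose[, j] <- (a1_col[, j] == alleles[1]) + (a2_col[, j] == alleles[1])
    dose[miss, j] <- NA_integer_
  }
  sex_code <- as.integer(fam6[, 5])
  bad_sex <- !sex_code %in% c(1L, 2L)
  if (any(bad_sex)) {
    warning(sprintf("excluding %d individual(s) with unknown sex code",
                    sum(bad_sex)))
  }
  phen <- as.integer(fam6[, 6])
  meta <- new_meta(
    id = fam6[, 2],
    sex = ifelse(sex_code == 1L, "male", "female"),
    role = ifelse(phen == 2L, "case", "control"),
    batch = "batch1", design = "case-control",
    affection = ifelse(phen %in% c(1L, 2L), phen, NA_integer_)
  )
  meta$sex[bad_sex] <- "male"  # placeholder; rows dropped below
  male <- meta$sex == "male" & !bad_sex
  on_x <- si$chrom == "X"
  if (any(on_x) && any(male)) {
    xm <- dose[male, on_x, drop = FALSE]
    het <- !is.na(xm) & xm == 1L
    if (any(het)) {
      warning(sprintf("%d heterozygous male X call(s) set to missing",
                      sum(het)))
      xm[het] <- NA_integer_
    }
    xm[!is.na(xm)] <- xm[!is.na(xm)] %/% 2L
    dose[male, on_x] <- xm
  }
  meta <- read_sidecar_into(meta, paste0(prefix, ".sample_info.tsv"))
  g <- genotype_table(si, dose, meta)
  if (any(bad_sex)) g <- subset_genotypes(g, !bad_sex)
  g
}

#' Read genotypes from PLINK files
#'
#' Accepts a path prefix (or a path ending in `.bed`/`.ped`) and dispatches to
#' the binary or text reader. Dosages count copies of allele A1 as listed in
#' the BIM (for PED, of the first allele observed); sex is parsed from FAM
#' column 5; a `<prefix>.sample_info.tsv` sidecar, when present, restores
#' batch, design, role and family labels.
#'
#' @param path file-set prefix, or a `.bed`/`.ped` file path.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path) {
  prefix <- sub("\\.(bed|bim|fam|ped|map)$", "", path)
  if (file.exists(paste0(prefix, ".bed"))) {
    read_plink_bed(prefix)
  } else if (file.exists(paste0(prefix, ".ped"))) {
    read_plink_ped(prefix)
  } else {
    stop("no .bed or .ped file found for prefix: ", prefix)
  }
}

# ---- Filters ---------------------------------------------------------------

#' Common-variant and call-rate filters
#'
#' Removes SNPs with minor allele frequency below `maf_floor` (computed in the
#' cohort, X-aware) or per-SNP call rate below `call_rate_floor`.
#'
#' @param g a [genotype_table()].
#' @param maf_floor minimum minor-allele frequency (default 0.01, common
#'   variants only).
#' @param call_rate_floor minimum fraction of non-missing calls per SNP.
#' @return The filtered [genotype_table()].
#' @export
apply_common_filters <- function(g, maf_floor = 0.01, call_rate_floor = 0.9) {
  stopifnot(maf_floor >= 0, maf_floor <= 1,
            call_rate_floor >= 0, call_rate_floor <= 1)
  f <- a1_frequency(g)
  maf <- pmin(f, 1 - f)
  call_rate <- colMeans(!is.na(g$dosages))
  keep <- !is.na(maf) & maf >= maf_floor & call_rate >= call_rate_floor
  if (!any(keep)) stop("no SNPs survive the MAF/call-rate filters")
  if (any(!keep)) {
    message(sprintf(
      "apply_common_filters: removed %d of %d SNPs (MAF < %g or call rate < %g)",
      sum(!keep), length(keep), maf_floor, call_rate_floor
    ))
  }
  subset_genotypes(g, snps = keep)
}

# ---- Summary-statistic and config serialisation ----------------------------

#' Write / read association records as TSV
#'
#' @param records a data.frame of association or meta records.
#' @param path TSV path.
#' @return The path (write) or data.frame (read).
#' @export
write_assoc_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_assoc_tsv
#' @export
read_assoc_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Analysis run configuration
#'
#' Bundles the pipeline's thresholds with their standard defaults:
#' genome-wide significance 5e-8, FDR enrichment threshold q = 0.8, 100
#' permutations, MAF floor 0.01, 5 kb gene flanks, sex-difference cutoff 1e-3
#' for anthropometric-heterogeneous SNP selection, top-SNP heterogeneity FDR
#' levels (X: male 0.2 / female 0.01; autosomes: male 0.2 / female 0.001).
#'
#' @param ... overrides for any default field.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    alpha_gwas = 5e-8,
    q_enrichment = 0.8,
    n_perm = 100L,
    maf_floor = 0.01,
    call_rate_floor = 0.9,
    gene_flank = 5000L,
    ah_p_cut = 1e-3,
    fdr_top_x = c(male = 0.2, female = 0.01),
    fdr_top_auto = c(male = 0.2, female = 0.001),
    clump_r2_max = 0.2,
    clump_window_bp = 5e5,
    top_k_x = 20L,
    top_k_auto = 100L,
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  raw <- unclass(cfg)
  for (nm in c("fdr_top_x", "fdr_top_auto")) raw[[nm]] <- as.list(raw[[nm]])
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("fdr_top_x", "fdr_top_auto")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(run_config, raw)
}
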