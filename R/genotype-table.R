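#' Genotype table
#'
#' The package's central container: an individuals-by-SNPs dosage matrix with
#' per-SNP and per-individual metadata. Dosages count copies of allele `a1`
#' (0/1/2 on autosomes and on the female X, 0/1 on the male X; `NA` =
#' missing).
#'
#' @param snp_info data.frame with columns `id, chrom, pos, a1, a2, freq`.
#' @param dosages integer matrix, rows = individuals, columns = SNPs.
#' @param meta data.frame with columns `id, sex, role, batch, design,
#'   affection, family` (`sex` in male/female; `role` in proband, father,
#'   mother, case, control, pseudo-control; `affection` 1 = unaffected,
#'   2 = affected, NA = unknown; `family` NA outside trios).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(snp_info, dosages, meta) {
  stopifnot(
    is.matrix(dosages),
    nrow(meta) == nrow(dosages), nrow(snp_info) == ncol(dosages),
    all(c("id", "chrom", "pos", "a1", "a2", "freq") %in% names(snp_info)),
    all(c("id", "sex", "role", "batch", "design", "affection", "family") %in%
          names(meta)),
    all(meta$sex %in% c("male", "female")),
    !anyDuplicated(meta$id)
  )
  on_x <- snp_info$chrom == "X"
  if (any(on_x)) {
    male_x <- dosages[meta$sex == "male", on_x, drop = FALSE]
    if (any(male_x > 1, na.rm = TRUE)) {
      stop("internal failure: male X dosage exceeds 1")
    }
  }
  rownames(dosages) <- meta$id
  colnames(dosages) <- snp_info$id
  structure(list(snp_info = snp_info, dosages = dosages, meta = meta),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "genotype_table: %d individuals x %d SNPs (%s)\n",
    nrow(x$dosages), ncol(x$dosages),
    paste(sprintf("%s=%d", names(table(x$meta$role)), table(x$meta$role)),
          collapse = ", ")
  ))
  invisible(x)
}

#' Number of individuals / SNPs in a genotype table
#' @param g a `genotype_table`.
#' @return Integer count.
#' @export
n_individuals <- function(g) nrow(g$dosages)

#' @rdname n_individuals
#' @export
n_snps <- function(g) ncol(g$dosages)

#' Subset a genotype table
#'
#' @param g a `genotype_table`.
#' @param individuals logical/integer/character index into rows (optional).
#' @param snps logical/integer/character index into SNP columns (optional).
#' @return A `genotype_table`.
#' @export
subset_genotypes <- function(g, individuals = NULL, snps = NULL) {
  d <- g$dosages
  meta <- g$meta
  si <- g$snp_info
  if (!is.null(individuals)) {
    if (is.character(individuals)) individuals <- match(individuals, meta$id)
    d <- d[individuals, , drop = FALSE]
    meta <- meta[individuals, , drop = FALSE]
  }
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, si$id)
    d <- d[, snps, drop = FALSE]
    si <- si[snps, , drop = FALSE]
  }
  rownames(meta) <- NULL
  rownames(si) <- NULL
  genotype_table(si, d, meta)
}

#' Row-bind genotype tables sharing a SNP panel
#'
#' @param ... `genotype_table` objects with identical `snp_info`.
#' @return A `genotype_table`.
#' @export
bind_genotype_tables <- function(...) {
  gs <- list(...)
  stopifnot(length(gs) >= 1)
  si <- gs[[1]]$snp_info
  for (g in gs[-1]) {
    if (!identical(g$snp_info$id, si$id)) stop("SNP panels differ")
  }
  genotype_table(
    si,
    do.call(rbind, lapply(gs, function(g) g$dosages)),
    do.call(rbind, lapply(gs, function(g) {
      m <- g$meta
      rownames(m) <- NULL
      m
    }))
  )
}

new_meta <- function(id, sex, role, batch, design, affection, family = NA) {
  data.frame(
    id = id, sex = sex, role = role, batch = batch, design = design,
    affection = affection, family = family, stringsAsFactors = FALSE
  )
}
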