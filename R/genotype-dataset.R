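#' Construct a multi-study genotype dataset
#'
#' The container consumed by every analysis stage: a samples-by-SNPs matrix of
#' minor-allele dosages (0/1/2, `NA` for missing), a per-sample covariate
#' table, and a per-SNP annotation table mapping each SNP to one or two gene
#' regions and a functional group.
#'
#' @param genotypes Integer matrix, samples in rows (rownames = sample IDs),
#'   SNPs in columns (colnames = rsIDs); values in `{0, 1, 2, NA}` counting
#'   minor alleles.
#' @param samples Data frame with columns `sample_id`, `study`, `design`
#'   (`"case_control"` or `"family"`), `family_id` (`NA` unless the study is
#'   a family study), `status` (`"case"` / `"unaffected"`), `age` (years),
#'   `sex` (`"male"` / `"female"`), and optionally `nevus_count`,
#'   `dysplastic_nevi` (`"absent"` / `"present"` / `NA`), `chronic_sun`,
#'   `intermittent_sun`.
#' @param snps Data frame with columns `rsid`, `chrom`, `pos`,
#'   `minor_allele`, `major_allele`, `genes` (comma-separated gene regions,
#'   one or two), `functional_group`, and optionally the QC flags
#'   `assay_failed` and `genotypeable`.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, samples, snps) {
  samples <- tibble::as_tibble(samples)
  snps <- tibble::as_tibble(snps)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"

  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype values must be 0, 1, 2 or NA (found ",
         paste(unique(setdiff(bad, 0:2)), collapse = ", "), ")")
  }
  if (nrow(genotypes) != nrow(samples)) {
    stop("genotype matrix has ", nrow(genotypes), " rows but sample table has ",
         nrow(samples))
  }
  if (ncol(genotypes) != nrow(snps)) {
    stop("genotype matrix has ", ncol(genotypes), " columns but SNP table has ",
         nrow(snps), " rows")
  }
  if (is.null(rownames(genotypes))) rownames(genotypes) <- samples$sample_id
  if (is.null(colnames(genotypes))) colnames(genotypes) <- snps$rsid
  stopifnot(identical(rownames(genotypes), as.character(samples$sample_id)),
            identical(colnames(genotypes), as.character(snps$rsid)))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample IDs")
  if (anyDuplicated(snps$rsid)) stop("duplicate rsIDs")
  if (!all(samples$status %in% c("case", "unaffected"))) {
    stop("status must be 'case' or 'unaffected'")
  }
  if (any(is.na(snps$genes) | !nzchar(snps$genes))) {
    stop("every SNP must map to at least one gene region")
  }
  fam_design <- samples$design == "family"
  if (any(fam_design & is.na(samples$family_id))) {
    stop("family_id required for samples in family-design studies")
  }
  for (col in c("nevus_count", "dysplastic_nevi", "chronic_sun",
                "intermittent_sun", "family_id")) {
    if (!col %in% names(samples)) samples[[col]] <- NA
  }
  structure(list(genotypes = genotypes, samples = samples, snps = snps),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("<genotype_dataset> ", nrow(x$genotypes), " samples x ",
      ncol(x$genotypes), " SNPs\n", sep = "")
  tab <- table(x$samples$study, x$samples$status)
  print(tab)
  cat(length(unique(unlist(strsplit(x$snps$genes, ",", fixed = TRUE)))),
      "gene regions;",
      length(unique(x$snps$functional_group)), "functional groups\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Subset a genotype dataset
#'
#' @param dataset A [genotype_dataset()].
#' @param samples,snps Character vectors of sample IDs / rsIDs (or logical or
#'   integer indices) to keep; `NULL` keeps all.
#' @return The subsetted `genotype_dataset`.
#' @export
subset_dataset <- function(dataset, samples = NULL, snps = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  si <- if (is.null(samples)) seq_len(nrow(dataset$genotypes)) else {
    if (is.character(samples)) match(samples, dataset$samples$sample_id) else which(rep(TRUE, nrow(dataset$genotypes)))[samples]
  }
  vi <- if (is.null(snps)) seq_len(ncol(dataset$genotypes)) else {
    if (is.character(snps)) match(snps, dataset$snps$rsid) else which(rep(TRUE, ncol(dataset$genotypes)))[snps]
  }
  if (anyNA(si)) stop("unknown sample IDs")
  if (anyNA(vi)) stop("unknown rsIDs")
  genotype_dataset(dataset$genotypes[si, vi, drop = FALSE],
                   dataset$samples[si, , drop = FALSE],
                   dataset$snps[vi, , drop = FALSE])
}

#' SNP-to-set membership map for gene, group and overall tests
#'
#' Expands the comma-separated `genes` annotation: a SNP mapping to two gene
#' regions appears in both gene-level sets, but enters each functional-group
#' pool and the overall pool only once.
#'
#' @param snps SNP annotation table of a [genotype_dataset()].
#' @return A list with `gene` (named list of rsID vectors per gene region),
#'   `group` (per functional group, duplicates removed) and `overall`.
#' @export
snp_set_map <- function(snps) {
  pairs <- tidyr::separate_rows(
    dplyr::select(tibble::as_tibble(snps), "rsid", "genes", "functional_group"),
    "genes", sep = ",")
  gene <- split(pairs$rsid, pairs$genes)
  grp_tab <- dplyr::distinct(pairs, .data$rsid, .data$functional_group)
  group <- lapply(split(grp_tab$rsid, grp_tab$functional_group), unique)
  list(gene = gene, group = group, overall = unique(snps$rsid))
}
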