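sample_cols <- c("sample_id", "study_id", "family_id", "status", "age",
                 "sex", "nevus_count", "dysplastic_nevi", "chronic_sun",
                 "intermittent_sun")

#' Write a genotype dataset to the tab-delimited interchange dialect
#'
#' One TSV holds the sample table followed by one genotype column per SNP
#' (values 0/1/2/NA counting minor alleles); a companion TSV holds the SNP
#' annotations (1-based positions). [read_genotypes()] round-trips the pair
#' losslessly.
#'
#' @param dataset A [genotype_dataset()].
#' @param path Genotype TSV path.
#' @param annotation_path SNP annotation TSV path.
#' @export
write_genotypes <- function(dataset, path, annotation_path) {
  s <- dataset$samples
  tab <- tibble::tibble(
    sample_id = s$sample_id, study_id = s$study, family_id = s$family_id,
    status = s$status, age = s$age, sex = s$sex,
    nevus_count = s$nevus_count, dysplastic_nevi = s$dysplastic_nevi,
    chronic_sun = s$chronic_sun, intermittent_sun = s$intermittent_sun)
  geno <- tibble::as_tibble(dataset$genotypes)
  readr::write_tsv(dplyr::bind_cols(tab, geno), path, na = "NA")
  readr::write_tsv(dplyr::select(dataset$snps, -dplyr::any_of("true_maf")),
                   annotation_path, na = "NA")
  invisible(path)
}

#' Read a genotype dataset from TSV or VCF
#'
#' The TSV dialect is the one written by [write_genotypes()]. For VCF input
#' (requires the vcfR package) GT calls are converted to ALT-allele dosages,
#' multi-allelic sites are rejected, and the minor allele is defined from
#' the allele frequency among unaffected subjects of the supplied sample
#' table (dosages are flipped where ALT is the major allele).
#'
#' @param path Genotype TSV or VCF path.
#' @param annotation_path SNP annotation TSV (required; every SNP must map
#'   to a gene region).
#' @param format `"tsv"` or `"vcf"`.
#' @param samples Sample table (required for VCF input).
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, annotation_path, format = c("tsv", "vcf"),
                           samples = NULL) {
  format <- match.arg(format)
  snps <- readr::read_tsv(annotation_path, show_col_types = FALSE)
  if (format == "vcf") {
    return(read_genotypes_vcf(path, snps, samples))
  }
  raw <- readr::read_tsv(
    path, show_col_types = FALSE, na = "NA",
    col_types = readr::cols(
      sample_id = "c", study_id = "c", family_id = "c", status = "c",
      age = "d", sex = "c", nevus_count = "i", dysplastic_nevi = "c",
      chronic_sun = "c", intermittent_sun = "c", .default = "i"))
  geno_cols <- setdiff(names(raw), sample_cols)
  G <- as.matrix(raw[, geno_cols])
  bad <- which(!(is.na(G) | G %in% 0:2), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid genotype code '", G[bad[1, 1], bad[1, 2]], "' at line ",
         bad[1, 1] + 1L, " (sample ", raw$sample_id[bad[1, 1]], ", SNP ",
         geno_cols[bad[1, 2]], ")")
  }
  storage.mode(G) <- "integer"
  rownames(G) <- raw$sample_id
  fam_study <- unique(raw$study_id[!is.na(raw$family_id)])
  samples <- tibble::tibble(
    sample_id = raw$sample_id, study = raw$study_id,
    design = ifelse(raw$study_id %in% fam_study, "family", "case_control"),
    family_id = raw$family_id, status = raw$status, age = raw$age,
    sex = raw$sex, nevus_count = raw$nevus_count,
    dysplastic_nevi = raw$dysplastic_nevi, chronic_sun = raw$chronic_sun,
    intermittent_sun = raw$intermittent_sun)
  genotype_dataset(G, samples, snps[match(geno_cols, snps$rsid), ])
}

read_genotypes_vcf <- function(path, snps, samples) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF input requires the vcfR package")
  }
  if (is.null(samples)) stop("VCF input needs a sample table (for control allele frequencies)")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {  # single-variant files come back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    stop("multi-allelic VCF site(s) rejected: ",
         paste(fix[multi, "ID"], collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  G <- t(dos)
  colnames(G) <- fix[, "ID"]
  samples <- tibble::as_tibble(samples)
  G <- G[match(samples$sample_id, rownames(G)), , drop = FALSE]
  ctrl <- samples$status == "unaffected"
  alt_freq <- colMeans(G[ctrl, , drop = FALSE], na.rm = TRUE) / 2
  flip <- !is.na(alt_freq) & alt_freq > 0.5
  G[, flip] <- 2L - G[, flip]
  ann <- snps[match(colnames(G), snps$rsid), ]
  genotype_dataset(G, samples, ann)
}

#' Write / read qPCR plates as CSV
#'
#' One CSV holds both reactions; columns `plate_id`, `target`, `well`,
#' `sample_id`, `type`, `replicate`, `ct`, `ng`.
#'
#' @param plates A `qpcr_plate_set` (see [simulate_qpcr_plates()]).
#' @param path CSV path.
#' @export
write_plates <- function(plates, path) {
  readr::write_csv(dplyr::bind_rows(plates$t_plate, plates$s_plate), path,
                   na = "NA")
  invisible(path)
}

#' @rdname write_plates
#' @return `read_plates()` returns a `qpcr_plate_set`.
#' @export
read_plates <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, na = "NA")
  structure(list(t_plate = raw[raw$target == "T", ],
                 s_plate = raw[raw$target == "S", ]),
            class = "qpcr_plate_set")
}

#' Bonferroni significance threshold for the SNP-based analysis
#'
#' @param n_snps Number of SNPs entering the SNP-based analysis (post-QC).
#' @param alpha Family-wise error rate.
#' @return `alpha / n_snps`.
#' @export
bonferroni_threshold <- function(n_snps, alpha = 0.05) {
  if (n_snps < 1) stop("n_snps must be positive")
  alpha / n_snps
}

#' Run the full association pipeline
#'
#' QC cascade, per-study SNP models, random-effects meta-analysis, ARTP
#' gene/group/overall tables (ordered from most to least significant) for
#' each requested outcome, the Bonferroni threshold computed from the
#' number of analyzed SNPs, and — when plates are supplied — the telomere
#' stage (T/S ratios plus the TL-melanoma meta-analysis). With `out_dir`
#' set, results are written as TSVs alongside a JSON provenance record
#' (settings, seed and a content hash).
#'
#' @param dataset A [genotype_dataset()].
#' @param plates Optional `qpcr_plate_set`; `NULL` skips the telomere stage.
#' @param outcomes Outcomes to analyse (those unsupported by the data are
#'   skipped with a message).
#' @param B Permutations for the ARTP null.
#' @param seed Integer seed.
#' @param thresholds QC thresholds passed to [apply_snp_filters()].
#' @param duplicates Optional duplicate-concordance table for QC.
#' @param covariates Adjustment covariates.
#' @param out_dir Optional output directory.
#' @return List: `qc_report`, `n_analyzed`, `bonferroni`, per-outcome
#'   `snp` / `artp` tables, and `telomere` (or `NULL`).
#' @export
run_pipeline <- function(dataset, plates = NULL,
                         outcomes = c("melanoma", "dysplastic_nevi",
                                      "nevus_count"),
                         B = 10000L, seed = 1L,
                         thresholds = list(), duplicates = NULL,
                         covariates = c("age", "sex"), out_dir = NULL) {
  qc <- apply_snp_filters(dataset, thresholds, duplicates)
  clean <- qc$dataset
  n_analyzed <- ncol(clean$genotypes)
  bonf <- bonferroni_threshold(n_analyzed)

  results <- list()
  for (i in seq_along(outcomes)) {
    oc <- outcomes[i]
    if (!length(eligible_studies(clean, oc))) {
      message("outcome ", oc, " not supported by any study; skipped")
      next
    }
    res <- artp_analysis(clean, oc, B = B, seed = seed + i,
                         covariates = covariates)
    res$snp$significant <- !is.na(res$snp$p) & res$snp$p < bonf
    results[[oc]] <- res[c("snp", "artp")]
  }

  telomere <- NULL
  if (!is.null(plates) &&
      nrow(plates$t_plate[plates$t_plate$type == "sample", ]) > 0) {
    measures <- ts_ratio(plates$t_plate, plates$s_plate)
    telomere <- list(measures = measures,
                     melanoma = tryCatch(tl_melanoma_or(measures, clean),
                                         error = function(e) NULL))
  } else if (!is.null(plates)) {
    message("empty plate input; telomere stage skipped")
  }

  out <- list(qc_report = qc$report, n_analyzed = n_analyzed,
              bonferroni = bonf, outcomes = results, telomere = telomere,
              seed = seed)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, B, seed)
  out
}

write_pipeline_outputs <- function(out, out_dir, B, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(out$qc_report$per_snp, file.path(out_dir, "qc_snps.tsv"))
  readr::write_tsv(out$qc_report$totals, file.path(out_dir, "qc_totals.tsv"))
  for (oc in names(out$outcomes)) {
    readr::write_tsv(out$outcomes[[oc]]$snp,
                     file.path(out_dir, paste0("snp_", oc, ".tsv")))
    readr::write_tsv(out$outcomes[[oc]]$artp,
                     file.path(out_dir, paste0("artp_", oc, ".tsv")))
  }
  if (!is.null(out$telomere)) {
    readr::write_tsv(out$telomere$measures,
                     file.path(out_dir, "telomere_measures.tsv"))
  }
  settings <- list(B = B, seed = seed, n_analyzed = out$n_analyzed,
                   bonferroni = out$bonferroni,
                   thresholds = out$qc_report$thresholds,
                   package_version = as.character(utils::packageVersion("telosnp")))
  settings$config_hash <- content_hash(settings)
  jsonlite::write_json(settings, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# Dependency-free stable content hash (polynomial rolling hash over the
# serialized object; exact in double precision).
content_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
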