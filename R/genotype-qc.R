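#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: all
#' heterozygote counts with the parity of the minor-allele count are
#' enumerated, each configuration's conditional (Levene-Haldane) probability
#' is computed, and the p-value is the sum of probabilities no larger than
#' that of the observed configuration.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return Exact two-sided p-value in `(0, 1]`.
#' @export
#' @examples
#' hwe_exact_test(2, 0, 2)  # 6/70
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped subject required")
  n_a <- 2L * n_aa + n_Aa          # minor allele count
  n_A <- 2L * n_AA + n_Aa
  rare <- min(n_a, n_A)
  if (rare == 0L) return(1.0)      # monomorphic: single attainable configuration
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- hets * log(2) + lfactorial(n) -
    lfactorial((n_a - hets) / 2) - lfactorial(hets) -
    lfactorial((n_A - hets) / 2) +
    lfactorial(n_a) + lfactorial(n_A) - lfactorial(2 * n)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_Aa, hets)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' Conditional probabilities of all attainable heterozygote counts
#'
#' Enumeration behind [hwe_exact_test()]; exposed for self-checks (the
#' probabilities sum to one).
#' @inheritParams hwe_exact_test
#' @return Tibble with `n_het` and `prob`.
#' @export
hwe_het_distribution <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2L * n_aa + n_Aa
  n_A <- 2L * n_AA + n_Aa
  rare <- min(n_a, n_A)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- hets * log(2) + lfactorial(n) -
    lfactorial((n_a - hets) / 2) - lfactorial(hets) -
    lfactorial((n_A - hets) / 2) +
    lfactorial(n_a) + lfactorial(n_A) - lfactorial(2 * n)
  prob <- exp(logp - max(logp))
  tibble::tibble(n_het = hets, prob = prob / sum(prob))
}

#' Minor-allele frequency among unaffected subjects
#'
#' @param dataset A [genotype_dataset()].
#' @return Named numeric vector of control MAFs (pooled across studies).
#' @export
control_maf <- function(dataset) {
  ctrl <- dataset$genotypes[dataset$samples$status == "unaffected", ,
                            drop = FALSE]
  colMeans(ctrl, na.rm = TRUE) / 2
}

#' Apply the SNP-level quality-control cascade
#'
#' Exclusions are applied in a fixed order — assay failure, monoallelic,
#' call rate, duplicate concordance, not genotypeable, Hardy-Weinberg
#' disequilibrium in unaffected subjects, control MAF — and each excluded SNP
#' is counted once under the first check it fails, so per-reason totals add
#' up. HWE and MAF are computed in unaffected subjects pooled across studies.
#' The concordance filter needs a duplicate-sample concordance table; when
#' none is supplied that filter is skipped (with a message).
#'
#' @param dataset A [genotype_dataset()]; QC flag columns `assay_failed` and
#'   `genotypeable` in the SNP table are honoured when present.
#' @param thresholds List with `min_call_rate`, `min_concordance`,
#'   `min_maf_controls`, `hwe_alpha` (all in `[0, 1]`).
#' @param duplicates Optional data frame `rsid`, `concordance` from a
#'   duplicate-sample comparison.
#' @return List with `dataset` (kept SNPs only) and `report` (a `qc_report`).
#' @export
apply_snp_filters <- function(dataset,
                              thresholds = list(min_call_rate = 0.90,
                                                min_concordance = 0.95,
                                                min_maf_controls = 0.01,
                                                hwe_alpha = 0.05 / 20809),
                              duplicates = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (ncol(dataset$genotypes) == 0) stop("empty dataset")
  th <- utils::modifyList(
    list(min_call_rate = 0.90, min_concordance = 0.95,
         min_maf_controls = 0.01, hwe_alpha = 0.05 / 20809),
    thresholds)
  num <- unlist(th[c("min_call_rate", "min_concordance", "min_maf_controls")])
  if (any(num < 0 | num > 1)) stop("thresholds must lie in [0, 1]")

  g <- dataset$genotypes
  snps <- dataset$snps
  ctrl <- dataset$samples$status == "unaffected"
  L <- ncol(g)

  call_rate <- colMeans(!is.na(g))
  maf <- control_maf(dataset)
  hwe_p <- vapply(seq_len(L), function(j) {
    gc <- g[ctrl, j]
    gc <- gc[!is.na(gc)]
    if (!length(gc)) return(NA_real_)
    hwe_exact_test(sum(gc == 0L), sum(gc == 1L), sum(gc == 2L))
  }, numeric(1))

  reason <- rep(NA_character_, L)
  flag <- function(idx, why) {
    hit <- idx & is.na(reason)
    reason[hit] <<- why
  }
  assay <- if ("assay_failed" %in% names(snps)) isTRUE_v(snps$assay_failed) else rep(FALSE, L)
  flag(assay, "assay_failed")
  mono <- vapply(seq_len(L), function(j) {
    v <- g[, j][!is.na(g[, j])]
    length(v) > 0 && length(unique(v)) == 1L
  }, logical(1))
  flag(mono, "monoallelic")
  flag(call_rate < th$min_call_rate, "call_rate")
  if (is.null(duplicates)) {
    message("no duplicate-sample table supplied; concordance filter skipped")
  } else {
    conc <- duplicates$concordance[match(snps$rsid, duplicates$rsid)]
    flag(!is.na(conc) & conc < th$min_concordance, "concordance")
  }
  notgt <- if ("genotypeable" %in% names(snps)) !isTRUE_v(snps$genotypeable, default = TRUE) else rep(FALSE, L)
  flag(notgt, "not_genotypeable")
  flag(!is.na(hwe_p) & hwe_p < th$hwe_alpha, "hwe")
  flag(!is.na(maf) & maf < th$min_maf_controls, "maf")

  per_snp <- tibble::tibble(
    rsid = snps$rsid, call_rate = call_rate, control_maf = maf,
    hwe_p = hwe_p,
    status = ifelse(is.na(reason), "kept", paste0("excluded:", reason)))
  reasons <- c("assay_failed", "monoallelic", "call_rate", "concordance",
               "not_genotypeable", "hwe", "maf")
  n_by_reason <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE),
                        integer(1))
  totals <- tibble::tibble(reason = reasons, n = unname(n_by_reason))
  kept <- is.na(reason)
  n_genotyped <- sum(kept) + totals$n[totals$reason == "maf"]
  report <- structure(
    list(per_snp = per_snp, totals = totals, thresholds = th,
         n_input = L, n_genotyped = n_genotyped, n_kept = sum(kept)),
    class = "qc_report")
  list(dataset = subset_dataset(dataset, snps = snps$rsid[kept]),
       report = report)
}

isTRUE_v <- function(x, default = FALSE) {
  x <- as.logical(x)
  x[is.na(x)] <- default
  x
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$n_input, " SNPs in; ", x$n_genotyped,
      " passed genotyping QC; ", x$n_kept, " kept for analysis\n", sep = "")
  print(as.data.frame(x$totals), row.names = FALSE)
  invisible(x)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of minor-allele dosages (composite LD),
#' computed over samples non-missing for both SNPs.
#'
#' @param dataset A [genotype_dataset()].
#' @param snp_a,snp_b rsIDs.
#' @return r-squared in `[0, 1]`, or `NA` when either SNP has zero variance
#'   among the complete pairs.
#' @export
pairwise_r2 <- function(dataset, snp_a, snp_b) {
  ga <- dataset$genotypes[, snp_a]
  gb <- dataset$genotypes[, snp_b]
  keep <- !is.na(ga) & !is.na(gb)
  if (sum(keep) < 2) stop("fewer than 2 complete sample pairs")
  ga <- ga[keep]; gb <- gb[keep]
  if (stats::var(ga) == 0 || stats::var(gb) == 0) return(NA_real_)
  stats::cor(ga, gb)^2
}

#' Full pairwise r-squared matrix
#'
#' @param dataset A [genotype_dataset()].
#' @param snps Optional rsIDs to restrict to.
#' @return Symmetric matrix of dosage r-squared (pairwise-complete).
#' @export
ld_r2_matrix <- function(dataset, snps = NULL) {
  g <- dataset$genotypes
  if (!is.null(snps)) g <- g[, snps, drop = FALSE]
  suppressWarnings(stats::cor(g, use = "pairwise.complete.obs")^2)
}

age_band <- function(age) {
  cut(age, breaks = c(-Inf, 30, 40, 50, 60, Inf), right = FALSE,
      labels = c("<30", "30-39", "40-49", "50-59", ">=60"))
}

nevus_band <- function(count) {
  cut(count, breaks = c(-Inf, 9.5, 50.5, Inf),
      labels = c("<10", "10-50", ">50"))
}

#' Descriptive characteristics table by case status
#'
#' Counts and percentages of age band, sex, nevus-count band (<10, 10-50,
#' >50), dysplastic nevi and sun-exposure categories, separately for cases
#' and unaffected subjects. Percentages are computed over non-missing values
#' of each variable and rounded to one decimal.
#'
#' @param dataset A [genotype_dataset()].
#' @return Tibble with `variable`, `category`, `n_case`, `pct_case`,
#'   `n_unaffected`, `pct_unaffected`.
#' @export
descriptive_table <- function(dataset) {
  s <- dataset$samples
  vars <- list(
    age = as.character(age_band(s$age)),
    sex = as.character(s$sex),
    nevus_count = as.character(nevus_band(s$nevus_count)),
    dysplastic_nevi = as.character(s$dysplastic_nevi),
    chronic_sun = as.character(s$chronic_sun),
    intermittent_sun = as.character(s$intermittent_sun))
  lvls <- list(
    age = c("<30", "30-39", "40-49", "50-59", ">=60"),
    sex = c("male", "female"),
    nevus_count = c("<10", "10-50", ">50"),
    dysplastic_nevi = c("absent", "present"),
    chronic_sun = c("no", "yes"),
    intermittent_sun = c("very_little", "some", "high"))
  is_case <- s$status == "case"
  rows <- lapply(names(vars), function(v) {
    x <- vars[[v]]
    if (all(is.na(x))) return(NULL)
    lv <- intersect(lvls[[v]], unique(x[!is.na(x)]))
    nc <- vapply(lv, function(l) sum(x == l & is_case, na.rm = TRUE), integer(1))
    nu <- vapply(lv, function(l) sum(x == l & !is_case, na.rm = TRUE), integer(1))
    tibble::tibble(
      variable = v, category = lv,
      n_case = unname(nc), pct_case = unname(round(100 * nc / sum(nc), 1)),
      n_unaffected = unname(nu),
      pct_unaffected = unname(round(100 * nu / sum(nu), 1)))
  })
  dplyr::bind_rows(rows)
}
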