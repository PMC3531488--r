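#' Configuration for the multi-study synthetic data generator
#'
#' Defaults emulate four Mediterranean melanoma studies: three case-control
#' studies (227/173, 264/165 and 207/207 cases/controls) and one family
#' study of 62 families with 96 affected and 225 unaffected members, so the
#' unaffected total is 770. Genotypes cover 39 gene regions with 476 tagSNPs
#' (12-13 per gene, nine SNPs annotated to two regions) in five functional
#' groups, with per-SNP MAFs drawn from `maf_range` and within-gene LD from
#' a Gaussian copula with first-order autocorrelation `ld_block_rho`.
#'
#' @param studies Data frame of study designs and per-study quotas.
#' @param family_sizes,family_cases Integer vectors, one entry per family in
#'   the family study: total members (two founders plus offspring) and the
#'   number of affected members.
#' @param n_genes,snps_per_gene,dual_gene_snps Gene regions, SNPs per region
#'   (recycled), and how many SNPs are annotated to two adjacent regions.
#' @param n_groups Number of functional groups (genes assigned round-robin).
#' @param maf_range Range for per-SNP minor-allele frequencies, in (0, 1).
#' @param ld_block_rho Copula correlation between adjacent SNPs in a gene,
#'   in \[0, 1).
#' @param causal_effects List with named numeric vectors `melanoma`
#'   (per-allele log-OR), `nevus_count` (log-IRR), `dysplastic_nevi`
#'   (log-OR), names = rsIDs.
#' @param age_range Age range (years) for unrelated subjects.
#' @param baseline_prevalence Baseline melanoma probability at mean age; a
#'   free sampling parameter of the generator (case-control sampling makes
#'   odds ratios invariant to it).
#' @param dn_prevalence Baseline probability of dysplastic nevi.
#' @param nevus_base_rate Mean nevus count at mean age.
#' @param age_logor,sex_logor Covariate effects in the melanoma model.
#' @param nevus_age_slope Log-linear age slope of the nevus-count mean.
#' @param tl_decline_per_year Change in ln(T/S) per year of age.
#' @param tl_sd Residual SD of ln(T/S).
#' @param missing_rate Genotype missingness rate.
#' @param seed Integer seed; fixed seed gives byte-identical bundles.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(studies = NULL,
                       family_sizes = rep(c(5L, 6L), c(51L, 11L)),
                       family_cases = rep(c(1L, 2L), c(28L, 34L)),
                       n_genes = 39L, snps_per_gene = rep(c(13L, 12L), c(8L, 31L)),
                       dual_gene_snps = 9L, n_groups = 5L,
                       maf_range = c(0.05, 0.5), ld_block_rho = 0.5,
                       causal_effects = list(), age_range = c(17, 80),
                       baseline_prevalence = 0.3, dn_prevalence = 0.3,
                       nevus_base_rate = 15, age_logor = 0.01,
                       sex_logor = 0.1, nevus_age_slope = -0.01,
                       tl_decline_per_year = -0.005, tl_sd = 0.15,
                       missing_rate = 0, seed = 1L) {
  if (is.null(studies)) {
    studies <- tibble::tibble(
      study = c("ccs1", "ccs2", "ccs3", "fs"),
      design = c("case_control", "case_control", "case_control", "family"),
      n_cases = c(227L, 264L, 207L, NA),
      n_controls = c(173L, 165L, 207L, NA))
  }
  studies <- tibble::as_tibble(studies)
  cc <- studies[studies$design == "case_control", ]
  if (any(!is.na(cc$n_cases) & cc$n_cases <= 0) ||
      any(!is.na(cc$n_controls) & cc$n_controls <= 0)) {
    stop("sample sizes must be positive")
  }
  if (any(maf_range <= 0) || any(maf_range >= 1)) {
    stop("maf_range must lie strictly inside (0, 1)")
  }
  if (ld_block_rho < 0 || ld_block_rho >= 1) stop("ld_block_rho must be in [0, 1)")
  if (nevus_base_rate <= 0 || baseline_prevalence <= 0 ||
      baseline_prevalence >= 1) stop("rates must be positive (probabilities in (0,1))")
  if (any(family_cases >= family_sizes)) {
    stop("each family needs at least one unaffected member")
  }
  ce <- utils::modifyList(
    list(melanoma = numeric(), nevus_count = numeric(),
         dysplastic_nevi = numeric()), as.list(causal_effects))
  structure(list(
    studies = studies, family_sizes = as.integer(family_sizes),
    family_cases = as.integer(family_cases), n_genes = as.integer(n_genes),
    snps_per_gene = rep_len(as.integer(snps_per_gene), n_genes),
    dual_gene_snps = as.integer(dual_gene_snps), n_groups = as.integer(n_groups),
    maf_range = maf_range, ld_block_rho = ld_block_rho, causal_effects = ce,
    age_range = age_range, baseline_prevalence = baseline_prevalence,
    dn_prevalence = dn_prevalence, nevus_base_rate = nevus_base_rate,
    age_logor = age_logor, sex_logor = sex_logor,
    nevus_age_slope = nevus_age_slope,
    tl_decline_per_year = tl_decline_per_year, tl_sd = tl_sd,
    missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_config")
}

# SNP annotation shared by every batch drawn under one config.
build_snp_table <- function(config) {
  genes <- sprintf("gene%02d", seq_len(config$n_genes))
  groups <- sprintf("group%d", ((seq_len(config$n_genes) - 1L) %% config$n_groups) + 1L)
  gene_of_snp <- rep(seq_len(config$n_genes), config$snps_per_gene)
  L <- length(gene_of_snp)
  rsid <- sprintf("rs%06d", seq_len(L))
  gene_lab <- genes[gene_of_snp]
  # a handful of SNPs sit in two overlapping gene regions and are annotated
  # to both; they enter both gene-level tests
  dual <- which(!duplicated(gene_of_snp))[-1]
  dual <- utils::head(dual, config$dual_gene_snps)
  gene_lab[dual] <- paste(genes[gene_of_snp[dual] - 1L], gene_lab[dual], sep = ",")
  mafs <- stats::runif(L, config$maf_range[1], config$maf_range[2])
  tibble::tibble(rsid = rsid, chrom = gene_of_snp, pos = seq_len(L) * 1000L,
                 minor_allele = "A", major_allele = "G", genes = gene_lab,
                 functional_group = groups[gene_of_snp], true_maf = mafs)
}

# Gaussian-copula genotypes: latent AR(1) within each gene, thresholded to
# 0/1/2 with Hardy-Weinberg marginal probabilities at each SNP's MAF.
gen_genotype_matrix <- function(n, snps, rho) {
  L <- nrow(snps)
  gene_of_snp <- snps$chrom
  Z <- matrix(stats::rnorm(n * L), n, L)
  if (rho > 0 && L > 1) {
    for (j in 2:L) {
      if (gene_of_snp[j] == gene_of_snp[j - 1L]) {
        Z[, j] <- rho * Z[, j - 1L] + sqrt(1 - rho^2) * Z[, j]
      }
    }
  }
  U <- stats::pnorm(Z)
  p <- snps$true_maf
  c0 <- matrix((1 - p)^2, n, L, byrow = TRUE)
  c1 <- matrix((1 - p)^2 + 2 * p * (1 - p), n, L, byrow = TRUE)
  G <- (U > c0) + (U > c1)
  storage.mode(G) <- "integer"
  dimnames(G) <- list(NULL, snps$rsid)
  G
}

new_samples <- function(n, config, study, design, prefix) {
  tibble::tibble(
    sample_id = sprintf("%s_%05d", prefix, seq_len(n)),
    study = study, design = design, family_id = NA_character_,
    status = "unaffected",
    age = stats::runif(n, config$age_range[1], config$age_range[2]),
    sex = sample(c("male", "female"), n, replace = TRUE),
    nevus_count = NA_integer_, dysplastic_nevi = NA_character_,
    chronic_sun = NA_character_, intermittent_sun = NA_character_)
}

#' Simulate an unascertained cohort of unrelated genotyped samples
#'
#' Draws `n_samples` unrelated subjects with ages, sexes and LD-blocked
#' genotypes under the configured MAFs; no phenotypes are assigned (`status`
#' is initialised to `"unaffected"`). Unrelated samples are in
#' Hardy-Weinberg equilibrium by construction.
#'
#' @param config A [sim_config()].
#' @param n_samples Cohort size.
#' @param study Study label.
#' @param seed Seed (defaults to the config seed).
#' @return A [genotype_dataset()].
#' @export
simulate_genotypes <- function(config, n_samples = 1000L, study = "cohort",
                               seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (n_samples <= 0) stop("n_samples must be positive")
  set.seed(seed)
  snps <- build_snp_table(config)
  samples <- new_samples(n_samples, config, study, "case_control", study)
  G <- gen_genotype_matrix(n_samples, snps, config$ld_block_rho)
  rownames(G) <- samples$sample_id
  genotype_dataset(G, samples, snps)
}

melanoma_eta <- function(G, samples, config) {
  eta <- stats::qlogis(config$baseline_prevalence) +
    config$age_logor * (samples$age - 45) +
    config$sex_logor * (samples$sex == "female")
  for (rs in names(config$causal_effects$melanoma)) {
    eta <- eta + config$causal_effects$melanoma[[rs]] * G[, rs]
  }
  eta
}

draw_secondary_phenotypes <- function(G, samples, config) {
  log_mu <- log(config$nevus_base_rate) +
    config$nevus_age_slope * (samples$age - 45)
  for (rs in names(config$causal_effects$nevus_count)) {
    log_mu <- log_mu + config$causal_effects$nevus_count[[rs]] * G[, rs]
  }
  samples$nevus_count <- stats::rpois(nrow(samples), exp(log_mu))
  eta_dn <- stats::qlogis(config$dn_prevalence)
  for (rs in names(config$causal_effects$dysplastic_nevi)) {
    eta_dn <- eta_dn + config$causal_effects$dysplastic_nevi[[rs]] * G[, rs]
  }
  samples$dysplastic_nevi <- ifelse(
    stats::rbinom(nrow(samples), 1, stats::plogis(eta_dn)) == 1,
    "present", "absent")
  samples
}

#' Assign phenotypes and perform case-control / family ascertainment
#'
#' Melanoma status is drawn from a logistic model with the configured
#' per-allele log-ORs plus age and sex terms; nevus counts from a Poisson
#' model; dysplastic nevi from a logistic model. For case-control studies
#' the supplied cohort is used as the first sampling batch and further
#' batches are drawn until the configured case/control quotas are met
#' (rejection sampling). The returned dataset contains exactly the quota.
#'
#' @param dataset Cohort from [simulate_genotypes()].
#' @param config A [sim_config()]; quotas are taken from the row of
#'   `config$studies` matching `study`, else from `n_cases`/`n_controls`.
#' @param n_cases,n_controls Quotas (override the config row).
#' @param seed Seed.
#' @return A [genotype_dataset()] with `status`, `nevus_count` and
#'   `dysplastic_nevi` filled in and quotas met.
#' @export
simulate_phenotypes <- function(dataset, config, n_cases = NULL,
                                n_controls = NULL, seed = config$seed + 1L) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  missing_causal <- setdiff(
    unlist(lapply(config$causal_effects, names)), dataset$snps$rsid)
  if (length(missing_causal)) {
    stop("causal rsID(s) absent from dataset: ",
         paste(missing_causal, collapse = ", "))
  }
  set.seed(seed)
  study <- dataset$samples$study[1]
  row <- config$studies[config$studies$study == study, ]
  if (is.null(n_cases)) n_cases <- if (nrow(row)) row$n_cases else NA
  if (is.null(n_controls)) n_controls <- if (nrow(row)) row$n_controls else NA

  G <- dataset$genotypes
  samples <- dataset$samples
  case <- stats::rbinom(nrow(samples), 1, stats::plogis(
    melanoma_eta(G, samples, config)))
  samples$status <- ifelse(case == 1, "case", "unaffected")
  if (!is.na(n_cases) && !is.na(n_controls)) {
    batch <- 0L
    while (sum(samples$status == "case") < n_cases ||
           sum(samples$status == "unaffected") < n_controls) {
      batch <- batch + 1L
      if (batch > 200L) stop("quota not reached after 200 batches")
      nb <- max(200L, nrow(samples))
      more <- new_samples(nb, config, study, "case_control",
                          sprintf("%s_b%d", study, batch))
      Gb <- gen_genotype_matrix(nb, dataset$snps, config$ld_block_rho)
      rownames(Gb) <- more$sample_id
      cb <- stats::rbinom(nb, 1, stats::plogis(melanoma_eta(Gb, more, config)))
      more$status <- ifelse(cb == 1, "case", "unaffected")
      samples <- dplyr::bind_rows(samples, more)
      G <- rbind(G, Gb)
    }
    keep <- c(utils::head(which(samples$status == "case"), n_cases),
              utils::head(which(samples$status == "unaffected"), n_controls))
    keep <- sort(keep)
    samples <- samples[keep, , drop = FALSE]
    G <- G[keep, , drop = FALSE]
  }
  samples <- draw_secondary_phenotypes(G, samples, config)
  genotype_dataset(G, samples, dataset$snps)
}

# Family study: two founders per family drawn like unrelated subjects,
# offspring genotypes by Mendelian transmission (one allele per parent per
# SNP). The affected set of the configured size is sampled within each
# family with probability proportional to exp(sum of member risk scores),
# i.e. the conditional-logistic ascertainment model.
simulate_family_study <- function(config, snps, study = "fs") {
  nfam <- length(config$family_sizes)
  all_samples <- list(); all_G <- list()
  for (f in seq_len(nfam)) {
    m <- config$family_sizes[f]
    founders_G <- gen_genotype_matrix(2L, snps, config$ld_block_rho)
    kid_G <- matrix(0L, m - 2L, nrow(snps))
    for (k in seq_len(m - 2L)) {
      a1 <- transmit_allele(founders_G[1, ])
      a2 <- transmit_allele(founders_G[2, ])
      kid_G[k, ] <- a1 + a2
    }
    G <- rbind(founders_G, kid_G)
    age <- c(stats::runif(2, 45, 80), stats::runif(m - 2L, 17, 50))
    fam <- tibble::tibble(
      sample_id = sprintf("%s_f%03d_%d", study, f, seq_len(m)),
      study = study, design = "family",
      family_id = sprintf("f%03d", f), status = "unaffected",
      age = age, sex = sample(c("male", "female"), m, replace = TRUE),
      nevus_count = NA_integer_, dysplastic_nevi = NA_character_,
      chronic_sun = NA_character_, intermittent_sun = NA_character_)
    eta <- melanoma_eta(G, fam, config)
    d <- config$family_cases[f]
    subs <- utils::combn(m, d)
    wt <- exp(apply(subs, 2, function(idx) sum(eta[idx])))
    pick <- subs[, sample.int(ncol(subs), 1, prob = wt)]
    fam$status[pick] <- "case"
    all_samples[[f]] <- fam
    all_G[[f]] <- G
  }
  samples <- dplyr::bind_rows(all_samples)
  G <- do.call(rbind, all_G)
  rownames(G) <- samples$sample_id
  colnames(G) <- snps$rsid
  list(samples = samples, G = G)
}

transmit_allele <- function(g) {
  # number of minor alleles transmitted by a parent with dosage g
  out <- integer(length(g))
  out[g == 2L] <- 1L
  het <- g == 1L
  out[het] <- stats::rbinom(sum(het), 1L, 0.5)
  out
}

#' Simulate a complete multi-study bundle
#'
#' Runs the generator under the full study configuration: ascertained
#' case-control studies, a Mendelian family study with conditional
#' case-quota ascertainment, secondary phenotypes, true ln(T/S) telomere
#' values, and triplicate qPCR plates for the subset of studies with
#' telomere measurements (by default the first case-control study and the
#' family study).
#'
#' @param config A [sim_config()].
#' @param qpcr_studies Studies whose samples get qPCR plates.
#' @param qpcr_noise_sd Ct noise SD for the plates.
#' @return List of class `synthetic_bundle`: `dataset`, `truth` (causal
#'   effects and per-sample true ln(T/S)), `plates`, `provenance`.
#' @export
simulate_bundle <- function(config = sim_config(),
                            qpcr_studies = c("ccs1", "fs"),
                            qpcr_noise_sd = 0.15) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  snps <- build_snp_table(config)
  parts_s <- list(); parts_g <- list()
  for (i in seq_len(nrow(config$studies))) {
    st <- config$studies$study[i]
    if (config$studies$design[i] == "family") {
      fam <- simulate_family_study(config, snps, st)
      fam$samples <- draw_secondary_phenotypes(fam$G, fam$samples, config)
      parts_s[[st]] <- fam$samples
      parts_g[[st]] <- fam$G
    } else {
      n0 <- config$studies$n_cases[i] + config$studies$n_controls[i]
      pool <- new_samples(n0, config, st, "case_control", st)
      G <- gen_genotype_matrix(n0, snps, config$ld_block_rho)
      rownames(G) <- pool$sample_id
      cohort <- genotype_dataset(G, pool, snps)
      asc <- simulate_phenotypes(cohort, config,
                                 n_cases = config$studies$n_cases[i],
                                 n_controls = config$studies$n_controls[i],
                                 seed = config$seed + i)
      parts_s[[st]] <- asc$samples
      parts_g[[st]] <- asc$genotypes
    }
  }
  samples <- dplyr::bind_rows(parts_s)
  G <- do.call(rbind, parts_g)
  if (config$missing_rate > 0) {
    nav <- stats::runif(length(G)) < config$missing_rate
    G[nav] <- NA_integer_
  }
  dataset <- genotype_dataset(G, samples, snps)
  ln_ts <- config$tl_decline_per_year * (samples$age - 45) +
    stats::rnorm(nrow(samples), 0, config$tl_sd)
  names(ln_ts) <- samples$sample_id
  tl_ids <- samples$sample_id[samples$study %in% qpcr_studies]
  plates <- simulate_qpcr_plates(tl_ids, exp(ln_ts[tl_ids]),
                                 noise_sd = qpcr_noise_sd,
                                 seed = config$seed + 97L)
  structure(list(
    dataset = dataset,
    truth = list(causal_effects = config$causal_effects, ln_ts = ln_ts),
    plates = plates,
    provenance = list(config = config, seed = config$seed)),
    class = "synthetic_bundle")
}

#' Simulate triplicate qPCR plates with a dilution-series standard curve
#'
#' Two plates (telomere "T" reaction and single-copy-gene "S" reaction).
#' Each experimental sample has three replicate wells per plate; each plate
#' carries a six-point 1:2 dilution series from 40 ng down to 1.25 ng. Ct
#' values follow a log-linear amplification model,
#' `Ct = intercept - log2(quantity) / log2(1 + efficiency)`, plus Gaussian
#' noise. The T-side quantity of a sample with relative telomere length
#' `ts` is `ts * input_ng`; the S-side quantity is `input_ng`.
#'
#' @param sample_ids Unique sample identifiers.
#' @param true_ts Named (or positionally matched) positive T/S ratios.
#' @param noise_sd Gaussian Ct noise SD (0 gives noiseless plates).
#' @param efficiency Amplification efficiency (1 = perfect doubling).
#' @param input_ng DNA input per experimental well.
#' @param seed Seed.
#' @return List of class `qpcr_plate_set` with tibbles `t_plate` and
#'   `s_plate` (`plate_id`, `target`, `well`, `sample_id`, `type`,
#'   `replicate`, `ct`, `ng`).
#' @export
simulate_qpcr_plates <- function(sample_ids, true_ts, noise_sd = 0.15,
                                 efficiency = 1, input_ng = 20, seed = 1L) {
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  if (any(true_ts <= 0)) stop("true T/S ratios must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(seed)
  slope <- -1 / log2(1 + efficiency)
  dil <- 40 / 2^(0:5)  # 40, 20, 10, 5, 2.5, 1.25 ng
  one_plate <- function(target, intercept, quantities) {
    std <- tidyr::expand_grid(ng = dil, replicate = 1:3)
    smp <- tidyr::expand_grid(sample_id = sample_ids, replicate = 1:3)
    smp$ng <- rep(unname(quantities), each = 3)
    ct_std <- intercept + slope * log2(std$ng)
    ct_smp <- intercept + slope * log2(smp$ng)
    out <- dplyr::bind_rows(
      tibble::tibble(plate_id = paste0("plate_", target), target = target,
                     sample_id = NA_character_, type = "standard",
                     replicate = std$replicate, ct = ct_std, ng = std$ng),
      tibble::tibble(plate_id = paste0("plate_", target), target = target,
                     sample_id = smp$sample_id, type = "sample",
                     replicate = smp$replicate, ct = ct_smp, ng = NA_real_))
    out$ct <- out$ct + stats::rnorm(nrow(out), 0, noise_sd)
    out$well <- sprintf("%s%02d", LETTERS[(seq_len(nrow(out)) - 1) %% 8 + 1],
                        (seq_len(nrow(out)) - 1) %/% 8 + 1)
    out
  }
  structure(list(
    t_plate = one_plate("T", 30, true_ts * input_ng),
    s_plate = one_plate("S", 28, rep(input_ng, length(sample_ids)))),
    class = "qpcr_plate_set")
}

#' Synthetic genotype dataset reproducing a QC exclusion cascade
#'
#' Builds a deterministic case-control dataset in which each quality-control
#' filter removes a known number of SNPs: assay-failure flags, one
#' monoallelic SNP, low call rate, low duplicate concordance,
#' not-genotypeable flags, extreme Hardy-Weinberg disequilibrium among
#' unaffected subjects (every control heterozygous), and SNPs with control
#' MAF below 1%. The remaining SNPs are well-behaved (near-exact
#' Hardy-Weinberg proportions at MAF 0.20, complete calls).
#'
#' @param n_snps Total SNPs before QC.
#' @param exclusions Named counts for `assay_failed`, `monoallelic`,
#'   `call_rate`, `concordance`, `not_genotypeable`, `hwe`.
#' @param n_low_maf SNPs with control MAF below 1% (excluded at the
#'   analysis-restriction step).
#' @param n_cases,n_controls Sample sizes.
#' @return List with `dataset` (a [genotype_dataset()]) and `duplicates`
#'   (the duplicate-sample concordance table consumed by
#'   [apply_snp_filters()]).
#' @export
qc_cascade_example <- function(n_snps = 747L,
                               exclusions = c(assay_failed = 93L,
                                              monoallelic = 1L,
                                              call_rate = 93L,
                                              concordance = 5L,
                                              not_genotypeable = 20L,
                                              hwe = 18L),
                               n_low_maf = 41L,
                               n_cases = 796L, n_controls = 770L) {
  n <- n_cases + n_controls
  n_good <- n_snps - sum(exclusions) - n_low_maf
  if (n_good < 0) stop("exclusion counts exceed n_snps")

  hwe_block <- function(n_grp) {
    # near-exact Hardy-Weinberg proportions at MAF 0.20
    n2 <- round(n_grp * 0.04); n1 <- round(n_grp * 0.32)
    rep(c(2L, 1L, 0L), c(n2, n1, n_grp - n1 - n2))
  }
  good_col <- c(hwe_block(n_cases), hwe_block(n_controls))
  rare_col <- c(rep(0L, n_cases - 1L), 1L,            # one case carrier
                rep(0L, n_controls - 2L), 1L, 1L)     # two control carriers
  lowcall_col <- good_col
  lowcall_col[seq_len(ceiling(0.15 * n))] <- NA_integer_
  hwe_col <- c(rep(0L, n_cases), rep(1L, n_controls)) # every control het

  cols <- list(); status_flag <- character(0)
  add <- function(colv, reason, k) {
    for (i in seq_len(k)) cols[[length(cols) + 1L]] <<- colv
    status_flag <<- c(status_flag, rep(reason, k))
  }
  add(good_col, "assay_failed", exclusions[["assay_failed"]])
  add(rep(0L, n), "monoallelic", exclusions[["monoallelic"]])
  add(lowcall_col, "call_rate", exclusions[["call_rate"]])
  add(good_col, "concordance", exclusions[["concordance"]])
  add(good_col, "not_genotypeable", exclusions[["not_genotypeable"]])
  add(hwe_col, "hwe", exclusions[["hwe"]])
  add(rare_col, "low_maf", n_low_maf)
  add(good_col, "good", n_good)
  G <- do.call(cbind, cols)
  rsid <- sprintf("rs%06d", seq_len(n_snps))
  colnames(G) <- rsid

  samples <- tibble::tibble(
    sample_id = sprintf("s%05d", seq_len(n)),
    study = "ccs", design = "case_control", family_id = NA_character_,
    status = rep(c("case", "unaffected"), c(n_cases, n_controls)),
    age = rep_len(c(25, 35, 45, 55, 65), n),
    sex = rep_len(c("male", "female"), n))
  rownames(G) <- samples$sample_id
  genes <- sprintf("gene%02d", ((seq_len(n_snps) - 1L) %% 39L) + 1L)
  snps <- tibble::tibble(
    rsid = rsid, chrom = 1L, pos = seq_len(n_snps) * 1000L,
    minor_allele = "A", major_allele = "G", genes = genes,
    functional_group = "group1",
    assay_failed = status_flag == "assay_failed",
    genotypeable = status_flag != "not_genotypeable")
  dup <- tibble::tibble(rsid = rsid[status_flag == "concordance"],
                        concordance = 0.90)
  list(dataset = genotype_dataset(G, samples, snps), duplicates = dup)
}

#' Expand printed per-category counts into a sample table
#'
#' Utility for reproducing descriptive-table arithmetic from published
#' marginal counts: each variable's per-category counts are expanded into
#' that many samples (padded with `NA` up to the group total), so
#' [descriptive_table()] recomputes the published percentages.
#'
#' @param cases,unaffected Named lists mapping variable (`age`, `sex`,
#'   `nevus_count`, `dysplastic_nevi`, `chronic_sun`, `intermittent_sun`) to
#'   a named vector of per-category counts.
#' @param n_cases,n_unaffected Group totals (for `NA` padding).
#' @return A [genotype_dataset()] with one placeholder SNP.
#' @export
samples_from_margins <- function(cases, unaffected, n_cases, n_unaffected) {
  rep_values <- list(
    age = c("<30" = 25, "30-39" = 35, "40-49" = 45, "50-59" = 55, ">=60" = 65),
    nevus_count = c("<10" = 5, "10-50" = 30, ">50" = 60))
  expand <- function(margins, n_total) {
    out <- tibble::tibble(.rows = n_total)
    for (v in c("age", "sex", "nevus_count", "dysplastic_nevi",
                "chronic_sun", "intermittent_sun")) {
      cnt <- margins[[v]]
      if (is.null(cnt)) {
        out[[v]] <- NA
        next
      }
      vals <- rep(names(cnt), cnt)
      if (v %in% names(rep_values)) vals <- rep_values[[v]][vals]
      length(vals) <- n_total  # NA padding for missing values
      out[[v]] <- unname(vals)
    }
    out$age <- as.numeric(out$age)
    out$nevus_count <- as.numeric(out$nevus_count)
    out
  }
  tab <- dplyr::bind_rows(
    dplyr::mutate(expand(cases, n_cases), status = "case"),
    dplyr::mutate(expand(unaffected, n_unaffected), status = "unaffected"))
  n <- nrow(tab)
  tab$sample_id <- sprintf("m%05d", seq_len(n))
  tab$study <- "printed"; tab$design <- "case_control"
  tab$family_id <- NA_character_
  G <- matrix(0L, n, 1, dimnames = list(tab$sample_id, "rs000001"))
  snps <- tibble::tibble(rsid = "rs000001", chrom = 1L, pos = 1000L,
                         minor_allele = "A", major_allele = "G",
                         genes = "gene01", functional_group = "group1")
  genotype_dataset(G, tab, snps)
}
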