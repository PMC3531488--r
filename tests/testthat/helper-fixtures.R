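# Shared fixture builders: small study configurations and hand-built
# datasets used across the module tests.

small_config <- function(seed = 1L, n_genes = 4L, snps_per_gene = 5L,
                         n_cases = 80L, n_controls = 80L,
                         n_families = 20L, family_size = 5L,
                         family_cases = 2L, ...) {
  sim_config(
    studies = tibble::tibble(
      study = c("ccs1", "fs"),
      design = c("case_control", "family"),
      n_cases = c(n_cases, NA), n_controls = c(n_controls, NA)),
    family_sizes = rep(family_size, n_families),
    family_cases = rep(family_cases, n_families),
    n_genes = n_genes, snps_per_gene = snps_per_gene, dual_gene_snps = 0L,
    seed = seed, ...)
}

# Four-study null configuration at the scale used for calibration checks.
null_config_4study <- function(seed, n_genes = 40L, snps_per_gene = 5L,
                               n_cc = 100L) {
  sim_config(
    studies = tibble::tibble(
      study = c("ccs1", "ccs2", "ccs3", "fs"),
      design = c(rep("case_control", 3), "family"),
      n_cases = c(rep(n_cc, 3), NA), n_controls = c(rep(n_cc, 3), NA)),
    family_sizes = rep(5L, 25L), family_cases = rep(2L, 25L),
    n_genes = n_genes, snps_per_gene = snps_per_gene, dual_gene_snps = 0L,
    seed = seed)
}

# A one-study case-control dataset built from explicit genotype and status
# vectors (no randomness).
manual_cc_dataset <- function(genotypes, status, age = NULL, sex = NULL) {
  n <- length(status)
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, ncol = 1)
  ids <- sprintf("s%04d", seq_len(n))
  rs <- sprintf("rs%06d", seq_len(ncol(genotypes)))
  dimnames(genotypes) <- list(ids, rs)
  samples <- tibble::tibble(
    sample_id = ids, study = "s1", design = "case_control",
    family_id = NA_character_, status = status,
    age = age %||% rep(40, n),
    sex = sex %||% rep(c("male", "female"), length.out = n))
  snps <- tibble::tibble(
    rsid = rs, chrom = 1L, pos = seq_along(rs), minor_allele = "A",
    major_allele = "G", genes = "gene01", functional_group = "group1")
  genotype_dataset(genotypes, samples, snps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Monte-Carlo oracle for the exact HWE test: shuffle the 2n alleles into
# random genotype pairings and compare conditional configuration
# probabilities, independent of the analytic enumeration.
hwe_mc_oracle <- function(n_AA, n_Aa, n_aa, M = 20000) {
  n <- n_AA + n_Aa + n_aa
  alleles <- rep(c(1L, 0L), c(2L * n_aa + n_Aa, 2L * n_AA + n_Aa))
  dist <- hwe_het_distribution(n_AA, n_Aa, n_aa)
  p_obs <- dist$prob[match(n_Aa, dist$n_het)]
  hits <- 0L
  for (m in seq_len(M)) {
    a <- sample(alleles)
    het <- sum(a[seq(1, 2 * n - 1, by = 2)] != a[seq(2, 2 * n, by = 2)])
    if (dist$prob[match(het, dist$n_het)] <= p_obs * (1 + 1e-12)) {
      hits <- hits + 1L
    }
  }
  hits / M
}

# Brute-force conditional-logistic log-likelihood: direct sum over
# enumerated case subsets, written independently of the fitting code.
clogit_brute_loglik <- function(X, strata, case, beta) {
  ll <- 0
  for (ids in split(seq_along(strata), strata)) {
    d <- sum(case[ids])
    if (d == 0 || d == length(ids)) next
    eta_obs <- sum(X[ids[case[ids] == 1], , drop = FALSE] %*% beta)
    subs <- utils::combn(length(ids), d)
    denom <- sum(apply(subs, 2, function(ix)
      exp(sum(X[ids[ix], , drop = FALSE] %*% beta))))
    ll <- ll + eta_obs - log(denom)
  }
  ll
}

# Brute-force ARTP: recompute s_j and the adaptive p-value for the first
# row of a pooled replicate-by-SNP p-value matrix with explicit loops.
artp_brute <- function(P, candidates) {
  R <- nrow(P)
  W <- matrix(NA_real_, R, length(candidates))
  for (r in seq_len(R)) {
    sp <- sort(P[r, ])
    for (ji in seq_along(candidates)) {
      W[r, ji] <- sum(log(sp[seq_len(candidates[ji])]))
    }
  }
  mins <- rep(NA_real_, R)
  for (r in seq_len(R)) {
    s_r <- rep(NA_real_, length(candidates))
    for (ji in seq_along(candidates)) {
      s_r[ji] <- sum(W[, ji] <= W[r, ji]) / R
    }
    mins[r] <- min(s_r)
  }
  sum(mins <= mins[1]) / R
}
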