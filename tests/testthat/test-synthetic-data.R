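test_that("fixed seed gives byte-identical bundles", {
  b1 <- simulate_bundle(small_config(seed = 42L))
  b2 <- simulate_bundle(small_config(seed = 42L))
  expect_identical(b1$dataset$genotypes, b2$dataset$genotypes)
  expect_identical(b1$dataset$samples, b2$dataset$samples)
  expect_identical(b1$plates$t_plate$ct, b2$plates$t_plate$ct)
  b3 <- simulate_bundle(small_config(seed = 43L))
  expect_false(identical(b1$dataset$genotypes, b3$dataset$genotypes))
})

test_that("observed control MAF tracks the configured MAF", {
  cfg <- sim_config(
    studies = tibble::tibble(study = "c1", design = "case_control",
                             n_cases = 10L, n_controls = 5000L),
    family_sizes = integer(0), family_cases = integer(0),
    n_genes = 1L, snps_per_gene = 3L, dual_gene_snps = 0L,
    maf_range = c(0.3, 0.3), ld_block_rho = 0, seed = 13L)
  b <- simulate_bundle(cfg, qpcr_studies = character(0))
  maf <- control_maf(b$dataset)
  # 3-sigma binomial bound at n = 5000: 0.3 +/- 0.0195
  expect_true(all(maf > 0.28 & maf < 0.32))
})

test_that("unrelated samples are in Hardy-Weinberg equilibrium", {
  cfg <- sim_config(
    studies = tibble::tibble(study = "c1", design = "case_control",
                             n_cases = 10L, n_controls = 2000L),
    family_sizes = integer(0), family_cases = integer(0),
    n_genes = 8L, snps_per_gene = 5L, dual_gene_snps = 0L, seed = 17L)
  b <- simulate_bundle(cfg, qpcr_studies = character(0))
  ctrl <- b$dataset$genotypes[b$dataset$samples$status == "unaffected", ]
  ps <- apply(ctrl, 2, function(g)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2)))
  # no SNP wildly out of HWE; exact p-values roughly uniform
  expect_gt(min(ps), 0.05 / (40 * 100))
  expect_gt(mean(ps > 0.1), 0.7)
})

test_that("within-gene LD is controlled by ld_block_rho", {
  mk <- function(rho) {
    cfg <- sim_config(
      studies = tibble::tibble(study = "c1", design = "case_control",
                               n_cases = 10L, n_controls = 2000L),
      family_sizes = integer(0), family_cases = integer(0),
      n_genes = 4L, snps_per_gene = 5L, dual_gene_snps = 0L,
      ld_block_rho = rho, seed = 19L)
    b <- simulate_bundle(cfg, qpcr_studies = character(0))
    d <- b$dataset
    r2 <- c()
    for (g in unique(d$snps$chrom)) {
      rs <- d$snps$rsid[d$snps$chrom == g]
      for (j in seq_len(length(rs) - 1)) {
        r2 <- c(r2, pairwise_r2(d, rs[j], rs[j + 1]))
      }
    }
    mean(r2)
  }
  expect_lt(mk(0), 0.02)                      # independence case
  expect_gt(mk(0.9), mk(0.5))                 # monotone in rho
  expect_gt(mk(0.9), 0.4)
})

test_that("family genotypes are Mendelian-consistent", {
  b <- simulate_bundle(small_config(seed = 23L, n_families = 30L))
  d <- b$dataset
  fam_rows <- which(d$samples$design == "family")
  for (f in unique(d$samples$family_id[fam_rows])) {
    rows <- which(d$samples$family_id %in% f)
    G <- d$genotypes[rows, , drop = FALSE]
    p1 <- G[1, ]; p2 <- G[2, ]  # founders come first within each family
    kids <- G[-(1:2), , drop = FALSE]
    lo <- (p1 == 2) + (p2 == 2)           # minimum transmissible dosage
    hi <- 2 - ((p1 == 0) + (p2 == 0))     # maximum transmissible dosage
    for (k in seq_len(nrow(kids))) {
      expect_true(all(kids[k, ] >= lo & kids[k, ] <= hi))
    }
  }
})

test_that("ascertainment meets case-control and family quotas", {
  b <- simulate_bundle(small_config(seed = 29L))
  s <- b$dataset$samples
  expect_equal(sum(s$study == "ccs1" & s$status == "case"), 80)
  expect_equal(sum(s$study == "ccs1" & s$status == "unaffected"), 80)
  expect_equal(sum(s$study == "fs" & s$status == "case"), 40)       # 20 x 2
  expect_equal(sum(s$study == "fs" & s$status == "unaffected"), 60) # 20 x 3
  # per-family case quota holds exactly
  per_fam <- tapply(s$status[s$design == "family"] == "case",
                    s$family_id[s$design == "family"], sum)
  expect_true(all(per_fam == 2))
})

test_that("null phenotypes give uniform downstream SNP p-values", {
  cfg <- null_config_4study(seed = 31L, n_genes = 20L, snps_per_gene = 5L)
  b <- simulate_bundle(cfg, qpcr_studies = character(0))
  obs <- permutation_null(b$dataset, "melanoma", B = 0L, seed = 1L)$observed
  expect_gt(stats::ks.test(obs$p, "punif")$p.value, 0.01)
})

test_that("a planted per-allele effect is recovered by the Poisson model", {
  cfg <- sim_config(
    studies = tibble::tibble(study = "c1", design = "case_control",
                             n_cases = 10L, n_controls = 1000L),
    family_sizes = integer(0), family_cases = integer(0),
    n_genes = 1L, snps_per_gene = 3L, dual_gene_snps = 0L,
    maf_range = c(0.3, 0.4), ld_block_rho = 0,
    causal_effects = list(nevus_count = c(rs000002 = 0.3)), seed = 37L)
  b <- simulate_bundle(cfg, qpcr_studies = character(0))
  r <- fit_nevus_poisson(b$dataset, "rs000002", study = "c1")
  expect_true(r$converged)
  expect_lt(abs(exp(r$effect) - exp(0.3)), 0.1)
})

test_that("simulation rejects invalid configurations", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(ld_block_rho = 1), "ld_block_rho")
  expect_error(sim_config(nevus_base_rate = -1), "rates")
  expect_error(
    sim_config(studies = tibble::tibble(study = "x", design = "case_control",
                                        n_cases = -5L, n_controls = 10L)),
    "positive")
  cfg <- small_config()
  pool <- simulate_genotypes(cfg, 50L)
  bad <- sim_config(causal_effects = list(melanoma = c(rs999999 = 0.5)))
  expect_error(simulate_phenotypes(pool, bad), "absent")
})

test_that("qPCR plates carry the dilution series and triplicates", {
  pl <- simulate_qpcr_plates(c("a", "b"), c(a = 1.2, b = 0.8),
                             noise_sd = 0, seed = 2L)
  std <- pl$t_plate[pl$t_plate$type == "standard", ]
  expect_setequal(unique(std$ng), 40 / 2^(0:5))
  expect_true(all(table(std$ng) == 3))
  smp <- pl$s_plate[pl$s_plate$type == "sample", ]
  expect_true(all(table(smp$sample_id) == 3))
  expect_error(simulate_qpcr_plates(c("a", "a"), c(1, 1)), "duplicate")
  expect_error(simulate_qpcr_plates("a", -1), "positive")
})
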