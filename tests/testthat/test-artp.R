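test_that("rank truncated product statistic is the log product of smallest p", {
  p <- c(0.01, 0.5, 0.9)
  expect_equal(rtp_statistic(p, 1), log(0.01))
  expect_equal(rtp_statistic(p, 3), sum(log(p)))
  expect_equal(rtp_statistic(rev(p), 2), rtp_statistic(p, 2))  # rank-based
  expect_error(rtp_statistic(c(0.1, 0), 1), "\\(0, 1\\]")
  expect_error(rtp_statistic(numeric(0), 1), "empty")
  expect_error(rtp_statistic(p, 4), "out of range")
})

test_that("adaptive p equals a brute-force enumeration oracle", {
  set.seed(3)
  for (i in 1:5) {
    B <- 60; L <- 4
    perm <- matrix(runif(B * L)^sample(c(1, 2), 1), B, L,
                   dimnames = list(NULL, sprintf("rs%d", 1:L)))
    obs <- setNames(runif(L)^2, colnames(perm))
    J <- 1:3
    res <- artp_pvalue(obs, perm, candidates = J)
    oracle <- artp_brute(rbind(obs, perm), J)
    expect_equal(res$p, oracle, tolerance = 1e-12)
  }
  # ties handled identically (discrete p-values)
  perm <- matrix(sample(seq(0.05, 1, by = 0.05), 200, TRUE), 50, 4,
                 dimnames = list(NULL, sprintf("rs%d", 1:4)))
  obs <- setNames(c(0.05, 0.2, 0.2, 0.9), colnames(perm))
  res <- artp_pvalue(obs, perm, candidates = 1:4)
  expect_equal(res$p, artp_brute(rbind(obs, perm), 1:4), tolerance = 1e-12)
})

test_that("adaptive p on an exhaustively enumerable toy equals the exact permutation p", {
  # 8 samples, 4 cases: all 70 case assignments enumerated; per-SNP p from
  # Fisher tests of carrier status, the ARTP layer applied to the full
  # enumeration with the observed assignment as replicate 1.
  set.seed(9)
  G <- cbind(rbinom(8, 1, 0.5), rbinom(8, 1, 0.5), rbinom(8, 1, 0.5))
  colnames(G) <- sprintf("rs%d", 1:3)
  subsets <- utils::combn(8, 4)
  pmat <- matrix(NA_real_, ncol(subsets), 3, dimnames = list(NULL, colnames(G)))
  for (b in seq_len(ncol(subsets))) {
    y <- integer(8); y[subsets[, b]] <- 1L
    for (l in 1:3) {
      pmat[b, l] <- stats::fisher.test(table(factor(G[, l], 0:1),
                                             factor(y, 0:1)))$p.value
    }
  }
  obs <- pmat[1, ]
  perm <- pmat[-1, , drop = FALSE]  # the 69 other assignments
  res <- artp_pvalue(obs, perm, candidates = 1:3)
  expect_equal(res$p, artp_brute(pmat, 1:3), tolerance = 1e-14)
  # the adaptive p is an exact enumeration probability: a multiple of 1/70
  expect_equal(res$p * 70, round(res$p * 70), tolerance = 1e-10)
})

test_that("single-SNP set degenerates to the SNP permutation p", {
  set.seed(15)
  B <- 200
  perm <- matrix(runif(B), B, 1, dimnames = list(NULL, "rs1"))
  obs <- c(rs1 = 0.013)
  res <- artp_pvalue(obs, perm, candidates = 1L)
  direct <- (1 + sum(perm[, 1] <= obs)) / (B + 1)
  expect_lte(abs(res$p - direct), 1 / (B + 1) + 1e-12)
  expect_gte(res$p, 1 / (B + 1))
})

test_that("adaptive p respects the Bonferroni sanity bound", {
  set.seed(21)
  for (i in 1:10) {
    L <- sample(3:8, 1)
    B <- 150
    perm <- matrix(runif(B * L), B, L,
                   dimnames = list(NULL, sprintf("rs%d", 1:L)))
    obs <- setNames(runif(L)^3, colnames(perm))
    res <- artp_pvalue(obs, perm)
    expect_lte(res$p, length(res$candidates) * res$min_sj + 1e-12)
    expect_gte(res$p, res$min_sj - 1e-12)
  }
})

test_that("permutation null is reproducible and consistent with the scan", {
  b <- simulate_bundle(small_config(seed = 3L))
  n1 <- permutation_null(b$dataset, "melanoma", B = 30L, seed = 7L)
  n2 <- permutation_null(b$dataset, "melanoma", B = 30L, seed = 7L)
  expect_identical(n1$perm_p, n2$perm_p)
  # observed row equals the per-SNP pipeline output
  for (r in sample(b$dataset$snps$rsid, 4)) {
    sm <- snp_meta(b$dataset, r, "melanoma")
    expect_equal(n1$observed$p[n1$observed$rsid == r], sm$meta$p,
                 tolerance = 1e-8)
    expect_equal(n1$observed$effect[n1$observed$rsid == r], sm$meta$effect,
                 tolerance = 1e-8)
  }
})

test_that("permuted p-values are uniform under the null", {
  cfg <- null_config_4study(seed = 8L, n_genes = 10L, snps_per_gene = 4L)
  b <- simulate_bundle(cfg, qpcr_studies = character(0))
  nul <- permutation_null(b$dataset, "melanoma", B = 200L, seed = 5L)
  # pooled empirical CDF near nominal; entries are dependent across SNPs
  # (shared permuted labels), so the tolerance reflects the effective
  # permutation count, not the raw pool size
  pooled <- as.vector(nul$perm_p)
  expect_lt(abs(mean(pooled <= 0.1) - 0.1), 0.05)
  expect_lt(abs(mean(pooled <= 0.5) - 0.5), 0.06)
})

test_that("a gene of SNPs in perfect LD behaves as its single SNP", {
  b <- simulate_bundle(small_config(seed = 19L, n_genes = 3L,
                                    snps_per_gene = 2L))
  d <- b$dataset
  # duplicate rs000001 into its gene-mates: perfect LD within gene01
  d$genotypes[, 2] <- d$genotypes[, 1]
  nul <- permutation_null(d, "melanoma", B = 300L, seed = 11L)
  obs <- setNames(nul$observed$p, nul$observed$rsid)
  gene_res <- artp_pvalue(obs, nul$perm_p, snps = c("rs000001", "rs000002"))
  snp_res <- artp_pvalue(obs, nul$perm_p, snps = "rs000001")
  expect_lt(abs(gene_res$p - snp_res$p), 0.05)
})

test_that("combine_levels pools genes, groups and overall correctly", {
  set.seed(23)
  L <- 6
  perm <- matrix(runif(100 * L), 100, L,
                 dimnames = list(NULL, sprintf("rs%d", 1:L)))
  obs <- setNames(runif(L), colnames(perm))
  snps <- tibble::tibble(
    rsid = names(obs), chrom = 1L, pos = 1:L, minor_allele = "A",
    major_allele = "G",
    genes = c("g1", "g1", "g2", "g2,g3", "g3", "g3"),
    functional_group = c("grp1", "grp1", "grp1", "grp2", "grp2", "grp2"))
  map <- snp_set_map(snps)
  expect_setequal(map$gene$g3, c("rs4", "rs5", "rs6"))  # dual-mapped SNP
  expect_setequal(map$gene$g2, c("rs3", "rs4"))
  expect_equal(sort(map$overall), sort(names(obs)))     # pooled once
  tab <- combine_levels(obs, perm, map)
  expect_equal(sum(tab$level == "gene"), 3)
  expect_equal(sum(tab$level == "group"), 2)
  expect_equal(sum(tab$level == "overall"), 1)
  genes <- tab[tab$level == "gene", ]
  expect_true(!is.unsorted(genes$p))  # ordered most to least significant
  # single-SNP gene in its own group: gene p equals group p
  snps1 <- tibble::tibble(rsid = "rs1", chrom = 1L, pos = 1L,
                          minor_allele = "A", major_allele = "G",
                          genes = "g1", functional_group = "grp1")
  t1 <- combine_levels(obs["rs1"], perm[, "rs1", drop = FALSE],
                       snp_set_map(snps1))
  expect_equal(t1$p[t1$level == "gene"], t1$p[t1$level == "group"])
})

test_that("nevus-count ARTP runs on the count outcome", {
  b <- simulate_bundle(small_config(seed = 27L, n_genes = 2L,
                                    snps_per_gene = 3L))
  res <- artp_analysis(b$dataset, "nevus_count", B = 40L, seed = 3L)
  expect_true(all(res$artp$p >= 1 / 41 & res$artp$p <= 1))
  expect_equal(sum(res$artp$level == "gene"), 2)
})
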