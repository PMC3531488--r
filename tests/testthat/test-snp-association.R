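test_that("2x2 collapse equals the closed-form cross-product odds ratio", {
  g <- c(rep(1L, 30), rep(0L, 70), rep(1L, 20), rep(0L, 80))
  d <- manual_cc_dataset(g, rep(c("case", "unaffected"), each = 100))
  r <- fit_trend_logistic(d, "rs000001", covariates = character(0))
  expect_equal(exp(r$effect), (30 * 80) / (70 * 20), tolerance = 1e-8)
  expect_equal(r$model, "dominant")  # no homozygous-minor subjects
  expect_equal(r$n_used, 200L)
})

test_that("trend logistic agrees with glm on random datasets", {
  set.seed(101)
  for (i in 1:5) {
    n <- 250
    g <- rbinom(n, 2, runif(1, 0.2, 0.4))
    age <- runif(n, 20, 70)
    sex <- sample(c("male", "female"), n, TRUE)
    y <- rbinom(n, 1, plogis(-0.3 + 0.3 * g + 0.01 * age))
    d <- manual_cc_dataset(g, ifelse(y == 1, "case", "unaffected"),
                           age = age, sex = sex)
    r <- fit_trend_logistic(d, "rs000001")
    gg <- if (r$model == "dominant") as.numeric(g >= 1) else g
    fit <- stats::glm(y ~ gg + age + I(sex == "female"), family = binomial)
    expect_equal(r$effect, unname(coef(fit)["gg"]), tolerance = 1e-6)
    expect_equal(r$se, unname(sqrt(diag(vcov(fit)))["gg"]), tolerance = 1e-6)
  }
})

test_that("dominant fallback is a pure function of the genotype margin", {
  set.seed(7)
  g <- c(rep(2L, 4), rbinom(196, 1, 0.5))  # 4 homozygous-minor subjects
  d <- manual_cc_dataset(g, sample(rep(c("case", "unaffected"), 100)))
  r <- fit_trend_logistic(d, "rs000001")
  expect_equal(r$model, "dominant")
  g2 <- c(rep(2L, 5), rep(1L, 60), rep(0L, 135))
  d2 <- manual_cc_dataset(g2, sample(rep(c("case", "unaffected"), 100)))
  r2 <- fit_trend_logistic(d2, "rs000001")
  expect_equal(r2$model, "additive")
})

test_that("effect sign flips and p is invariant under allele relabeling", {
  set.seed(11)
  g <- rbinom(300, 2, 0.4)
  y <- rbinom(300, 1, plogis(-0.2 + 0.4 * g))
  st <- ifelse(y == 1, "case", "unaffected")
  d1 <- manual_cc_dataset(g, st)
  d2 <- manual_cc_dataset(2L - g, st)
  r1 <- fit_trend_logistic(d1, "rs000001")
  r2 <- fit_trend_logistic(d2, "rs000001")
  expect_equal(r1$effect, -r2$effect, tolerance = 1e-7)
  expect_equal(r1$p, r2$p, tolerance = 1e-7)
  # and invariance to sample order
  perm <- sample(300)
  d3 <- manual_cc_dataset(g[perm], st[perm])
  r3 <- fit_trend_logistic(d3, "rs000001")
  expect_equal(r1$effect, r3$effect, tolerance = 1e-8)
})

test_that("separation is flagged as non-converged, not reported", {
  g <- c(rep(1L, 50), rep(0L, 50))
  d <- manual_cc_dataset(g, rep(c("case", "unaffected"), each = 50))
  r <- fit_trend_logistic(d, "rs000001", covariates = character(0))
  expect_false(r$converged)
  expect_true(is.na(r$effect))
  # constant genotype is a degenerate input
  d2 <- manual_cc_dataset(rep(1L, 100), rep(c("case", "unaffected"), 50))
  expect_error(fit_trend_logistic(d2, "rs000001"), "constant genotype")
})

test_that("conditional logistic likelihood equals subset enumeration", {
  set.seed(13)
  for (i in 1:3) {
    nfam <- 15
    sizes <- sample(2:5, nfam, TRUE)
    strata <- rep(seq_len(nfam), sizes)
    n <- length(strata)
    X <- cbind(rbinom(n, 2, 0.3), runif(n, 20, 70))
    case <- unlist(lapply(sizes, function(m) {
      d <- sample(seq_len(m - 1), 1)
      sample(rep(c(1, 0), c(d, m - d)))
    }))
    for (beta in list(c(0, 0), c(0.5, -0.02), c(-1, 0.05))) {
      expect_equal(telosnp:::clogit_loglik(X, strata, case, beta),
                   clogit_brute_loglik(X, strata, case, beta),
                   tolerance = 1e-10)
    }
  }
})

test_that("conditional logistic MLE matches survival::clogit", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  set.seed(17)
  fam <- rep(1:40, each = 4)
  g <- rbinom(160, 2, 0.3)
  age <- runif(160, 20, 60)
  y <- as.integer(ave(runif(160) + 0.3 * g, fam,
                      FUN = function(v) v >= sort(v, decreasing = TRUE)[2]))
  fit <- telosnp:::clogit_fit(cbind(g, age), fam, y)
  ref <- survival::clogit(y ~ g + age + strata(fam), method = "exact")
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
})

test_that("mirrored 1:1 strata give log-OR zero; single stratum separates", {
  ids <- sprintf("s%02d", 1:4)
  G <- matrix(c(1L, 0L, 0L, 1L), ncol = 1, dimnames = list(ids, "rs000001"))
  samples <- tibble::tibble(
    sample_id = ids, study = "fs", design = "family",
    family_id = c("f1", "f1", "f2", "f2"),
    status = c("case", "unaffected", "case", "unaffected"),
    age = 40, sex = "male")
  snps <- tibble::tibble(rsid = "rs000001", chrom = 1L, pos = 1L,
                         minor_allele = "A", major_allele = "G",
                         genes = "gene01", functional_group = "group1")
  d <- genotype_dataset(G, samples, snps)
  r <- fit_conditional_logistic(d, "rs000001", covariates = character(0))
  expect_true(r$converged)
  expect_equal(r$effect, 0, tolerance = 1e-8)
  # single discordant stratum: conditional likelihood monotone in beta
  d1 <- subset_dataset(d, samples = ids[1:2])
  r1 <- fit_conditional_logistic(d1, "rs000001", covariates = character(0))
  expect_false(r1$converged)
})

test_that("Poisson sandwich reduces to model variance for independent data", {
  set.seed(19)
  n <- 1000
  g <- rbinom(n, 2, 0.3)
  age <- runif(n, 20, 70)
  y <- rpois(n, exp(1.5 + 0.2 * g))
  fit <- telosnp:::poisson_fit(cbind(1, g, age), y, seq_len(n))
  expect_true(fit$converged)
  expect_true(all(fit$se / fit$se_model > 0.9 & fit$se / fit$se_model < 1.1))
})

test_that("Poisson cluster-robust SEs match sandwich::vcovCL", {
  skip_if_not_installed("sandwich")
  set.seed(23)
  n <- 400
  cl <- rep(1:80, each = 5)
  re <- rep(rnorm(80, 0, 0.3), each = 5)
  g <- rbinom(n, 2, 0.3)
  y <- rpois(n, exp(1 + 0.2 * g + re))
  fit <- telosnp:::poisson_fit(cbind(1, g), y, cl)
  ref <- stats::glm(y ~ g, family = poisson)
  vc <- sandwich::vcovCL(ref, cluster = cl)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(sqrt(diag(vc))), tolerance = 1e-6)
})

test_that("nevus Poisson IRR is null when genotype is unassociated", {
  cfg <- sim_config(
    studies = tibble::tibble(study = "c1", design = "case_control",
                             n_cases = 10L, n_controls = 800L),
    family_sizes = integer(0), family_cases = integer(0),
    n_genes = 1L, snps_per_gene = 3L, dual_gene_snps = 0L,
    maf_range = c(0.3, 0.4), seed = 27L)
  b <- simulate_bundle(cfg, qpcr_studies = character(0))
  r <- fit_nevus_poisson(b$dataset, "rs000001", study = "c1")
  expect_lt(abs(exp(r$effect) - 1), 0.1)
})

test_that("interaction term has power under a planted product effect", {
  set.seed(29)
  hits <- 0
  for (i in 1:40) {
    n <- 1500
    g <- rbinom(n, 2, 0.3)
    m <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-0.8 + 0.1 * g + 0.2 * m + 0.7 * g * m))
    d <- manual_cc_dataset(g, ifelse(y == 1, "case", "unaffected"))
    d$samples$dysplastic_nevi <- ifelse(m == 1, "present", "absent")
    r <- fit_interaction(d, "rs000001", "dysplastic_nevi",
                         covariates = character(0))
    if (r$converged && r$p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 40, 0.8)
  # modifier entirely missing -> informative error for that study
  d2 <- manual_cc_dataset(rbinom(100, 2, 0.3),
                          rep(c("case", "unaffected"), 50))
  expect_error(fit_interaction(d2, "rs000001", "dysplastic_nevi"),
               "missing")
})

test_that("nevus score equals the first principal component", {
  set.seed(31)
  n <- 400
  nc <- rpois(n, 20)
  dn <- rbinom(n, 1, plogis(-1 + 0.1 * nc))  # correlated indicators
  d <- manual_cc_dataset(rbinom(n, 2, 0.3),
                         sample(rep(c("case", "unaffected"), n / 2)))
  d$samples$nevus_count <- nc
  d$samples$dysplastic_nevi <- ifelse(dn == 1, "present", "absent")
  sc <- compute_nevus_score(d)
  z <- scale(cbind(nc, dn))
  expect_equal(sc$score, (z[, 1] + z[, 2]) / sqrt(2), tolerance = 1e-10)
  pc <- prcomp(z)$x[, 1]
  expect_equal(abs(cor(sc$score, pc)), 1, tolerance = 1e-8)
  expect_true(all(sc$quartile %in% 1:4))
  # lower-closed quartile intervals: scores exactly at a cut go up
  qs <- stats::quantile(sc$score, c(0.25, 0.5, 0.75), names = FALSE)
  at_cut <- which(sc$score == qs[2])
  if (length(at_cut)) expect_true(all(sc$quartile[at_cut] == 3))
})

test_that("adjusting for the nevus score leaves null SNP ORs unchanged", {
  b <- simulate_bundle(small_config(seed = 33L, n_cases = 150L,
                                    n_controls = 150L))
  d <- b$dataset
  sc <- compute_nevus_score(d)
  d$samples$nevus_q <- sc$quartile[match(d$samples$sample_id, sc$sample_id)]
  rs <- d$snps$rsid[1:10]
  deltas <- vapply(rs, function(r) {
    a <- fit_trend_logistic(d, r, study = "ccs1")
    b2 <- fit_trend_logistic(d, r, study = "ccs1",
                             covariates = c("age", "sex", "nevus_q"))
    abs(a$effect - b2$effect)
  }, numeric(1))
  expect_lt(mean(deltas), 0.05)
})
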