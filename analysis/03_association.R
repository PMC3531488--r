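#!/usr/bin/env Rscript
# Per-study SNP association models and random-effects meta-analysis for the
# three outcomes: melanoma (trend logistic, conditional on family in the
# family study), dysplastic nevi (among unaffected subjects), and nevus
# count (Poisson with age-by-genotype interaction and cluster-robust
# variance). Writes one tidy table per outcome.

library(telosnp)

dataset <- read_genotypes("results/data/genotypes_clean.tsv",
                          "results/data/snp_annotation_clean.tsv")
thr <- bonferroni_threshold(ncol(dataset$genotypes))

for (outcome in c("melanoma", "dysplastic_nevi", "nevus_count")) {
  scan <- permutation_null(dataset, outcome, B = 0L, seed = 1L)
  obs <- scan$observed
  obs$or <- exp(obs$effect)
  obs$ci_lo <- exp(obs$effect - 1.96 * obs$se)
  obs$ci_hi <- exp(obs$effect + 1.96 * obs$se)
  readr::write_tsv(scan$per_study,
                   sprintf("results/assoc_%s_per_study.tsv", outcome))
  readr::write_tsv(obs, sprintf("results/assoc_%s_meta.tsv", outcome))
  top <- obs[order(obs$p), ][1:3, ]
  cat("\n==", outcome, "==\n")
  cat(sprintf("%d SNPs tested; %d below the Bonferroni threshold %.3g\n",
              nrow(obs), sum(obs$p < thr, na.rm = TRUE), thr))
  cat("top SNPs:\n")
  print(as.data.frame(top[, c("rsid", "or", "ci_lo", "ci_hi", "p", "k")]),
        row.names = FALSE, digits = 3)
}

cat("\nUnder the global-null generator no SNP is expected below the",
    "threshold; planted effects (see provenance.json) surface here.\n")
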