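#!/usr/bin/env Rscript
# Relative telomere length from the qPCR plates (per-plate standard curves,
# triplicates averaged on the quantity scale), its relationship with
# demographic characteristics among unaffected subjects, and the
# TL-melanoma odds ratio meta-analysed across the contributing studies.

library(telosnp)

dataset <- read_genotypes("results/data/genotypes_clean.tsv",
                          "results/data/snp_annotation_clean.tsv")
plates <- read_plates("results/data/qpcr_plates.csv")

measures <- ts_ratio(plates$t_plate, plates$s_plate)
readr::write_tsv(measures, "results/telomere_measures.tsv")
cat("T/S ratios for", nrow(measures), "samples;",
    sum(measures$flag != "ok"), "flagged wells\n")
curve <- fit_standard_curve(plates$t_plate)
cat(sprintf("T-plate standard curve: slope %.3f per log2(ng), R2 %.4f\n",
            curve$slope, curve$r2))

cat("\nln(T/S) by age band among unaffected subjects:\n")
age <- tl_covariate_regression(measures, dataset, "age")
print(as.data.frame(age$categories), row.names = FALSE, digits = 3)
cat("trend p:", format(age$trend_p, digits = 3), "\n")

for (cv in c("sex", "nevus_count", "dysplastic_nevi")) {
  res <- tl_covariate_regression(measures, dataset, cv)
  cat(sprintf("%-16s trend p = %.3g\n", cv, res$trend_p))
}

cat("\nTL and melanoma risk (per unit ln(T/S), age/sex adjusted):\n")
mel <- tl_melanoma_or(measures, dataset)
print(as.data.frame(mel$per_study), row.names = FALSE, digits = 3)
with(mel$meta, cat(sprintf(
  "pooled OR %.2f (95%% CI %.2f-%.2f), p = %.2g, tau2 = %.3g\n",
  exp(effect), exp(ci_lo), exp(ci_hi), p, tau2)))
readr::write_tsv(mel$per_study, "results/telomere_melanoma_per_study.tsv")
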