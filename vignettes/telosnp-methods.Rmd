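---
title: "Methods: multi-study telomere-gene association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-study telomere-gene association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Candidate-gene studies of telomere biology and melanoma ask whether common
variants in genes that maintain or protect telomeres are associated with
melanoma risk, with the presence of dysplastic nevi, or with nevus count —
phenotypes on the causal path to melanoma. The analysis has a fixed shape:
tagSNPs in a few dozen gene regions are genotyped in several studies (here,
three case-control studies and one family study), each SNP is tested per
study with a design-appropriate model, per-study estimates are pooled by
random-effects meta-analysis, and SNP-level p-values are then combined into
gene-region, functional-group and overall p-values with the adaptive rank
truncated product (ARTP) statistic, whose null distribution comes from
permutation. `telosnp` implements that pipeline end to end, together with
qPCR relative telomere length (the T/S ratio) and a synthetic multi-study
generator that makes every stage testable without access to subject-level
data.

## Genotype quality control

SNPs pass through a fixed exclusion cascade — assay failure, monoallelic,
call rate below 90%, duplicate concordance below 95%, not genotypeable,
Hardy-Weinberg disequilibrium among unaffected subjects, control MAF below
1% — and each excluded SNP is counted once under the first check it fails,
which is what makes per-reason totals well defined and additive. The
Hardy-Weinberg test is the exact conditional test: given the allele counts,
all heterozygote counts of matching parity are enumerated, each
configuration's conditional probability is computed in closed form, and the
p-value sums the probabilities no larger than the observed configuration's.
The HWE significance level is a configuration value (default `0.05/20809`,
an array-wide Bonferroni divisor) rather than a constant derived from the
analysis set, because the divisor belongs to the genotyping platform, not
to the study. MAF and HWE are computed in unaffected subjects pooled across
studies; the concordance filter consumes an optional duplicate-sample
table and is skipped (with a message) when none exists. Pairwise LD is the
squared Pearson correlation of dosages (composite LD), which needs no
phasing and is undefined — reported as `NA`, never 0 — when a SNP is
monomorphic in the complete pairs.

## Per-study association models

All binary outcomes use additive-trend logistic regression: minor-allele
dosage 0/1/2 entered linearly, adjusted for age (continuous) and sex, with
Wald ("P-trend") p-values. When any genotype class holds fewer than 5
subjects in the analysis sample — the margin pooled over cases and
non-cases, after complete-case exclusion — the model drops to dominant
coding (carriers vs non-carriers) and the result is labelled accordingly;
the rule depends only on the genotype margin, so the same model is chosen
for the observed data and every permutation replicate. Separation is
detected by divergence of the Newton iterations and flagged as
non-convergence; such study-SNP pairs are dropped from the meta-analysis
rather than imputed.

The family study uses the exact conditional likelihood, conditioning on
family: within a family with `d` affected members among `n`, the observed
case set is compared against all `choose(n, d)` candidate subsets. Families
are small, so full subset enumeration is cheap (a guard refuses strata
beyond 10^6 subsets), and the likelihood, score and information are exact
sums over the enumerated subsets — the same quantities a brute-force oracle
computes, which is how the tests verify them.

Nevus count (unaffected subjects only) uses Poisson regression with an
age-by-genotype interaction and a cluster-robust sandwich variance with
families as clusters (singletons for unrelated subjects; CR0 with a
G/(G-1) factor, matching `sandwich::vcovCL` defaults). Because the model
contains the interaction, a single reported IRR needs a reference age: age
is centred at the per-study mean, so the genotype coefficient is the
per-allele rate ratio at mean age. This is a reporting convention of this
package, chosen to make the single-number IRR well defined; it is not
claimed to reproduce any particular publication's convention.

The nevus score used for sensitivity adjustment is a one-factor score of
nevus count and dysplastic-nevi status. With exactly two standardised
indicators the one-factor solution is the first principal component,
`(z1 + z2)/sqrt(2)`, computed in closed form (`factanal` cannot identify a
one-factor model from two indicators). Quartiles use lower-closed
intervals, the last closed.

The compiled Newton solvers in `src/` exist because the permutation null
refits every per-study SNP model for every permutation — millions of fits
at production settings — where `glm` and `survival::clogit` carry too much
per-call overhead. Those established implementations are instead the
independent oracles in the test suite: the compiled fitters must match
`glm`, `survival::clogit(method = "exact")` and `sandwich::vcovCL` to
numerical precision on random datasets.

## Meta-analysis

Per-study log-effects are pooled with the DerSimonian-Laird moment
estimator: fixed inverse-variance weights give Q, the between-study
variance is `max(0, (Q - (k-1))/C)`, and the pooled effect re-weights by
`1/(SE^2 + tau2)`. No Knapp-Hartung adjustment is applied; with one study
the input passes through unchanged, and the fixed-effects variant simply
forces `tau2 = 0`. Conditional (family) and unconditional (case-control)
estimates are treated as exchangeable (effect, SE) pairs. The estimator is
reimplemented — it is a four-line closed form — because the permutation
path needs it vectorised over B-by-L matrices; `metafor::rma(method="DL")`
is the cross-check in the tests.

## ARTP: gene, group and overall p-values

For a set of L SNPs with p-values `p_(1) <= ... <= p_(L)`, the rank
truncated product statistic at truncation point j is
`W_j = sum_{i<=j} log p_(i)`. The adaptive version computes, for each
candidate j in the ladder J = {1, ..., min(L, 10)} (configurable), the
permutation p-value `s_j = (1 + #{b: W_j^(b) <= W_j}) / (B+1)`, takes
`min_j s_j` as the adaptive statistic, and obtains its p-value from the
same replicates with a single-layer adjustment: each replicate's own
`min_j s_j^(b)` is computed by ranking it among all others (observed
included), and the reported p-value is the fraction of replicate minima at
or below the observed minimum. Ties are counted conservatively (`<=`), and
the `+1` convention keeps every p-value in `[1/(B+1), 1]`.

One permutation null is shared by every gene, group and overall test for an
outcome: outcome labels are permuted within study — within family for the
family study, preserving each family's number of affected members — with
covariates kept attached to samples, and all per-study models are refit and
re-meta-analysed per replicate. Sharing the null preserves the LD between
SNPs, which is exactly what the truncated product must respect for its
null distribution to be valid. When a family member's genotype is missing
for some SNP, the permuted case set for that SNP is drawn among the
non-missing members with the case count preserved; with complete genotypes
(the generator default) this is identical to within-family label
permutation. For the nevus-count outcome the counts themselves are permuted
within study and the cluster-robust Poisson fits are rerun; permuting
across families does discard the family correlation of counts under the
null, a standard and slightly conservative simplification.

A SNP annotated to two overlapping gene regions enters both gene tests but
each functional-group pool and the overall pool once. Failed fits
(separation in a permutation replicate) enter the set statistics as p = 1,
which cannot anti-conservatively inflate significance. Set tables are
ordered from most to least significant; because adaptive p-values are
floored at `1/(B+1)`, ties at the floor are broken by the per-candidate
minimum `s_j` and then by the smallest observed per-SNP p-value in the set
— a deterministic rule that keeps "ranks first" well defined in the
planted-signal analyses.

B defaults to 10,000 in `permutation_null()`, the production setting; the
analysis drivers use B = 2,000 and the test suite B = 200-500, which only
coarsens the attainable p-value floor.

## qPCR relative telomere length

Each reaction (telomere T, single-copy gene S) is run on its own plate in
triplicate, with a six-point 1:2 dilution series (40 down to 1.25 ng) of a
pooled standard on every plate. A least-squares fit of Ct on log2(ng)
defines the per-plate standard curve (slope -1 at perfect efficiency);
every well's Ct maps back to a nanogram quantity through its own plate's
curve, replicates deviating more than 1.0 Ct from the triplicate median are
dropped and flagged (standard qPCR practice; the threshold is a package
choice), the surviving replicates are averaged on the quantity scale —
averaging Ct would bias the ratio because the Ct-to-quantity map is convex
— and T/S is the ratio of mean quantities. Because both plates share the
pooled-standard DNA, the ratio is already normalised to that pool; an
explicit reference sample can rescale it to T/S = 1 if desired. No
inter-plate calibration beyond the shared standards is attempted.

Downstream, ln(T/S) is the analysis scale: linear models of ln(T/S) on a
characteristic plus age and study give exponentiated coefficients that are
geometric-mean ratios, and TL-melanoma associations reuse the per-study
logistic machinery (conditional in the family study) with ln(T/S) as a
continuous exposure, pooled by the same random-effects meta-analysis.

## The synthetic generator: what it emulates, and what it does not

The generator's defaults are the study conditions: per-study quotas
227/173, 264/165, 207/207 (case-control) and 62 families — 51 of five
members and 11 of six, 28 with one affected and 34 with two, i.e. 96
affected and 225 unaffected members — giving 770 unaffected subjects in
total; 39 gene regions carrying 476 tagSNPs (12-13 per gene, nine SNPs
annotated to two regions) in five functional groups; MAFs uniform on
(0.05, 0.5); and ages 17-80. The printed per-study case counts sum to 794,
so that is the default bundle's case total.

Genotypes come from a Gaussian copula: a latent AR(1) process with
correlation `ld_block_rho` (default 0.5) within each gene, thresholded to
0/1/2 at Hardy-Weinberg cut points for each SNP's MAF. This controls
adjacent-SNP r² monotonically and keeps marginals in HWE, which is all the
pipeline's assumptions require; it is not a realistic human LD map, and
there is no phasing, imputation or population structure. Families are two
founders plus offspring; offspring genotypes follow Mendelian transmission
independently per SNP (consistent pedigrees, but no transmitted
haplotypes). Melanoma status follows a logistic model (baseline prevalence
0.3 — a sampling-efficiency parameter to which case-control odds ratios
are invariant, not an epidemiological claim), nevus counts a Poisson model
with a mild negative age slope, dysplastic nevi a logistic model; each
accepts per-SNP causal effects by rsID. Case-control studies are assembled
by rejection sampling to quota; in the family study the affected set of
the configured size is drawn per family with probability proportional to
`exp(sum of member risk scores)`, the ascertainment model under which the
conditional-logistic analysis is correctly specified. ln(T/S) declines by
0.005 per year of age (within the range reported for adult leukocyte DNA)
around a residual SD of 0.15, and plate Ct values add Gaussian noise
(default SD 0.15) to a perfect-efficiency amplification model.

A passing pipeline on these bundles demonstrates internal validity — exact
arithmetic, correct conditioning, calibrated permutation nulls, unbiased
recovery of planted effects — under clean LD and correctly specified
outcome models. It does not demonstrate robustness to genotyping artefacts,
population stratification, overdispersed counts, or real haplotype
structure, none of which the generator produces.

## Numerical choices and degenerate inputs

* Newton iterations stop at a gradient and step of 1e-10/1e-8; divergence
  (|beta| > 25) or a singular information matrix is reported as
  non-convergence, never as an estimate.
* The exact HWE test includes ties (probabilities equal to the observed
  configuration's, within a 1e-12 relative tolerance) in the p-value.
* `pairwise_r2` on a zero-variance column returns `NA`; constant genotypes
  raise degenerate-input errors in the fitters; monomorphic SNPs get HWE
  p = 1 and fall to the monoallelic/MAF filters.
* Permutation p-values use the +1 correction throughout and can never be 0.
* Quartile ties on the nevus score go to the upper interval (lower-closed
  intervals).

## Problem sizes in the tests and acceptance script

Null calibration of the gene-level ARTP type-I error uses four studies
(three case-control studies of 100/100 and 25 five-member families with
two affected each), 40 genes of 5 SNPs and B = 500, pooling gene p-values
across 10 independently seeded bundles (400 gene tests); calibration is a
property of the null distribution, not of sample size, so the scaled-down
studies measure the same quantity as the full design. Planted-effect
recovery uses a per-allele log-OR of 0.41 (CI coverage over 100
replicates) and a log-OR of 0.6 for gene ranking (50 replicates at
B = 200); with MAFs drawn from the default (0.05, 0.5) range the rank
experiment's power varies with the causal SNP's drawn MAF, which is why its
recovery rate sits near, not far above, 90%. The analysis drivers run the
full 476-SNP design at B = 2,000.
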