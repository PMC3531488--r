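#' @importFrom Rcpp sourceCpp
#' @useDynLib telosnp, .registration = TRUE
NULL

assoc_result <- function(rsid, study, outcome, model, effect, se, n_used,
                         converged) {
  tibble::tibble(rsid = rsid, study = study, outcome = outcome, model = model,
                 effect = effect, se = se, p = wald_p(effect, se),
                 n_used = n_used, converged = converged)
}

outcome_frame <- function(dataset, outcome, study) {
  s <- dataset$samples
  keep <- s$study == study
  if (outcome == "melanoma") {
    y <- as.numeric(s$status == "case")
  } else if (outcome == "dysplastic_nevi") {
    keep <- keep & s$status == "unaffected" & !is.na(s$dysplastic_nevi)
    y <- as.numeric(s$dysplastic_nevi == "present")
  } else if (outcome == "nevus_count") {
    keep <- keep & s$status == "unaffected" & !is.na(s$nevus_count)
    y <- as.numeric(s$nevus_count)
  } else stop("unknown outcome: ", outcome)
  idx <- which(keep)
  list(idx = idx, y = y[idx], samples = s[idx, , drop = FALSE])
}

covariate_matrix <- function(samples, covariates) {
  cols <- lapply(covariates, function(cv) {
    switch(cv,
           age = as.numeric(samples$age),
           sex = as.numeric(samples$sex == "female"),
           as.numeric(samples[[cv]]))
  })
  if (!length(cols)) return(matrix(numeric(0), nrow = nrow(samples), ncol = 0))
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

#' Additive-trend logistic regression for one SNP in one study
#'
#' Fits a maximum-likelihood logistic model of a binary outcome on the
#' minor-allele dosage (0/1/2 trend coding) plus covariates, complete-case.
#' When any genotype class holds fewer than `fallback_threshold` subjects in
#' the analysis sample, carriers are collapsed against non-carriers and the
#' result is labelled `model = "dominant"`. Non-finite ML estimates
#' (separation) are flagged as non-converged with no effect reported.
#'
#' @param dataset A [genotype_dataset()].
#' @param rsid SNP to test.
#' @param outcome `"melanoma"` (case vs unaffected) or `"dysplastic_nevi"`
#'   (among unaffected subjects).
#' @param study Study identifier; defaults to the only study present.
#' @param covariates Character vector of adjustment covariates (default age
#'   as continuous plus sex).
#' @param fallback_threshold Minimum per-genotype-class count below which the
#'   dominant model is used.
#' @return One-row association tibble: `rsid`, `study`, `outcome`, `model`,
#'   `effect` (log-OR per coded unit), `se`, `p` (Wald trend), `n_used`,
#'   `converged`.
#' @export
fit_trend_logistic <- function(dataset, rsid, outcome = "melanoma",
                               study = unique(dataset$samples$study),
                               covariates = c("age", "sex"),
                               fallback_threshold = 5L) {
  stopifnot(length(study) == 1)
  fr <- outcome_frame(dataset, outcome, study)
  g <- dataset$genotypes[fr$idx, rsid]
  Xc <- covariate_matrix(fr$samples, covariates)
  cc <- !is.na(g) & stats::complete.cases(Xc)
  g <- g[cc]; y <- fr$y[cc]
  if (length(unique(y)) < 2) stop("outcome has a single level in study ", study)
  if (length(unique(g)) < 2) stop("constant genotype for ", rsid, " in study ", study)
  model <- choose_genotype_model(g, fallback_threshold)
  gc <- code_genotype(g, model)
  if (length(unique(gc)) < 2) stop("constant genotype after dominant collapse")
  X <- cbind(1, gc, Xc[cc, , drop = FALSE])
  fit <- logistic_fit(X, y)
  assoc_result(rsid, study, outcome, model,
               if (fit$converged) fit$beta[2] else NA_real_,
               if (fit$converged) fit$se[2] else NA_real_,
               sum(cc), fit$converged)
}

#' Conditional logistic regression conditioning on family
#'
#' Maximises the exact conditional likelihood: within each family with `d`
#' affected members among `n`, the observed case set is compared against all
#' `choose(n, d)` candidate subsets; families without outcome variation are
#' uninformative and contribute nothing. The Wald SE comes from the observed
#' information. The dominant-model fallback rule matches
#' [fit_trend_logistic()].
#'
#' @inheritParams fit_trend_logistic
#' @return One-row association tibble as in [fit_trend_logistic()].
#' @export
fit_conditional_logistic <- function(dataset, rsid, outcome = "melanoma",
                                     study = unique(dataset$samples$study),
                                     covariates = c("age", "sex"),
                                     fallback_threshold = 5L) {
  stopifnot(length(study) == 1)
  fr <- outcome_frame(dataset, outcome, study)
  g <- dataset$genotypes[fr$idx, rsid]
  Xc <- covariate_matrix(fr$samples, covariates)
  cc <- !is.na(g) & stats::complete.cases(Xc) & !is.na(fr$samples$family_id)
  g <- g[cc]; y <- fr$y[cc]
  fam <- fr$samples$family_id[cc]
  if (length(unique(g)) < 2) stop("constant genotype for ", rsid, " in study ", study)
  model <- choose_genotype_model(g, fallback_threshold)
  gc <- code_genotype(g, model)
  X <- cbind(gc, Xc[cc, , drop = FALSE])
  colnames(X)[1] <- "genotype"
  enum <- clogit_enumerate(X, fam, y)
  if (is.null(enum)) stop("no informative strata in study ", study)
  fit <- cpp_clogit_newton(enum$Xs, enum$starts - 1L, enum$ends - 1L,
                           enum$obs - 1L)
  ok <- fit$converged
  assoc_result(rsid, study, outcome, model,
               if (ok) fit$beta[1] else NA_real_,
               if (ok) sqrt(fit$vcov[1, 1]) else NA_real_,
               sum(cc), ok)
}

#' Poisson model for nevus count with cluster-robust variance
#'
#' Log-linear Poisson fit of nevus count on the minor-allele dosage, age,
#' sex, and an age-by-genotype interaction, in unaffected subjects of one
#' study. Age is centred at the study mean before forming the interaction,
#' so the reported genotype IRR is the per-allele rate ratio at mean age.
#' Standard errors use a cluster-robust sandwich estimator with families as
#' clusters (unrelated subjects are singleton clusters).
#'
#' @inheritParams fit_trend_logistic
#' @param interaction Include the age-by-genotype product term.
#' @return One-row association tibble (`effect` = log-IRR, robust `se`).
#' @export
fit_nevus_poisson <- function(dataset, rsid,
                              study = unique(dataset$samples$study),
                              covariates = c("age", "sex"),
                              interaction = TRUE,
                              fallback_threshold = 5L) {
  stopifnot(length(study) == 1)
  fr <- outcome_frame(dataset, "nevus_count", study)
  g <- dataset$genotypes[fr$idx, rsid]
  Xc <- covariate_matrix(fr$samples, covariates)
  cc <- !is.na(g) & stats::complete.cases(Xc)
  g <- g[cc]; y <- fr$y[cc]
  if (sum(cc) < 30) stop("fewer than 30 usable nevus counts in study ", study)
  if (any(y < 0) || any(y != floor(y))) stop("nevus counts must be non-negative integers")
  if (length(unique(g)) < 2) stop("constant genotype for ", rsid, " in study ", study)
  fam <- fr$samples$family_id[cc]
  fam[is.na(fam)] <- paste0(".s", which(is.na(fam)))  # singletons
  model <- choose_genotype_model(g, fallback_threshold)
  gc <- code_genotype(g, model)
  Xc <- Xc[cc, , drop = FALSE]
  if ("age" %in% colnames(Xc)) {
    Xc[, "age"] <- Xc[, "age"] - mean(Xc[, "age"])
  }
  X <- cbind(1, gc, Xc)
  if (interaction && "age" %in% colnames(Xc)) {
    X <- cbind(X, gc * Xc[, "age"])
  }
  fit <- poisson_fit(X, y, fam)
  assoc_result(rsid, study, "nevus_count", model,
               if (fit$converged) fit$beta[2] else NA_real_,
               if (fit$converged) fit$se[2] else NA_real_,
               sum(cc), fit$converged)
}

#' SNP-by-phenotype interaction on melanoma risk
#'
#' Adds a product term between the SNP dosage and a nevus phenotype
#' (presence of dysplastic nevi, or nevus count) to the per-study melanoma
#' logistic model and reports the Wald p-value of the product term.
#'
#' @inheritParams fit_trend_logistic
#' @param modifier `"dysplastic_nevi"` or `"nevus_count"`.
#' @return One-row tibble: `rsid`, `study`, `modifier`, `interaction_effect`,
#'   `se`, `p`, `n_used`, `converged`.
#' @export
fit_interaction <- function(dataset, rsid, modifier = "dysplastic_nevi",
                            study = unique(dataset$samples$study),
                            covariates = c("age", "sex"),
                            fallback_threshold = 5L) {
  stopifnot(length(study) == 1,
            modifier %in% c("dysplastic_nevi", "nevus_count"))
  fr <- outcome_frame(dataset, "melanoma", study)
  g <- dataset$genotypes[fr$idx, rsid]
  m <- if (modifier == "dysplastic_nevi") {
    as.numeric(fr$samples$dysplastic_nevi == "present")
  } else as.numeric(fr$samples$nevus_count)
  Xc <- covariate_matrix(fr$samples, covariates)
  cc <- !is.na(g) & !is.na(m) & stats::complete.cases(Xc)
  if (sum(cc) < 20) stop("modifier missing for too many subjects in study ", study)
  g <- g[cc]; y <- fr$y[cc]; m <- m[cc]
  model <- choose_genotype_model(g, fallback_threshold)
  gc <- code_genotype(g, model)
  X <- cbind(1, gc, m, gc * m, Xc[cc, , drop = FALSE])
  fit <- logistic_fit(X, y)
  tibble::tibble(rsid = rsid, study = study, modifier = modifier,
                 interaction_effect = if (fit$converged) fit$beta[4] else NA_real_,
                 se = if (fit$converged) fit$se[4] else NA_real_,
                 p = wald_p(if (fit$converged) fit$beta[4] else NA_real_,
                            if (fit$converged) fit$se[4] else NA_real_),
                 n_used = sum(cc), converged = fit$converged)
}

#' Nevus score from nevus count and dysplastic-nevi status
#'
#' One-factor score of the two standardised indicators. With exactly two
#' indicators the single-factor solution has equal loadings, so the score is
#' the first principal component, \eqn{(z_{count} + z_{dn})/\sqrt{2}}.
#' Defined only for samples with both indicators non-missing; quartile labels
#' use lower-closed intervals (the last interval is closed) on the pooled
#' non-missing distribution.
#'
#' @param dataset A [genotype_dataset()].
#' @return Tibble `sample_id`, `score`, `quartile`.
#' @export
compute_nevus_score <- function(dataset) {
  s <- dataset$samples
  dn <- as.numeric(s$dysplastic_nevi == "present")
  nc <- as.numeric(s$nevus_count)
  keep <- !is.na(dn) & !is.na(nc)
  if (sum(keep) < 8) stop("need at least 8 samples with both indicators")
  z1 <- scale(nc[keep])[, 1]
  z2 <- scale(dn[keep])[, 1]
  if (any(!is.finite(z1)) || any(!is.finite(z2))) {
    stop("zero variance in a nevus-score indicator")
  }
  score <- (z1 + z2) / sqrt(2)
  qs <- stats::quantile(score, c(0.25, 0.5, 0.75), names = FALSE)
  quartile <- findInterval(score, qs) + 1L
  tibble::tibble(sample_id = s$sample_id[keep], score = score,
                 quartile = quartile)
}

#' Per-study association fit dispatched on study design
#'
#' Case-control studies use unconditional logistic regression
#' ([fit_trend_logistic()]); family studies condition on family
#' ([fit_conditional_logistic()]); the nevus-count outcome uses the Poisson
#' model ([fit_nevus_poisson()]).
#'
#' @inheritParams fit_trend_logistic
#' @return One-row association tibble.
#' @export
fit_study_snp <- function(dataset, rsid, outcome, study,
                          covariates = c("age", "sex"),
                          fallback_threshold = 5L) {
  design <- dataset$samples$design[dataset$samples$study == study][1]
  if (outcome == "nevus_count") {
    fit_nevus_poisson(dataset, rsid, study, covariates,
                      fallback_threshold = fallback_threshold)
  } else if (identical(design, "family")) {
    fit_conditional_logistic(dataset, rsid, outcome, study, covariates,
                             fallback_threshold)
  } else {
    fit_trend_logistic(dataset, rsid, outcome, study, covariates,
                       fallback_threshold)
  }
}

#' Fit one SNP in every eligible study and meta-combine
#'
#' @inheritParams fit_trend_logistic
#' @param method `"random"` (DerSimonian-Laird) or `"fixed"`.
#' @return List with `per_study` (association tibble, one row per study; rows
#'   from failed fits carry `converged = FALSE`) and `meta` (a
#'   [meta_random_effects()] result over the converged studies).
#' @export
snp_meta <- function(dataset, rsid, outcome = "melanoma",
                     covariates = c("age", "sex"), method = "random",
                     fallback_threshold = 5L) {
  studies <- eligible_studies(dataset, outcome)
  rows <- lapply(studies, function(st) {
    tryCatch(fit_study_snp(dataset, rsid, outcome, st, covariates,
                           fallback_threshold),
             error = function(e) assoc_result(rsid, st, outcome, NA_character_,
                                              NA_real_, NA_real_, NA_integer_,
                                              FALSE))
  })
  per_study <- dplyr::bind_rows(rows)
  ok <- per_study$converged & !is.na(per_study$se) & per_study$se > 0
  meta <- if (any(ok)) {
    fn <- if (method == "fixed") meta_fixed_effects else meta_random_effects
    fn(per_study$effect[ok], per_study$se[ok])
  } else NULL
  list(per_study = per_study, meta = meta)
}

eligible_studies <- function(dataset, outcome) {
  s <- dataset$samples
  studies <- unique(s$study)
  keep <- vapply(studies, function(st) {
    fr <- outcome_frame(dataset, outcome, st)
    if (outcome == "nevus_count") return(length(fr$y) >= 30)
    length(unique(fr$y)) == 2
  }, logical(1))
  studies[keep]
}
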