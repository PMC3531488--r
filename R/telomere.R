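#' Fit a qPCR standard curve
#'
#' Least-squares fit of Ct on log2(input DNA quantity) over the plate's
#' dilution-series standards (default 40 down to 1.25 ng in 1:2 steps).
#' With perfect amplification efficiency the slope is -1 per log2(ng).
#'
#' @param plate A plate tibble (one element of a
#'   [simulate_qpcr_plates()] set, or read with [read_plates()]).
#' @return List of class `standard_curve`: `slope`, `intercept`, `r2`, and
#'   `quantity(ct)`, the inverse mapping from Ct to nanogram quantity.
#' @export
fit_standard_curve <- function(plate) {
  std <- plate[plate$type == "standard", ]
  if (length(unique(std$ng)) < 3) {
    stop("need at least 3 distinct standard quantities")
  }
  fit <- stats::lm(ct ~ log2(ng), data = std)
  co <- unname(stats::coef(fit))
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noiseless plates fit exactly
  structure(list(
    slope = co[2], intercept = co[1], r2 = r2,
    quantity = function(ct) 2^((ct - co[1]) / co[2])),
    class = "standard_curve")
}

#' Relative telomere length (T/S ratio) from paired qPCR plates
#'
#' Converts every well's Ct to a nanogram quantity via its own plate's
#' standard curve, drops replicates whose Ct deviates more than
#' `outlier_ct` from the triplicate median (flagged, not fatal), averages
#' the remaining replicates on the quantity scale, and forms the per-sample
#' ratio of mean T to mean S quantity. Because both plates share the pooled
#' standard-curve DNA, the ratio is already normalised to the pooled
#' standard; passing `reference` rescales so that sample's T/S is 1.
#'
#' @param t_plate,s_plate Telomere and single-copy-gene plate tibbles.
#' @param reference Optional sample ID used as the T/S = 1 reference.
#' @param outlier_ct Replicate outlier threshold (Ct units from the median).
#' @param min_r2 Standard-curve R-squared below which a QC flag is raised.
#' @return Tibble: `sample_id`, `t_quantity`, `s_quantity`, `ts_ratio`,
#'   `ln_ts`, `n_t`, `n_s` (replicates used), `flag`.
#' @export
ts_ratio <- function(t_plate, s_plate, reference = NULL, outlier_ct = 1.0,
                     min_r2 = 0.95) {
  curve_t <- fit_standard_curve(t_plate)
  curve_s <- fit_standard_curve(s_plate)
  mean_quantity <- function(plate, curve) {
    smp <- plate[plate$type == "sample", ]
    parts <- split(smp$ct, smp$sample_id)
    rows <- lapply(names(parts), function(id) {
      ct <- parts[[id]]
      keep <- abs(ct - stats::median(ct)) <= outlier_ct
      tibble::tibble(sample_id = id,
                     quantity = mean(curve$quantity(ct[keep])),
                     n_used = sum(keep), dropped = any(!keep))
    })
    dplyr::bind_rows(rows)
  }
  qt <- mean_quantity(t_plate, curve_t)
  qs <- mean_quantity(s_plate, curve_s)
  m <- dplyr::inner_join(qt, qs, by = "sample_id",
                         suffix = c("_t", "_s"))
  ts <- m$quantity_t / m$quantity_s
  if (!is.null(reference)) {
    ref <- ts[match(reference, m$sample_id)]
    if (is.na(ref)) stop("reference sample absent from both plates")
    ts <- ts / ref
  }
  flag <- dplyr::case_when(
    m$n_used_t < 2 | m$n_used_s < 2 ~ "few_replicates",
    curve_t$r2 < min_r2 | curve_s$r2 < min_r2 ~ "poor_curve",
    m$dropped_t | m$dropped_s ~ "replicate_dropped",
    TRUE ~ "ok")
  tibble::tibble(sample_id = m$sample_id, t_quantity = m$quantity_t,
                 s_quantity = m$quantity_s, ts_ratio = ts, ln_ts = log(ts),
                 n_t = m$n_used_t, n_s = m$n_used_s, flag = flag)
}

#' Telomere length versus demographic characteristics
#'
#' Linear model of ln(T/S) on one (categorical or banded) characteristic
#' among unaffected subjects, adjusted for age (continuous) and study.
#' Exponentiated category coefficients are geometric-mean ratios relative to
#' the first category; the trend p-value refits the model with the ordered
#' category index as a single numeric term. When the tested characteristic
#' is age itself, only study is adjusted for.
#'
#' @param measures Output of [ts_ratio()].
#' @param dataset A [genotype_dataset()] supplying covariates.
#' @param covariate One of `"age"`, `"sex"`, `"nevus_count"`,
#'   `"dysplastic_nevi"`, `"chronic_sun"`, `"intermittent_sun"`.
#' @param conf_level Confidence level.
#' @return List: `categories` (tibble `category`, `n`, `gmr`, `ci_lo`,
#'   `ci_hi`; reference row has `gmr = 1`), `trend_p`.
#' @export
tl_covariate_regression <- function(measures, dataset, covariate,
                                    conf_level = 0.95) {
  s <- dataset$samples
  d <- dplyr::inner_join(measures, s, by = "sample_id")
  d <- d[d$status == "unaffected" & is.finite(d$ln_ts), ]
  if (nrow(d) < 10) stop("need at least 10 unaffected samples with TL")
  x <- switch(covariate,
              age = as.character(age_band(d$age)),
              nevus_count = as.character(nevus_band(d$nevus_count)),
              as.character(d[[covariate]]))
  lvl_order <- list(
    age = c("<30", "30-39", "40-49", "50-59", ">=60"),
    sex = c("male", "female"),
    nevus_count = c("<10", "10-50", ">50"),
    dysplastic_nevi = c("absent", "present"),
    chronic_sun = c("no", "yes"),
    intermittent_sun = c("very_little", "some", "high"))
  lv <- intersect(lvl_order[[covariate]] %||% sort(unique(x)), unique(x))
  keep <- !is.na(x)
  d <- d[keep, ]; x <- factor(x[keep], levels = lv)
  if (nlevels(droplevels(x)) < 2) stop("constant covariate")
  df <- data.frame(y = d$ln_ts, x = x, age = d$age,
                   study = factor(d$study))
  adj <- if (covariate == "age") "study" else c("age", "study")
  adj <- adj[vapply(adj, function(a) length(unique(df[[a]])) > 1, logical(1))]
  form <- stats::reformulate(c("x", adj), response = "y")
  fit <- stats::lm(form, data = df)
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- paste0("x", lv[-1])
  est <- unname(sm[rows, "Estimate"]); se <- unname(sm[rows, "Std. Error"])
  categories <- tibble::tibble(
    category = lv,
    n = as.integer(table(x)[lv]),
    gmr = c(1, exp(est)),
    ci_lo = c(NA, exp(est - z * se)),
    ci_hi = c(NA, exp(est + z * se)))
  df$xnum <- as.numeric(x)
  tfit <- stats::lm(stats::reformulate(c("xnum", adj), response = "y"),
                    data = df)
  tsm <- summary(tfit)$coefficients
  list(categories = categories,
       trend_p = tsm["xnum", "Pr(>|t|)"])
}

#' Telomere length and melanoma risk, meta-analysed across studies
#'
#' Per study, ln(T/S) enters as a continuous exposure in a logistic model of
#' case status adjusted for age and sex — unconditional in case-control
#' studies, conditional on family in family studies — and the per-study
#' log-ORs are pooled by random-effects meta-analysis.
#'
#' @param measures Output of [ts_ratio()].
#' @param dataset A [genotype_dataset()].
#' @param covariates Adjustment covariates.
#' @return List with `per_study` (tibble) and `meta` (a
#'   [meta_random_effects()] result).
#' @export
tl_melanoma_or <- function(measures, dataset, covariates = c("age", "sex")) {
  s <- dataset$samples
  d <- dplyr::inner_join(measures, s, by = "sample_id")
  d <- d[is.finite(d$ln_ts), ]
  rows <- list()
  for (st in unique(d$study)) {
    ds <- d[d$study == st, ]
    if (length(unique(ds$status)) < 2) next
    y <- as.numeric(ds$status == "case")
    Xc <- covariate_matrix(ds, covariates)
    if (ds$design[1] == "family") {
      X <- cbind(ds$ln_ts, Xc)
      fit <- tryCatch(clogit_fit(X, ds$family_id, y),
                      error = function(e) NULL)
      if (is.null(fit)) next
      eff <- if (fit$converged) fit$beta[1] else NA_real_
      se <- if (fit$converged) fit$se[1] else NA_real_
      conv <- fit$converged
    } else {
      X <- cbind(1, ds$ln_ts, Xc)
      fit <- logistic_fit(X, y)
      eff <- if (fit$converged) fit$beta[2] else NA_real_
      se <- if (fit$converged) fit$se[2] else NA_real_
      conv <- fit$converged
    }
    rows[[st]] <- tibble::tibble(study = st, effect = eff, se = se,
                                 n_used = nrow(ds), converged = conv)
  }
  per_study <- dplyr::bind_rows(rows)
  ok <- per_study$converged & is.finite(per_study$se) & per_study$se > 0
  if (!any(ok)) stop("telomere length present for both cases and unaffected in no study")
  list(per_study = per_study,
       meta = meta_random_effects(per_study$effect[ok], per_study$se[ok]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
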