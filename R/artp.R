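#' Rank truncated product statistic
#'
#' \eqn{W_j = \sum_{i \le j} \ln p_{(i)}}: the log of the product of the `j`
#' smallest p-values in a set. Smaller values are more significant.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @param j Truncation point, `1 <= j <= length(pvalues)`.
#' @return The statistic `W_j`.
#' @export
rtp_statistic <- function(pvalues, j) {
  if (!length(pvalues)) stop("empty p-value list")
  if (any(pvalues <= 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]")
  }
  if (j < 1 || j > length(pvalues)) stop("truncation point out of range")
  sum(log(sort(pvalues))[seq_len(j)])
}

default_candidates <- function(L) seq_len(min(L, 10L))

# W matrix for one SNP set: rows = replicates (observed first), columns =
# candidate truncation points. NA p-values (failed fits) are treated as 1.
rtp_w_matrix <- function(P, candidates) {
  P[is.na(P)] <- 1
  lp <- log(pmin(pmax(P, 1e-300), 1))
  W <- apply(lp, 1, function(r) cumsum(sort(r))[candidates])
  if (length(candidates) == 1L) matrix(W, ncol = 1L) else t(W)
}

#' Adaptive rank truncated product p-value for a SNP set
#'
#' Combines per-SNP p-values over candidate truncation points with a shared
#' permutation null and a single-layer multiplicity adjustment: for each
#' candidate `j` the observed \eqn{W_j} is ranked within the permutation
#' replicates, giving \eqn{s_j = (1 + \#\{b: W_j^{(b)} \le W_j\})/(B+1)};
#' the adaptive statistic is \eqn{\min_j s_j}, and its p-value is obtained by
#' ranking each replicate's own \eqn{\min_j s_j^{(b)}} (computed by treating
#' that replicate as observed among the rest) in the same pooled set, so no
#' second permutation layer is needed. Ties are counted conservatively.
#'
#' @param observed_p Named vector of observed per-SNP p-values.
#' @param perm_p B-by-L matrix of per-SNP p-values under permutation
#'   (columns named by rsID), e.g. from [permutation_null()].
#' @param snps rsIDs forming the set; default all columns.
#' @param candidates Candidate truncation points; default `1:min(L, 10)`.
#' @param set_id Label carried into the result.
#' @return An `artp_result` list: `set`, `n_snps`, `candidates`, `w_obs`,
#'   `s_j` (per-candidate permutation p-values), `min_sj`, `best_j`,
#'   `p` (the adaptive p-value, in `[1/(B+1), 1]`), and `B`.
#' @export
artp_pvalue <- function(observed_p, perm_p, snps = NULL, candidates = NULL,
                        set_id = NA_character_) {
  if (is.null(snps)) snps <- colnames(perm_p)
  if (!length(snps)) stop("set has zero mapped SNPs")
  miss <- setdiff(snps, intersect(names(observed_p), colnames(perm_p)))
  if (length(miss)) stop("SNPs absent from p-value matrices: ",
                         paste(miss, collapse = ", "))
  B <- nrow(perm_p)
  if (B < 1) stop("need at least one permutation replicate")
  J <- if (is.null(candidates)) default_candidates(length(snps)) else candidates
  if (any(J < 1 | J > length(snps))) stop("candidate truncation points out of range")
  P <- rbind(observed_p[snps], perm_p[, snps, drop = FALSE])
  W <- rtp_w_matrix(P, J)
  s <- apply(W, 2, rank, ties.method = "max") / (B + 1)
  if (is.null(dim(s))) s <- matrix(s, ncol = length(J))
  min_s <- apply(s, 1, min)
  structure(list(set = set_id, n_snps = length(snps), candidates = J,
                 w_obs = W[1, ], s_j = s[1, ],
                 min_sj = min_s[1], best_j = J[which.min(s[1, ])],
                 p = sum(min_s <= min_s[1]) / (B + 1), B = B),
            class = "artp_result")
}

#' @export
print.artp_result <- function(x, ...) {
  cat("<artp_result> set ", x$set, ": ", x$n_snps, " SNPs, B = ", x$B,
      "\n  adaptive p = ", format(x$p), " (best truncation j = ", x$best_j,
      ")\n", sep = "")
  invisible(x)
}

#' Shared permutation null for SNP-level meta-analytic p-values
#'
#' For each of `B` permutations the outcome labels are permuted within study
#' (and within family for family-design studies, preserving the number of
#' affected members per family), every per-study SNP model is refit with the
#' same machinery as the observed analysis, and the per-study estimates are
#' re-combined by random-effects meta-analysis. One matrix of SNP-level
#' p-values serves every gene, functional-group and overall test, preserving
#' the LD between SNPs under the null. For the nevus-count outcome the
#' counts are permuted within study and the cluster-robust Poisson models
#' are refit.
#'
#' @param dataset A post-QC [genotype_dataset()].
#' @param outcome `"melanoma"`, `"dysplastic_nevi"` or `"nevus_count"`.
#' @param B Number of permutations (`B = 0` computes the observed scan only).
#' @param seed Integer seed making the permutation stream reproducible.
#' @param covariates Adjustment covariates for every model.
#' @param fallback_threshold Dominant-fallback rule threshold.
#' @return List of class `perm_null`: `observed` (tibble of SNP-level meta
#'   results: `rsid`, `effect`, `se`, `p`, `k`, `Q`, `tau2`), `perm_p`
#'   (B-by-L matrix of SNP-level p-values), `per_study` (per-study observed
#'   fits), plus `outcome`, `B`, `seed`.
#' @export
permutation_null <- function(dataset, outcome = "melanoma", B = 10000L,
                             seed = 1L, covariates = c("age", "sex"),
                             fallback_threshold = 5L) {
  if (B < 0) stop("B must be non-negative")
  set.seed(seed)
  rs <- dataset$snps$rsid
  L <- length(rs)
  studies <- eligible_studies(dataset, outcome)
  if (!length(studies)) stop("no study supports outcome ", outcome)
  beta_list <- se_list <- list()
  per_study <- list()

  for (st in studies) {
    fr <- outcome_frame(dataset, outcome, st)
    design <- fr$samples$design[1]
    Xc <- covariate_matrix(fr$samples, covariates)
    n <- length(fr$y)
    bmat <- matrix(NA_real_, B + 1L, L)
    smat <- matrix(NA_real_, B + 1L, L)
    models <- rep(NA_character_, L)
    ns <- rep(NA_integer_, L)

    if (outcome == "nevus_count") {
      fam <- fr$samples$family_id
      fam[is.na(fam)] <- paste0(".s", which(is.na(fam)))
      Y <- cbind(fr$y, if (B > 0)
        vapply(seq_len(B), function(b) fr$y[sample.int(n)], numeric(n)))
      agec <- if ("age" %in% colnames(Xc)) Xc[, "age"] - mean(Xc[, "age"]) else NULL
      Xb <- Xc
      if (!is.null(agec)) Xb[, "age"] <- agec
      for (l in seq_len(L)) {
        g <- dataset$genotypes[fr$idx, rs[l]]
        cc <- !is.na(g) & stats::complete.cases(Xc)
        gl <- g[cc]
        if (sum(cc) < 30 || length(unique(gl)) < 2) next
        models[l] <- choose_genotype_model(gl, fallback_threshold)
        gc_ <- code_genotype(gl, models[l])
        X <- cbind(1, gc_, Xb[cc, , drop = FALSE])
        if (!is.null(agec)) X <- cbind(X, gc_ * agec[cc])
        cl <- as.integer(factor(fam[cc])) - 1L
        out <- cpp_poisson_perm(X, Y[cc, , drop = FALSE], cl, 2L)
        bmat[, l] <- out$beta; smat[, l] <- out$se; ns[l] <- sum(cc)
      }
    } else if (design == "family") {
      fam <- fr$samples$family_id
      u <- if (B > 0) matrix(stats::runif(length(unique(fam)) * B), ncol = B,
                             dimnames = list(sort(unique(fam)), NULL)) else NULL
      for (l in seq_len(L)) {
        g <- dataset$genotypes[fr$idx, rs[l]]
        cc <- !is.na(g) & stats::complete.cases(Xc)
        gl <- g[cc]
        if (length(unique(gl)) < 2) next
        models[l] <- choose_genotype_model(gl, fallback_threshold)
        gc_ <- code_genotype(gl, models[l])
        X <- cbind(gc_, Xc[cc, , drop = FALSE])
        enum <- clogit_enumerate(X, fam[cc], fr$y[cc])
        if (is.null(enum)) next
        S <- length(enum$starts)
        sizes <- enum$ends - enum$starts + 1L
        ObsMat <- matrix(0L, S, B + 1L)
        ObsMat[, 1] <- enum$obs - 1L
        if (B > 0) {
          us <- u[enum$keys, , drop = FALSE]
          ObsMat[, -1] <- (enum$starts - 1L) + floor(us * sizes)
        }
        out <- cpp_clogit_perm(enum$Xs, enum$starts - 1L, enum$ends - 1L,
                               ObsMat, 1L)
        bmat[, l] <- out$beta; smat[, l] <- out$se; ns[l] <- sum(cc)
      }
    } else {
      Y <- cbind(fr$y, if (B > 0)
        vapply(seq_len(B), function(b) fr$y[sample.int(n)], numeric(n)))
      for (l in seq_len(L)) {
        g <- dataset$genotypes[fr$idx, rs[l]]
        cc <- !is.na(g) & stats::complete.cases(Xc)
        gl <- g[cc]
        if (length(unique(gl)) < 2) next
        models[l] <- choose_genotype_model(gl, fallback_threshold)
        gc_ <- code_genotype(gl, models[l])
        X <- cbind(1, gc_, Xc[cc, , drop = FALSE])
        out <- cpp_logistic_perm(X, Y[cc, , drop = FALSE], 2L)
        bmat[, l] <- out$beta; smat[, l] <- out$se; ns[l] <- sum(cc)
      }
    }
    beta_list[[st]] <- bmat
    se_list[[st]] <- smat
    per_study[[st]] <- assoc_result(rs, st, outcome, models,
                                    bmat[1, ], smat[1, ], ns,
                                    is.finite(bmat[1, ]))
  }

  S <- length(studies)
  bigb <- do.call(rbind, lapply(beta_list, as.vector))
  bigs <- do.call(rbind, lapply(se_list, as.vector))
  mm <- meta_dl_matrix(matrix(bigb, nrow = S), matrix(bigs, nrow = S))
  pmat <- matrix(mm$p, nrow = B + 1L, ncol = L, dimnames = list(NULL, rs))
  observed <- tibble::tibble(
    rsid = rs,
    effect = matrix(mm$effect, nrow = B + 1L)[1, ],
    se = matrix(mm$se, nrow = B + 1L)[1, ],
    p = unname(pmat[1, ]),
    k = matrix(mm$k, nrow = B + 1L)[1, ],
    Q = matrix(mm$Q, nrow = B + 1L)[1, ],
    tau2 = matrix(mm$tau2, nrow = B + 1L)[1, ])
  structure(list(observed = observed,
                 perm_p = pmat[-1, , drop = FALSE],
                 per_study = dplyr::bind_rows(per_study),
                 outcome = outcome, B = B, seed = seed),
            class = "perm_null")
}

#' Gene-, group- and overall-level ARTP tables
#'
#' Applies [artp_pvalue()] to every gene region, every functional group and
#' the overall SNP set, all against the same permutation null. A SNP mapped
#' to two gene regions enters both gene tests but each group/overall pool
#' once. Tables are ordered from most to least significant; ties at the
#' permutation floor are broken by the per-candidate minimum `s_j`, then by
#' the smallest observed per-SNP p-value in the set.
#'
#' @param observed_p Named vector of observed SNP-level p-values.
#' @param perm_p Permutation p-value matrix (columns named by rsID).
#' @param map Set map from [snp_set_map()].
#' @param candidates Candidate truncation points (default `1:min(L, 10)` per
#'   set).
#' @return Tibble: `level` (gene/group/overall), `set`, `n_snps`, `best_j`,
#'   `p`.
#' @export
combine_levels <- function(observed_p, perm_p, map, candidates = NULL) {
  one_level <- function(sets, level) {
    rows <- lapply(names(sets), function(nm) {
      snps <- intersect(sets[[nm]], names(observed_p))
      if (!length(snps)) stop("set ", nm, " has zero mapped SNPs")
      res <- artp_pvalue(observed_p, perm_p, snps, candidates, nm)
      tibble::tibble(level = level, set = nm, n_snps = res$n_snps,
                     best_j = res$best_j, p = res$p, min_sj = res$min_sj,
                     min_obs_p = min(observed_p[snps], na.rm = TRUE))
    })
    out <- dplyr::arrange(dplyr::bind_rows(rows), .data$p, .data$min_sj,
                          .data$min_obs_p)
    dplyr::select(out, -"min_sj", -"min_obs_p")
  }
  dplyr::bind_rows(
    one_level(map$gene, "gene"),
    one_level(map$group, "group"),
    one_level(list(overall = map$overall), "overall"))
}

#' End-to-end ARTP analysis for one outcome
#'
#' Convenience wrapper: builds the shared permutation null with
#' [permutation_null()], then computes the gene/group/overall tables with
#' [combine_levels()].
#'
#' @inheritParams permutation_null
#' @param candidates Candidate truncation points.
#' @return List: `snp` (observed SNP-level meta results), `artp` (the
#'   ordered set-level table), `null` (the `perm_null` object).
#' @export
artp_analysis <- function(dataset, outcome = "melanoma", B = 10000L,
                          seed = 1L, covariates = c("age", "sex"),
                          candidates = NULL) {
  nul <- permutation_null(dataset, outcome, B, seed, covariates)
  obs <- stats::setNames(nul$observed$p, nul$observed$rsid)
  keep <- !is.na(obs)
  map <- snp_set_map(dataset$snps[dataset$snps$rsid %in% names(obs)[keep], ])
  tab <- combine_levels(obs[keep], nul$perm_p[, keep, drop = FALSE], map,
                        candidates)
  list(snp = nul$observed, artp = tab, null = nul)
}
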