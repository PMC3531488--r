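# Thin R wrappers around the compiled Newton fitters, plus the subset
# enumeration that defines the exact conditional-logistic likelihood.

logistic_fit <- function(X, y) {
  fit <- cpp_logistic_newton(X, as.numeric(y))
  list(beta = drop(fit$beta), se = sqrt(pmax(diag(fit$vcov), 0)),
       converged = fit$converged)
}

poisson_fit <- function(X, y, cluster) {
  cl <- as.integer(factor(cluster)) - 1L
  fit <- cpp_poisson_newton(X, as.numeric(y), cl)
  list(beta = drop(fit$beta),
       se = sqrt(pmax(diag(fit$vcov), 0)),
       se_model = sqrt(pmax(diag(fit$vcov_model), 0)),
       converged = fit$converged)
}

# Enumerate, per stratum, every candidate case subset of the observed size.
# Returns the subset covariate-sum matrix and stratum bookkeeping consumed by
# the compiled solver; strata with 0 or all cases are uninformative and are
# dropped. A guard refuses strata whose subset count would explode.
clogit_enumerate <- function(X, strata, case, max_subsets = 1e6) {
  stopifnot(nrow(X) == length(strata), length(case) == length(strata))
  rows <- list(); starts <- integer(); ends <- integer(); obs <- integer()
  keys <- character()
  pos <- 0L
  groups <- split(seq_along(strata), strata)
  for (key in names(groups)) {
    s <- groups[[key]]
    d <- sum(case[s])
    n <- length(s)
    if (d == 0L || d == n) next
    if (choose(n, d) > max_subsets) {
      stop("stratum with ", n, " members and ", d,
           " cases: too many case subsets to enumerate")
    }
    subs <- utils::combn(n, d)
    Xs <- t(apply(subs, 2, function(idx) colSums(X[s[idx], , drop = FALSE])))
    if (d == 1L && nrow(Xs) == 1L) Xs <- t(Xs)  # combn collapses d = 1
    obs_members <- which(case[s] == 1)
    hit <- which(apply(subs, 2, function(idx) setequal(idx, obs_members)))
    rows[[length(rows) + 1L]] <- Xs
    starts <- c(starts, pos + 1L)
    ends <- c(ends, pos + ncol(subs))
    obs <- c(obs, pos + hit)
    keys <- c(keys, key)
    pos <- pos + ncol(subs)
  }
  if (!length(rows)) return(NULL)
  list(Xs = do.call(rbind, rows), starts = starts, ends = ends, obs = obs,
       keys = keys)
}

clogit_fit <- function(X, strata, case) {
  enum <- clogit_enumerate(X, strata, case)
  if (is.null(enum)) stop("no informative strata")
  fit <- cpp_clogit_newton(enum$Xs, enum$starts - 1L, enum$ends - 1L,
                           enum$obs - 1L)
  list(beta = drop(fit$beta), se = sqrt(pmax(diag(fit$vcov), 0)),
       converged = fit$converged, loglik = fit$loglik, enum = enum)
}

# Exact conditional log-likelihood at a fixed beta (used by oracle tests).
clogit_loglik <- function(X, strata, case, beta) {
  enum <- clogit_enumerate(X, strata, case)
  cpp_clogit_loglik(enum$Xs, enum$starts - 1L, enum$ends - 1L,
                    enum$obs - 1L, as.numeric(beta))
}

wald_p <- function(beta, se) {
  ifelse(is.na(beta) | is.na(se) | se <= 0, NA_real_,
         2 * stats::pnorm(-abs(beta / se)))
}

# Dominant-model fallback rule: additive 0/1/2 coding unless any genotype
# class has fewer than 5 subjects in the analysis sample, in which case
# carriers (1 or 2 copies) are collapsed against non-carriers.
choose_genotype_model <- function(g, threshold = 5L) {
  counts <- c(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
              sum(g == 2L, na.rm = TRUE))
  if (any(counts < threshold)) "dominant" else "additive"
}

code_genotype <- function(g, model) {
  if (model == "dominant") as.numeric(g >= 1L) else as.numeric(g)
}
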