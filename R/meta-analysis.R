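#' Random-effects meta-analysis (DerSimonian-Laird)
#'
#' Pools per-study log-scale effects with inverse-variance weights and the
#' DerSimonian-Laird moment estimator of the between-study variance:
#' fixed weights \eqn{w_i = 1/SE_i^2}, \eqn{Q = \sum w_i (b_i - b_F)^2},
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i))},
#' re-weighting \eqn{w_i^* = 1/(SE_i^2 + \tau^2)}. The Wald p-value is
#' two-sided. With a single study the input is returned unchanged.
#'
#' @param effect Numeric vector of per-study log-effects (log-OR / log-IRR).
#' @param se Matching standard errors, all positive.
#' @param conf_level Confidence level for the pooled interval.
#' @return A one-row tibble of class `meta_result`: `k`, `effect`, `se`,
#'   `ci_lo`, `ci_hi`, `p`, `Q`, `tau2`, with the per-study inputs attached
#'   as the `estimates` attribute.
#' @export
#' @examples
#' meta_random_effects(c(0.2, 0.6), c(0.1, 0.2))  # Q = 3.2, tau2 = 0.055
meta_random_effects <- function(effect, se, conf_level = 0.95) {
  check_meta_inputs(effect, se)
  k <- length(effect)
  w <- 1 / se^2
  b_fix <- sum(w * effect) / sum(w)
  Q <- sum(w * (effect - b_fix)^2)
  tau2 <- if (k > 1) {
    C <- sum(w) - sum(w^2) / sum(w)
    max(0, (Q - (k - 1)) / C)
  } else 0
  ws <- 1 / (se^2 + tau2)
  pooled <- sum(ws * effect) / sum(ws)
  pse <- 1 / sqrt(sum(ws))
  meta_result(pooled, pse, k, Q, tau2, effect, se, conf_level)
}

#' Fixed-effects (inverse-variance) meta-analysis
#'
#' Identical to [meta_random_effects()] with the between-study variance
#' forced to zero; the heterogeneity statistic Q is still reported.
#'
#' @inheritParams meta_random_effects
#' @return A one-row `meta_result` tibble with `tau2 = 0`.
#' @export
meta_fixed_effects <- function(effect, se, conf_level = 0.95) {
  check_meta_inputs(effect, se)
  w <- 1 / se^2
  pooled <- sum(w * effect) / sum(w)
  Q <- sum(w * (effect - pooled)^2)
  meta_result(pooled, 1 / sqrt(sum(w)), length(effect), Q, 0,
              effect, se, conf_level)
}

check_meta_inputs <- function(effect, se) {
  if (!length(effect)) stop("no study estimates to combine")
  if (length(effect) != length(se)) stop("effect and se lengths differ")
  if (!all(is.finite(effect)) || !all(is.finite(se))) {
    stop("non-finite study estimates")
  }
  if (any(se <= 0)) stop("all standard errors must be positive")
}

meta_result <- function(pooled, pse, k, Q, tau2, effect, se, conf_level) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    k = k, effect = pooled, se = pse,
    ci_lo = pooled - z * pse, ci_hi = pooled + z * pse,
    p = 2 * stats::pnorm(-abs(pooled / pse)),
    Q = Q, tau2 = tau2)
  attr(out, "estimates") <- tibble::tibble(effect = effect, se = se)
  class(out) <- c("meta_result", class(out))
  out
}

# Vectorised DL meta-analysis over matrices of per-study estimates:
# beta and se are S x M (studies x fits); NA entries (failed fits) drop that
# study from that column's pool. Returns pooled effect, SE and Wald p per
# column. This is the permutation-path workhorse.
meta_dl_matrix <- function(beta, se) {
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1)
  if (is.null(dim(se))) se <- matrix(se, nrow = 1)
  ok <- is.finite(beta) & is.finite(se) & se > 0
  w <- ifelse(ok, 1 / se^2, 0)
  b0 <- ifelse(ok, beta, 0)
  k <- colSums(ok)
  sw <- colSums(w)
  b_fix <- colSums(w * b0) / sw
  Q <- colSums(w * (b0 - rep(b_fix, each = nrow(beta)))^2 * ok)
  C <- sw - colSums(w^2) / sw
  tau2 <- ifelse(k > 1 & C > 0, pmax(0, (Q - (k - 1)) / C), 0)
  ws <- ifelse(ok, 1 / (se^2 + rep(tau2, each = nrow(se))), 0)
  sws <- colSums(ws)
  pooled <- colSums(ws * b0) / sws
  pse <- 1 / sqrt(sws)
  bad <- k == 0
  pooled[bad] <- NA_real_; pse[bad] <- NA_real_
  list(effect = pooled, se = pse, k = k, Q = Q, tau2 = tau2,
       p = wald_p(pooled, pse))
}
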