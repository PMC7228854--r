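# Causal-effect estimators operating on a harmonized_set.
#
# All estimators return an mr_estimate: beta on the scale of the input
# effects (log-odds for binary outcomes), its SE, a 95% interval at
# beta +/- 1.96 se, a two-sided p-value, and method metadata.

new_mr_estimate <- function(method, beta, se, pval, n_snps,
                            intercept = NA_real_, intercept_se = NA_real_,
                            intercept_pval = NA_real_,
                            reported = TRUE, reason = NA_character_) {
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
                 pval = pval, or_value = NA_real_, or_ci = c(NA_real_, NA_real_),
                 n_snps = n_snps,
                 intercept = intercept, intercept_se = intercept_se,
                 intercept_pval = intercept_pval,
                 reported = reported, reason = reason),
            class = "mr_estimate")
}

# placeholder for a gated / suppressed method
mr_estimate_na <- function(method, reason, n_snps = NA_integer_) {
  est <- new_mr_estimate(method, NA_real_, NA_real_, NA_real_, n_snps,
                         reported = FALSE, reason = reason)
  est
}

#' @export
print.mr_estimate <- function(x, ...) {
  if (!isTRUE(x$reported) && is.na(x$beta)) {
    cat(sprintf("%-16s n.a. (%s)\n", x$method, x$reason))
    return(invisible(x))
  }
  cat(sprintf("%-16s beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g, n SNPs = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snps))
  if (!is.na(x$or_value))
    cat(sprintf("%-16s OR = %.2f [%.2f, %.2f]\n", "",
                x$or_value, x$or_ci[1], x$or_ci[2]))
  if (!is.na(x$intercept))
    cat(sprintf("%-16s intercept = %.4f (se %.4f), p = %.3g\n", "",
                x$intercept, x$intercept_se, x$intercept_pval))
  invisible(x)
}

check_kept <- function(set, min_n, method) {
  k <- kept(set)
  if (nrow(k) < min_n)
    stop_mrb("%s requires at least %d kept instruments (have %d)",
             method, min_n, nrow(k), class = "insufficient_instruments_error")
  k
}

#' Inverse-variance-weighted fixed-effect estimate
#'
#' Combines per-SNP Wald ratios by fixed-effect meta-analysis with weights
#' `1/ratio_se^2`; equivalently, weighted least squares of `beta_out` on
#' `beta_exp` through the origin with weights `1/se_out^2`. The SE is
#' `(sum w)^(-1/2)` with no heterogeneity inflation; p is two-sided normal.
#'
#' @param set a `harmonized_set` with at least one kept instrument.
#' @return An `mr_estimate` with `method = "ivw"`.
#' @export
mr_ivw <- function(set) {
  k <- check_kept(set, 1L, "ivw")
  w <- 1 / k$ratio_se^2
  beta <- sum(w * k$ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  new_mr_estimate("ivw", beta, se, 2 * stats::pnorm(-abs(beta / se)), nrow(k))
}

# weighted median of values b with weights w (normalized internally):
# cumulative weight minus half of each element's own weight crosses 0.5,
# linearly interpolated between adjacent order statistics
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - 0.5 * w
  if (0.5 <= cw[1]) return(b[1])
  n <- length(b)
  if (0.5 >= cw[n]) return(b[n])
  j <- max(which(cw <= 0.5))
  b[j] + (b[j + 1] - b[j]) * (0.5 - cw[j]) / (cw[j + 1] - cw[j])
}

boot_se <- function(k, point_fun, n_boot, seed) {
  if (n_boot < 1L) return(NA_real_)
  with_seed(seed, {
    n <- nrow(k)
    ests <- vapply(seq_len(n_boot), function(i) {
      be <- stats::rnorm(n, k$beta_exp, k$se_exp)
      bo <- stats::rnorm(n, k$beta_out, k$se_out)
      rr <- bo / be
      rs <- k$se_out / abs(be)
      point_fun(rr, 1 / rs^2)
    }, numeric(1))
    stats::sd(ests)
  })
}

#' Weighted median estimate
#'
#' The inverse-variance-weighted median of the Wald ratios: consistent when
#' less than half of the total instrument weight comes from invalid
#' instruments. The SE comes from a parametric bootstrap that resamples
#' `beta_exp` and `beta_out` from normals with their reported SEs.
#'
#' @param set a `harmonized_set` with at least 3 kept instruments.
#' @param n_boot bootstrap replicates for the SE (default 1000); `0` skips
#'   the bootstrap and returns `NA` SE (point estimate only).
#' @param seed RNG seed for the bootstrap (the caller's RNG is untouched).
#' @return An `mr_estimate` with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000L, seed = NULL) {
  k <- check_kept(set, 3L, "weighted_median")
  w <- 1 / k$ratio_se^2
  beta <- weighted_median_point(k$ratio, w)
  se <- boot_se(k, weighted_median_point, n_boot, seed)
  pval <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("weighted_median", beta, se, pval, nrow(k))
}

weighted_mode_point <- function(b, w, phi = 1) {
  w <- w / sum(w)
  if (diff(range(b)) == 0) return(b[1])
  mu <- sum(w * b)
  wsd <- sqrt(sum(w * (b - mu)^2))
  med <- weighted_median_point(b, w)
  wmad <- weighted_median_point(abs(b - med), w) / 0.6745
  s <- min(wsd, wmad)
  if (s == 0) s <- max(wsd, wmad)        # guard: half-degenerate spread
  h <- phi * 0.9 * s * length(b)^(-1 / 5)
  dens <- function(x)
    vapply(x, function(xi) sum(w * stats::dnorm((xi - b) / h)), numeric(1))
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 512L)
  fx <- dens(grid)
  i <- which.max(fx)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  stats::optimize(dens, c(lo, hi), maximum = TRUE, tol = h * 1e-9)$maximum
}

#' Weighted mode estimate
#'
#' The maximizer of an inverse-variance-weighted normal-kernel density over
#' the Wald ratios; consistent when the largest homogeneous cluster of
#' instruments is valid. Bandwidth is
#' `phi * 0.9 * min(weighted SD, weighted MAD/0.6745) * n^(-1/5)`.
#' SE by parametric bootstrap as in [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param phi bandwidth multiplier (default 1).
#' @return An `mr_estimate` with `method = "weighted_mode"`.
#' @export
mr_weighted_mode <- function(set, phi = 1, n_boot = 1000L, seed = NULL) {
  k <- check_kept(set, 3L, "weighted_mode")
  if (all(k$ratio_se == 0))
    stop_mrb("weighted_mode: all ratio SEs are zero (degenerate weights)",
             class = "degenerate_weights_error")
  w <- 1 / k$ratio_se^2
  beta <- weighted_mode_point(k$ratio, w, phi)
  se <- boot_se(k, function(b, w) weighted_mode_point(b, w, phi),
                n_boot, seed)
  pval <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("weighted_mode", beta, se, pval, nrow(k))
}

# two-parameter WLS of bo on be with weights 1/seo^2, after orienting
# beta_exp > 0; returns coefficients, SEs (residual SD floored at 1), df
egger_fit <- function(be, bo, seo) {
  flip <- be < 0
  be[flip] <- -be[flip]; bo[flip] <- -bo[flip]
  w <- 1 / seo^2
  X <- cbind(1, be)
  XtWX <- crossprod(X, w * X)
  coefs <- unname(drop(solve(XtWX, crossprod(X, w * bo))))
  res <- bo - drop(X %*% coefs)
  df <- length(bo) - 2L
  sigma2 <- sum(w * res^2) / df
  se <- sqrt(diag(solve(XtWX))) * max(1, sqrt(sigma2))
  list(intercept = coefs[1], slope = coefs[2],
       se_intercept = se[1], se_slope = se[2], df = df)
}

#' MR-Egger regression
#'
#' Weighted least squares of the oriented SNP-outcome effects on the
#' SNP-exposure effects with an intercept (weights `1/se_out^2`). Every
#' instrument is first oriented so `beta_exp > 0` (both betas negated when
#' needed), which fixes the sign convention the intercept's interpretation
#' depends on. The slope is the causal estimate under InSIDE; the intercept
#' estimates the average directional pleiotropic effect. SEs use the WLS
#' convention with residual SD floored at 1; p-values from the t
#' distribution with `n_snps - 2` degrees of freedom.
#'
#' @param set a `harmonized_set` with at least 3 kept instruments.
#' @return An `mr_estimate` with `method = "egger"` and intercept fields.
#' @export
mr_egger <- function(set) {
  k <- check_kept(set, 3L, "egger")
  f <- egger_fit(k$beta_exp, k$beta_out, k$se_out)
  est <- new_mr_estimate("egger", f$slope, f$se_slope,
                         2 * stats::pt(-abs(f$slope / f$se_slope), f$df),
                         nrow(k),
                         intercept = f$intercept,
                         intercept_se = f$se_intercept,
                         intercept_pval =
                           2 * stats::pt(-abs(f$intercept / f$se_intercept),
                                         f$df))
  est
}

#' Log-odds to odds-ratio conversion
#'
#' Elementwise exponential of an estimate and its interval bounds. Rounding
#' (2 decimals) happens only in rendered reports, never here.
#'
#' @param beta log-odds estimate.
#' @param ci_low,ci_high 95% interval bounds on the log-odds scale.
#' @return list with `or_value` and `or_ci = c(low, high)`.
#' @export
logodds_to_or <- function(beta, ci_low, ci_high) {
  stopifnot(is.finite(beta), is.finite(ci_low), is.finite(ci_high))
  list(or_value = exp(beta), or_ci = c(exp(ci_low), exp(ci_high)))
}

# attach natural-scale transform when the outcome is binary
attach_or <- function(est, outcome_type) {
  if (identical(outcome_type, "binary") && !is.na(est$beta) &&
      is.finite(est$se)) {
    o <- logodds_to_or(est$beta, est$ci_low, est$ci_high)
    est$or_value <- o$or_value
    est$or_ci <- o$or_ci
  }
  est
}

#' Inverse-variance-weighted multiplicative random-effects estimate
#'
#' Identical point estimate to [mr_ivw()] but with the SE inflated by the
#' residual dispersion when Cochran's Q exceeds its degrees of freedom.
#' Not used by the default reporting policy (which is fixed-effect);
#' provided as an explicit option.
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate` with `method = "ivw_mre"`.
#' @export
mr_ivw_mre <- function(set) {
  k <- check_kept(set, 2L, "ivw_mre")
  w <- 1 / k$ratio_se^2
  beta <- sum(w * k$ratio) / sum(w)
  q <- sum(w * (k$ratio - beta)^2)
  phi <- max(1, q / (nrow(k) - 1L))
  se <- sqrt(phi / sum(w))
  new_mr_estimate("ivw_mre", beta, se, 2 * stats::pnorm(-abs(beta / se)),
                  nrow(k))
}
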