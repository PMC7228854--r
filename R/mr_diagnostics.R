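# Heterogeneity, instrument strength, NOME/SIMEX, Steiger directionality
# and leave-one-out diagnostics.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_i (ratio_i - beta_IVW)^2` with `w_i = 1/ratio_se_i^2`;
#' p-value from the upper tail of chi-square with `n_snps - 1` df.
#'
#' @param set a `harmonized_set` with at least 2 kept instruments.
#' @return list of class `heterogeneity_stats`: `q`, `df`, `pval`.
#' @export
cochran_q <- function(set) {
  k <- check_kept(set, 2L, "cochran_q")
  w <- 1 / k$ratio_se^2
  beta <- sum(w * k$ratio) / sum(w)
  q <- sum(w * (k$ratio - beta)^2)
  df <- nrow(k) - 1L
  structure(list(q = q, df = df,
                 pval = stats::pchisq(q, df, lower.tail = FALSE)),
            class = "heterogeneity_stats")
}

#' @export
print.heterogeneity_stats <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f, df = %d, p = %.3g\n", x$q, x$df, x$pval))
  invisible(x)
}

#' I-squared for the NOME assumption (I2_GX)
#'
#' Quantifies regression dilution of MR-Egger due to measurement error in
#' the SNP-exposure effects. Computed on Egger-oriented (absolute) exposure
#' effects: `Q_GX = sum ((|beta_exp_i| - b_w)/se_exp_i)^2` with `b_w` their
#' inverse-variance-weighted mean, and `I2 = max(0, (Q_GX - (n-1))/Q_GX)`.
#' Values above 0.9 indicate negligible dilution; 0.6-0.9 call for SIMEX
#' correction; below 0.6 MR-Egger is considered unreliable.
#'
#' @param set a `harmonized_set` with at least 2 kept instruments.
#' @return a number in `[0, 1]`.
#' @export
i2_gx <- function(set) {
  k <- check_kept(set, 2L, "i2_gx")
  b <- abs(k$beta_exp)
  w <- 1 / k$se_exp^2
  bw <- sum(w * b) / sum(w)
  q_gx <- sum(((b - bw) / k$se_exp)^2)
  if (q_gx <= 0) return(0)
  max(0, (q_gx - (nrow(k) - 1L)) / q_gx)
}

#' SIMEX-corrected MR-Egger regression
#'
#' Simulation-extrapolation correction for measurement error in the
#' SNP-exposure effects (NOME violation). For each `lambda > 0` in the
#' grid, `B` perturbed datasets add `sqrt(lambda) * se_exp * eps` noise to
#' each `beta_exp`, MR-Egger is refit, and coefficients are averaged; a
#' quadratic in `(1 + lambda)` through the averaged coefficients (the
#' naive fit is the `lambda = 0` point) is extrapolated to `lambda = -1`.
#' SEs are jackknife-over-replicates on the extrapolated coefficients;
#' p-values from t with `n_snps - 2` df. When all `se_exp` are zero there
#' is no measurement error to simulate and the naive fit is returned.
#'
#' @param set a `harmonized_set` with at least 3 kept instruments.
#' @param lambda_grid noise-inflation grid; must contain 0 and at least 3
#'   values (default `c(0, 0.5, 1, 1.5, 2)`).
#' @param B simulation replicates per grid point (default 1000).
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return An `mr_estimate` with `method = "egger_simex"`.
#' @export
mr_simex_egger <- function(set, lambda_grid = c(0, 0.5, 1, 1.5, 2),
                           B = 1000L, seed = NULL) {
  k <- check_kept(set, 3L, "simex_egger")
  if (!any(lambda_grid == 0) || length(lambda_grid) < 3L)
    stop_mrb("simex lambda grid must contain 0 and at least 3 values",
             class = "configuration_error")
  naive <- egger_fit(k$beta_exp, k$beta_out, k$se_out)
  df <- naive$df
  if (all(k$se_exp == 0)) {
    return(new_mr_estimate(
      "egger_simex", naive$slope, naive$se_slope,
      2 * stats::pt(-abs(naive$slope / naive$se_slope), df), nrow(k),
      intercept = naive$intercept, intercept_se = naive$se_intercept,
      intercept_pval = 2 * stats::pt(-abs(naive$intercept /
                                          naive$se_intercept), df)))
  }
  lambdas <- sort(unique(lambda_grid[lambda_grid > 0]))
  nl <- length(lambdas)
  n <- nrow(k)
  slopes <- ints <- matrix(NA_real_, nrow = B, ncol = nl)
  with_seed(seed, {
    for (j in seq_len(nl)) {
      sdj <- sqrt(lambdas[j]) * k$se_exp
      for (b in seq_len(B)) {
        be <- k$beta_exp + stats::rnorm(n, 0, sdj)
        f <- egger_fit(be, k$beta_out, k$se_out)
        slopes[b, j] <- f$slope
        ints[b, j] <- f$intercept
      }
    }
  })
  # quadratic extrapolation in x = 1 + lambda to x = 0; the extrapolated
  # value is a fixed linear functional h of the per-grid-point means, which
  # makes the jackknife over replicates cheap
  x <- 1 + c(0, lambdas)
  A <- cbind(1, x, x^2)
  h <- drop(solve(crossprod(A), t(A))[1, ])   # row for the x = 0 prediction
  extrap <- function(y0, mat) {
    ybar <- colMeans(mat)
    theta <- h[1] * y0 + sum(h[-1] * ybar)
    # leave-one-replicate-out means: (B*ybar - y_b) / (B - 1)
    loo <- h[1] * y0 +
      (matrix(ybar * B, nrow = B, ncol = nl, byrow = TRUE) - mat) %*%
      h[-1] / (B - 1)
    se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
    list(theta = theta, se = se)
  }
  sl <- extrap(naive$slope, slopes)
  ic <- extrap(naive$intercept, ints)
  new_mr_estimate("egger_simex", sl$theta, sl$se,
                  2 * stats::pt(-abs(sl$theta / sl$se), df), n,
                  intercept = ic$theta, intercept_se = ic$se,
                  intercept_pval = 2 * stats::pt(-abs(ic$theta / ic$se), df))
}

#' Per-SNP variance explained (Steiger r-squared)
#'
#' `r2 = t^2 / (t^2 + n_eff - 2)` with `t = beta/se`; `n_eff` is the total
#' sample size for continuous traits and `4 / (1/n_case + 1/n_control)` for
#' binary traits (case/control counts take precedence when both present).
#'
#' @param beta,se effect and standard error (vectorized).
#' @param n total sample size.
#' @param n_case,n_control case/control counts for binary traits.
#' @return variance explained, in `[0, 1)`.
#' @export
steiger_r2 <- function(beta, se, n = NULL, n_case = NULL, n_control = NULL) {
  len <- length(beta)
  fill <- function(x) if (is.null(x)) rep(NA_real_, len) else
    rep_len(as.numeric(x), len)
  n <- fill(n); n_case <- fill(n_case); n_control <- fill(n_control)
  n_eff <- ifelse(!is.na(n_case) & !is.na(n_control),
                  4 / (1 / n_case + 1 / n_control), n)
  if (anyNA(n_eff))
    stop_mrb("steiger_r2: sample size missing (need n, or n_case and n_control)",
             class = "missing_data_error")
  t2 <- (beta / se)^2
  t2 / (t2 + n_eff - 2)
}

#' Steiger directionality filter
#'
#' Computes per-SNP variance explained in the exposure and in the outcome,
#' and drops instruments more predictive of the outcome than of the
#' exposure (likely reverse causation). Exact ties are kept and flagged.
#'
#' @param set a `harmonized_set` whose rows carry per-SNP sample sizes on
#'   both sides (`n_exp`/`n_case_exp`/`n_control_exp` and outcome
#'   analogues).
#' @return list with `set` (the filtered `harmonized_set`) and `report`
#'   (data.frame `snp`, `r2_exp`, `r2_out`, `correct_direction`, `tie`).
#' @export
steiger_filter <- function(set) {
  k <- kept(set)
  r2_exp <- steiger_r2(k$beta_exp, k$se_exp, k$n_exp,
                       k$n_case_exp, k$n_control_exp)
  r2_out <- steiger_r2(k$beta_out, k$se_out, k$n_out,
                       k$n_case_out, k$n_control_out)
  tie <- r2_exp == r2_out
  correct <- r2_exp > r2_out | tie
  report <- data.frame(snp = k$snp, r2_exp = r2_exp, r2_out = r2_out,
                       correct_direction = correct, tie = tie,
                       stringsAsFactors = FALSE)
  keep_ids <- k$snp[correct]
  filtered <- subset_hset(set, set$status == "kept" & set$snp %in% keep_ids)
  list(set = filtered, report = report)
}

#' Instrument strength summary
#'
#' Per-SNP F statistics `(beta_exp/se_exp)^2`, their mean, the total
#' exposure variance explained by the instrument (sum of per-SNP Steiger
#' r-squared, `NA` when exposure sample sizes are missing), and I2_GX.
#'
#' @param set a `harmonized_set` with at least 1 kept instrument.
#' @return list of class `instrument_strength`: `f_per_snp`, `f_mean`,
#'   `r2_exposure_total`, `i2_gx` (`NA` with fewer than 2 instruments).
#' @export
f_statistic <- function(set) {
  k <- check_kept(set, 1L, "f_statistic")
  f <- (k$beta_exp / k$se_exp)^2
  r2_tot <- tryCatch(
    sum(steiger_r2(k$beta_exp, k$se_exp, k$n_exp,
                   k$n_case_exp, k$n_control_exp)),
    error = function(e) NA_real_)
  i2 <- if (nrow(k) >= 2L) i2_gx(set) else NA_real_
  structure(list(f_per_snp = stats::setNames(f, k$snp), f_mean = mean(f),
                 r2_exposure_total = r2_tot, i2_gx = i2),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("Instrument strength: mean F = %.1f (range %.1f-%.1f), total r2 = %s, I2_GX = %s\n",
              x$f_mean, min(x$f_per_snp), max(x$f_per_snp),
              ifelse(is.na(x$r2_exposure_total), "NA",
                     sprintf("%.4f", x$r2_exposure_total)),
              ifelse(is.na(x$i2_gx), "NA", sprintf("%.3f", x$i2_gx))))
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Repeats the IVW analysis omitting each kept instrument in turn; a
#' full-set estimate driven by a single SNP shows up as one omission
#' shifting the estimate far from the rest.
#'
#' @param set a `harmonized_set` with at least 2 kept instruments.
#' @return data.frame with one row per omitted SNP (`snp`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`), in instrument order; the full-set IVW
#'   estimate is attached as attribute `"full"`.
#' @export
leave_one_out <- function(set) {
  k <- check_kept(set, 2L, "leave_one_out")
  kept_idx <- which(set$status == "kept")
  rows <- lapply(seq_along(kept_idx), function(i) {
    est <- mr_ivw(subset_hset(set, kept_idx[-i]))
    data.frame(snp = k$snp[i], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "full") <- mr_ivw(set)
  out
}
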