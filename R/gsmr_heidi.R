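# GSMR: generalized least-squares causal estimate over the Wald ratios,
# accounting for residual LD, preceded by HEIDI outlier filtering.

# LD submatrix over the kept instruments; identity when ld is NULL
ld_for_set <- function(k, ld) {
  if (is.null(ld)) {
    r <- diag(nrow(k))
    dimnames(r) <- list(k$snp, k$snp)
    return(r)
  }
  missing_ld <- setdiff(k$snp, rownames(ld))
  if (length(missing_ld))
    stop_mrb("LD matrix does not cover instrument SNP(s): %s",
             paste(missing_ld, collapse = ", "), class = "coverage_error")
  unclass(ld)[k$snp, k$snp, drop = FALSE]
}

#' HEIDI outlier filtering
#'
#' Heterogeneity-in-dependent-instruments test: the instrument with the
#' strongest exposure association (largest `|beta_exp/se_exp|`; ties broken
#' by lowest exposure p-value, then lexicographic SNP id) is the reference.
#' For every other SNP, `d_i = ratio_i - ratio_ref` with
#' `var(d_i) = ratio_se_i^2 + ratio_se_ref^2 -
#' 2 r_iref ratio_se_i ratio_se_ref`; SNPs whose chi-square(1) p-value on
#' `d_i^2/var(d_i)` falls below the threshold are removed in a single pass.
#'
#' @param set a `harmonized_set`.
#' @param ld optional [ld_matrix] covering the kept instruments (identity
#'   assumed when `NULL`).
#' @param p_threshold removal threshold (default 0.01).
#' @return list with `set` (filtered `harmonized_set`) and `report` (list
#'   of class `heidi_report`: `reference_snp`, `removed` data.frame with
#'   `snp`/`heidi_pval`, `threshold`).
#' @export
heidi_filter <- function(set, ld = NULL, p_threshold = 0.01) {
  k <- check_kept(set, 2L, "heidi_filter")
  r <- ld_for_set(k, ld)
  z <- abs(k$beta_exp / k$se_exp)
  ord <- order(-z, k$pval_exp, k$snp)
  ref <- ord[1]
  i <- setdiff(seq_len(nrow(k)), ref)
  d <- k$ratio[i] - k$ratio[ref]
  v <- k$ratio_se[i]^2 + k$ratio_se[ref]^2 -
    2 * r[cbind(k$snp[i], rep(k$snp[ref], length(i)))] *
      k$ratio_se[i] * k$ratio_se[ref]
  p <- ifelse(v <= .Machine$double.eps, 1,
              stats::pchisq(d^2 / v, 1, lower.tail = FALSE))
  removed_i <- i[p < p_threshold]
  report <- structure(list(
    reference_snp = k$snp[ref],
    removed = data.frame(snp = k$snp[removed_i],
                         heidi_pval = p[match(removed_i, i)],
                         stringsAsFactors = FALSE),
    threshold = p_threshold), class = "heidi_report")
  keep_ids <- setdiff(k$snp, k$snp[removed_i])
  filtered <- subset_hset(set, set$status == "kept" & set$snp %in% keep_ids)
  list(set = filtered, report = report)
}

#' @export
print.heidi_report <- function(x, ...) {
  cat(sprintf("HEIDI filtering (reference %s, p < %g): %d SNP(s) removed\n",
              x$reference_snp, x$threshold, nrow(x$removed)))
  if (nrow(x$removed)) print(x$removed)
  invisible(x)
}

#' GSMR causal estimate
#'
#' Generalized least squares over the Wald ratio vector `r` with covariance
#' `V_ij = r_ij ratio_se_i ratio_se_j` built from the LD correlations:
#' `beta = (1' V^-1 r) / (1' V^-1 1)`, `se = (1' V^-1 1)^(-1/2)`, two-sided
#' normal p. With an identity LD matrix this reduces exactly to the IVW
#' estimate. Near-singular `V` (condition number above `1e12`, or not
#' positive definite) is regularized by adding `1e-10` to the diagonal with
#' a warning; if it remains non-positive-definite a conditioning error
#' suggests pruning.
#'
#' @param set a `harmonized_set` with at least 2 kept instruments
#'   (run [heidi_filter()] first; the pipeline gates GSMR at 10 SNPs).
#' @param ld optional [ld_matrix] (identity assumed when `NULL`).
#' @return An `mr_estimate` with `method = "gsmr"`.
#' @export
gsmr_estimate <- function(set, ld = NULL) {
  k <- check_kept(set, 2L, "gsmr")
  r <- ld_for_set(k, ld)
  V <- r * tcrossprod(k$ratio_se)
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e12) {
    warning("gsmr: ill-conditioned ratio covariance; adding 1e-10 ridge ",
            "to the diagonal (consider pruning correlated instruments)")
    diag(V) <- diag(V) + 1e-10
  }
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch))
    stop_mrb("gsmr: ratio covariance is not positive definite even after ",
             "regularization; prune correlated instruments",
             class = "conditioning_error")
  ones <- rep(1, nrow(k))
  Vi1 <- backsolve(ch, forwardsolve(t(ch), ones))
  denom <- sum(ones * Vi1)
  beta <- sum(k$ratio * Vi1) / denom
  se <- 1 / sqrt(denom)
  new_mr_estimate("gsmr", beta, se, 2 * stats::pnorm(-abs(beta / se)),
                  nrow(k))
}
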