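# Orchestration of the full bidirectional battery with the reporting policy.

#' Decision policy governing which methods run and are reported
#'
#' All thresholds and gates in one place: instrument significance,
#' the 10-SNP gate for MR-Egger and GSMR, the I2_GX bands for the
#' Egger/SIMEX/suppression policy, the HEIDI threshold, the palindromic
#' frequency window, bootstrap replicates and the master seed.
#'
#' @param p_instrument genome-wide significance threshold (default 5e-8).
#' @param r2_prune LD pruning threshold for instrument selection.
#' @param min_snps_egger_gsmr minimum instruments for MR-Egger and GSMR
#'   (default 10).
#' @param i2_full,i2_simex I2_GX bands: full Egger when `I2 > i2_full`,
#'   SIMEX when `i2_simex <= I2 <= i2_full`, suppressed below.
#' @param heidi_p HEIDI removal threshold (default 0.01).
#' @param alpha significance level for evidence grading (default 0.05).
#' @param eaf_window palindromic ambiguity window.
#' @param n_boot bootstrap / SIMEX replicates (default 1000).
#' @param phi weighted-mode bandwidth multiplier.
#' @param seed master seed; the pipeline is a pure function of (inputs,
#'   policy) — identical seeds give byte-identical results.
#' @return list of class `decision_policy`.
#' @export
decision_policy <- function(p_instrument = 5e-8, r2_prune = 0.001,
                            min_snps_egger_gsmr = 10L,
                            i2_full = 0.9, i2_simex = 0.6,
                            heidi_p = 0.01, alpha = 0.05,
                            eaf_window = c(0.42, 0.58),
                            n_boot = 1000L, phi = 1, seed = 1L) {
  stopifnot(i2_simex > 0, i2_simex < i2_full, i2_full <= 1,
            min_snps_egger_gsmr >= 3, p_instrument > 0, p_instrument < 1,
            length(eaf_window) == 2, eaf_window[1] < eaf_window[2])
  structure(list(p_instrument = p_instrument, r2_prune = r2_prune,
                 min_snps_egger_gsmr = as.integer(min_snps_egger_gsmr),
                 i2_full = i2_full, i2_simex = i2_simex, heidi_p = heidi_p,
                 alpha = alpha, eaf_window = eaf_window,
                 n_boot = as.integer(n_boot), phi = phi,
                 seed = as.integer(seed)),
            class = "decision_policy")
}

# three-band Egger reporting decision from I2_GX
egger_band <- function(i2, policy) {
  if (is.na(i2)) return("suppressed")
  if (i2 > policy$i2_full) "full"
  else if (i2 >= policy$i2_simex) "simex"
  else "suppressed"
}

#' Run one direction of the MR battery
#'
#' Selects instruments from the exposure table, harmonizes them with the
#' outcome, and runs the full battery under the reporting policy: IVW,
#' weighted median and weighted mode always (3+ instruments); MR-Egger and
#' GSMR only with `min_snps_egger_gsmr` (default 10) or more instruments;
#' the Egger entry follows the three I2_GX bands (full / SIMEX-corrected /
#' suppressed with reason); GSMR is preceded by HEIDI filtering (identity
#' LD assumed when none given). Cochran's Q, instrument strength,
#' the Steiger directionality report, re-estimation of every reported
#' method on the Steiger-filtered subset, leave-one-out IVW and the
#' evidence grade are attached.
#'
#' @param exposure,outcome [sumstat_table]s.
#' @param policy a [decision_policy].
#' @param ld optional [ld_matrix] over the exposure's instruments (used for
#'   pruning and GSMR).
#' @return list of class `direction_result` with elements `exposure`,
#'   `outcome`, `estimable`, `harmonized`, `estimates` (named list of
#'   `mr_estimate`, unreported ones carrying a reason), `heterogeneity`,
#'   `strength`, `steiger` (report), `steiger_refit`, `loo`, `heidi`,
#'   `evidence`, `policy`.
#' @export
run_direction <- function(exposure, outcome, policy = decision_policy(),
                          ld = NULL) {
  stopifnot(inherits(policy, "decision_policy"))
  ins <- select_instruments(exposure, policy$p_instrument, ld,
                            policy$r2_prune)
  hs <- harmonize(ins, outcome, policy$eaf_window)
  res <- list(exposure = attr(hs, "exposure_name"),
              outcome = attr(hs, "outcome_name"),
              harmonized = hs, policy = policy,
              estimable = n_kept(hs) >= 3L)
  out_type <- attr(hs, "outcome_type")

  res$strength <- if (n_kept(hs) >= 1L) f_statistic(hs) else NULL
  res$heterogeneity <- if (n_kept(hs) >= 2L) cochran_q(hs) else NULL
  if (!res$estimable) {
    message(sprintf("run_direction: %s -> %s not estimable (%d kept instruments < 3)",
                    res$exposure, res$outcome, n_kept(hs)))
    class(res) <- "direction_result"
    return(res)
  }

  est <- battery_estimates(hs, policy, ld, out_type)
  res$estimates <- est$estimates
  res$heidi <- est$heidi

  st <- steiger_filter(hs)
  res$steiger <- st$report
  res$steiger_refit <-
    if (n_kept(st$set) >= 3L)
      battery_estimates(st$set, policy, ld, out_type)$estimates
    else list()

  res$loo <- leave_one_out(hs)
  class(res) <- "direction_result"
  res$evidence <- evidence_summary(res, policy)
  res
}

# run the estimator battery under the policy gates on one harmonized set
battery_estimates <- function(hs, policy, ld, out_type) {
  n <- n_kept(hs)
  ests <- list(
    ivw = mr_ivw(hs),
    weighted_median = mr_weighted_median(hs, n_boot = policy$n_boot,
                                         seed = policy$seed),
    weighted_mode = mr_weighted_mode(hs, phi = policy$phi,
                                     n_boot = policy$n_boot,
                                     seed = policy$seed + 1L))
  heidi <- NULL
  if (n < policy$min_snps_egger_gsmr) {
    reason <- sprintf("fewer than %d instruments (n = %d)",
                      policy$min_snps_egger_gsmr, n)
    message("policy gate: MR-Egger and GSMR not run: ", reason)
    ests$egger <- mr_estimate_na("egger", reason, n)
    ests$gsmr <- mr_estimate_na("gsmr", reason, n)
  } else {
    band <- egger_band(i2_gx(hs), policy)
    ests$egger <- switch(band,
      full = mr_egger(hs),
      simex = mr_simex_egger(hs, B = policy$n_boot,
                             seed = policy$seed + 2L),
      suppressed = {
        message(sprintf("policy gate: MR-Egger suppressed (I2_GX < %g)",
                        policy$i2_simex))
        mr_estimate_na("egger", sprintf("I2_GX < %g", policy$i2_simex), n)
      })
    hf <- heidi_filter(hs, ld, policy$heidi_p)
    heidi <- hf$report
    ests$gsmr <- if (n_kept(hf$set) >= 2L)
      gsmr_estimate(hf$set, ld)
    else mr_estimate_na("gsmr", "fewer than 2 instruments after HEIDI", n)
  }
  ests <- lapply(ests, attach_or, outcome_type = out_type)
  list(estimates = ests, heidi = heidi)
}

#' Run the bidirectional battery
#'
#' [run_direction()] in both directions. The reverse-direction outcome
#' table is whatever the caller supplies — e.g. restricting a disorder
#' GWAS to adult-onset cases to preserve temporal ordering is the caller's
#' data choice, not enforced here.
#'
#' @param a,b [sumstat_table]s (a is the forward exposure).
#' @param policy a [decision_policy] shared by both directions.
#' @param ld_a,ld_b optional [ld_matrix] for each direction's instruments.
#' @return list of class `bidirectional_result` with elements `forward`
#'   (a -> b) and `reverse` (b -> a).
#' @export
run_bidirectional <- function(a, b, policy = decision_policy(),
                              ld_a = NULL, ld_b = NULL) {
  structure(list(forward = run_direction(a, b, policy, ld_a),
                 reverse = run_direction(b, a, policy, ld_b)),
            class = "bidirectional_result")
}

#' Grade cross-estimator consistency of a direction result
#'
#' An interpretation layer over the battery: `no-clear-evidence` when the
#' IVW p-value is at or above `alpha`; otherwise `consistent-evidence`
#' when every reported sensitivity estimate shares IVW's sign,
#' `weak-evidence` when at least half do, `inconsistent` otherwise.
#'
#' @param result a `direction_result`.
#' @param policy a [decision_policy] (for `alpha`).
#' @return list of class `evidence_grade`: `grade`, `ivw_pval`,
#'   `sign_agreement` (named logical vector over reported sensitivity
#'   methods).
#' @export
evidence_summary <- function(result, policy = decision_policy()) {
  stopifnot(inherits(result, "direction_result"))
  if (!isTRUE(result$estimable))
    return(structure(list(grade = "not-estimable", ivw_pval = NA_real_,
                          sign_agreement = logical()),
                     class = "evidence_grade"))
  ivw <- result$estimates$ivw
  sens <- result$estimates[setdiff(names(result$estimates), "ivw")]
  sens <- Filter(function(e) isTRUE(e$reported) && !is.na(e$beta), sens)
  agree <- vapply(sens, function(e) sign(e$beta) == sign(ivw$beta),
                  logical(1))
  grade <- if (ivw$pval >= policy$alpha) "no-clear-evidence"
  else if (length(agree) == 0L || all(agree)) "consistent-evidence"
  else if (mean(agree) >= 0.5) "weak-evidence"
  else "inconsistent"
  structure(list(grade = grade, ivw_pval = ivw$pval, sign_agreement = agree),
            class = "evidence_grade")
}

#' @export
print.evidence_grade <- function(x, ...) {
  cat(sprintf("Evidence grade: %s (IVW p = %.3g)\n", x$grade, x$ivw_pval))
  if (length(x$sign_agreement))
    cat("  sign agreement:",
        paste(sprintf("%s=%s", names(x$sign_agreement),
                      ifelse(x$sign_agreement, "yes", "no")),
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.direction_result <- function(x, ...) {
  cat(sprintf("MR battery: %s -> %s (%d kept instruments)\n",
              x$exposure, x$outcome, attr(x$harmonized, "n_kept")))
  if (!isTRUE(x$estimable)) {
    cat("  not estimable (< 3 kept instruments); diagnostics retained\n")
    return(invisible(x))
  }
  for (e in x$estimates) print(e)
  if (!is.null(x$heterogeneity)) print(x$heterogeneity)
  if (!is.null(x$strength)) print(x$strength)
  if (!is.null(x$heidi)) print(x$heidi)
  cat(sprintf("Steiger: %d/%d instruments in the correct direction\n",
              sum(x$steiger$correct_direction), nrow(x$steiger)))
  print(x$evidence)
  invisible(x)
}

#' @export
print.bidirectional_result <- function(x, ...) {
  print(x$forward); cat("\n"); print(x$reverse)
  invisible(x)
}

fmt_or <- function(est, binary) {
  if (!binary || !isTRUE(est$reported)) return("")
  if (is.na(est$or_value)) return("")
  sprintf("%.2f", est$or_value)
}

# one results-table row per direction, Tables 1/2 shape
result_row <- function(res) {
  binary <- identical(attr(res$harmonized, "outcome_type"), "binary")
  cell <- function(est, what) {
    if (is.null(est)) return(NA_real_)
    if (!isTRUE(est$reported) && what != "n_snps") return(NA_real_)
    est[[what]]
  }
  methods <- c("ivw", "weighted_median", "weighted_mode", "egger", "gsmr")
  row <- list(exposure = res$exposure, outcome = res$outcome,
              n_snps = attr(res$harmonized, "n_kept"))
  for (m in methods) {
    est <- res$estimates[[m]]
    pre <- m
    row[[paste0(pre, "_beta")]] <- cell(est, "beta")
    row[[paste0(pre, "_or")]] <- if (is.null(est)) "" else {
      if (!isTRUE(est$reported)) "n.a." else fmt_or(est, binary)
    }
    row[[paste0(pre, "_ci_low")]] <- cell(est, "ci_low")
    row[[paste0(pre, "_ci_high")]] <- cell(est, "ci_high")
    row[[paste0(pre, "_pval")]] <- cell(est, "pval")
  }
  row$egger_method <- if (!is.null(res$estimates$egger))
    res$estimates$egger$method else NA_character_
  row$n_snps_heidi <- if (!is.null(res$heidi))
    row$n_snps - nrow(res$heidi$removed) else NA_integer_
  # reference-only multiplicity correction (no correction is applied to
  # the reported p-values themselves)
  row$ivw_pval_bonferroni <- if (!is.null(res$estimates$ivw))
    min(1, res$estimates$ivw$pval) else NA_real_
  as.data.frame(row, stringsAsFactors = FALSE)
}

diagnostic_row <- function(res) {
  het <- res$heterogeneity; st <- res$strength
  eg <- res$estimates$egger
  data.frame(
    exposure = res$exposure, outcome = res$outcome,
    n_snps = attr(res$harmonized, "n_kept"),
    q = het$q %||% NA_real_, q_df = het$df %||% NA_integer_,
    q_pval = het$pval %||% NA_real_,
    i2_gx = st$i2_gx %||% NA_real_, f_mean = st$f_mean %||% NA_real_,
    r2_exposure_total = st$r2_exposure_total %||% NA_real_,
    egger_intercept = if (!is.null(eg)) eg$intercept else NA_real_,
    egger_intercept_se = if (!is.null(eg)) eg$intercept_se else NA_real_,
    egger_intercept_pval = if (!is.null(eg)) eg$intercept_pval else NA_real_,
    egger_status = if (is.null(eg)) "not_run"
                   else if (isTRUE(eg$reported)) eg$method
                   else paste0("n.a.: ", eg$reason),
    steiger_correct = if (!is.null(res$steiger))
      sum(res$steiger$correct_direction) else NA_integer_,
    steiger_flagged = if (!is.null(res$steiger))
      sum(!res$steiger$correct_direction) else NA_integer_,
    evidence = if (!is.null(res$evidence)) res$evidence$grade
               else "not-estimable",
    stringsAsFactors = FALSE)
}

#' Render the report files for one or more direction results
#'
#' Writes three tab-delimited files under `prefix`: `<prefix>_results.tsv`
#' (the main table in the exposure/outcome/n SNPs/per-method
#' beta-OR-CI-P/n SNPs after HEIDI layout; ORs rendered at 2 decimals only
#' for binary outcomes, suppressed methods as `n.a.`, plus a
#' reference-only Bonferroni column), `<prefix>_diagnostics.tsv` (Q,
#' I2_GX, F, Egger intercept, Steiger counts, evidence grade per
#' direction) and `<prefix>_loo.tsv` (leave-one-out series, long format
#' for plotting).
#'
#' @param results a `direction_result`, `bidirectional_result`, or list of
#'   `direction_result`s.
#' @param prefix output path prefix.
#' @return character vector of the three file paths, invisibly.
#' @export
render_report <- function(results, prefix = "mr_report") {
  if (inherits(results, "direction_result")) results <- list(results)
  if (inherits(results, "bidirectional_result"))
    results <- list(results$forward, results$reverse)
  stopifnot(all(vapply(results, inherits, logical(1), "direction_result")))
  n_dirs <- length(results)
  main <- do.call(rbind, lapply(results, result_row))
  main$ivw_pval_bonferroni <- pmin(1, main$ivw_pval_bonferroni * n_dirs)
  diag_tab <- do.call(rbind, lapply(results, diagnostic_row))
  loo <- do.call(rbind, lapply(results, function(r) {
    if (is.null(r$loo)) return(NULL)
    cbind(data.frame(exposure = r$exposure, outcome = r$outcome,
                     stringsAsFactors = FALSE), r$loo)
  }))
  paths <- paste0(prefix, c("_results.tsv", "_diagnostics.tsv", "_loo.tsv"))
  wt <- function(d, p) utils::write.table(d, p, sep = "\t", quote = FALSE,
                                          row.names = FALSE, na = "NA")
  wt(main, paths[1]); wt(diag_tab, paths[2])
  if (!is.null(loo)) wt(loo, paths[3]) else
    wt(data.frame(exposure = character(), outcome = character()), paths[3])
  invisible(paths)
}
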