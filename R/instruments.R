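# Instrument selection and exposure/outcome harmonization.

#' Select genome-wide-significant independent instruments
#'
#' Subsets an exposure table to SNPs with `pval < p_threshold` and, when an
#' LD matrix is supplied, greedily prunes correlated pairs: SNPs are visited
#' in order of ascending p-value and any remaining SNP with `r^2 >=
#' r2_threshold` against a kept SNP is removed. Without an LD matrix the
#' table is assumed to hold pre-clumped index SNPs (the usual published
#' form) and is passed through with a message.
#'
#' @param exposure a [sumstat_table].
#' @param p_threshold genome-wide significance threshold (default `5e-8`,
#'   strict `<`).
#' @param ld optional [ld_matrix] covering (at least) the significant SNPs.
#' @param r2_threshold squared-correlation pruning threshold (default 0.001).
#' @return A [sumstat_table] of instruments.
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8, ld = NULL,
                               r2_threshold = 0.001) {
  stopifnot(inherits(exposure, "sumstat_table"))
  sig <- exposure[!is.na(exposure$pval) & exposure$pval < p_threshold, ,
                  drop = FALSE]
  if (nrow(sig) == 0L)
    stop_mrb("no instruments: no SNP reached p < %g", p_threshold,
             class = "empty_instrument_error")
  if (is.null(ld)) {
    message("select_instruments: no LD matrix supplied; ",
            "assuming SNPs are pre-pruned index variants")
  } else {
    missing_ld <- setdiff(sig$snp, rownames(ld))
    if (length(missing_ld))
      stop_mrb("LD matrix does not cover instrument SNP(s): %s",
               paste(missing_ld, collapse = ", "), class = "coverage_error")
    ord <- sig$snp[order(sig$pval)]
    kept <- character()
    for (s in ord) {
      if (length(kept) == 0L ||
          all(ld[s, kept]^2 < r2_threshold)) kept <- c(kept, s)
    }
    sig <- sig[sig$snp %in% kept, , drop = FALSE]
  }
  rownames(sig) <- NULL
  attrs <- attributes(exposure)
  structure(sig, trait_name = attrs$trait_name, trait_type = attrs$trait_type,
            validation = attrs$validation,
            class = c("sumstat_table", "data.frame"))
}

palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Construct a harmonized instrument set directly
#'
#' Builds a `harmonized_set` from already-aligned exposure and outcome
#' effects (one row per instrument, all kept). This is the entry point for
#' users whose data are pre-harmonized and for constructing small sets in
#' tests; [harmonize()] produces the same structure from raw tables.
#'
#' Per-SNP Wald ratios use the first-order delta method:
#' `ratio = beta_out / beta_exp`, `ratio_se = se_out / |beta_exp|`.
#'
#' @param snp SNP identifiers.
#' @param beta_exp,se_exp SNP-exposure effects and standard errors.
#' @param beta_out,se_out SNP-outcome effects and standard errors.
#' @param eaf_exp,eaf_out optional effect-allele frequencies.
#' @param pval_exp,pval_out optional association p-values.
#' @param n_exp,n_out,n_case_exp,n_control_exp,n_case_out,n_control_out
#'   optional per-SNP sample sizes (needed for Steiger filtering).
#' @param exposure_name,outcome_name,exposure_type,outcome_type metadata.
#' @param second_order_se if `TRUE`, `ratio_se` additionally carries the
#'   second-order delta-method term
#'   `sqrt(se_out^2/beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)`.
#' @return A data.frame of class `harmonized_set`.
#' @export
harmonized_set <- function(snp, beta_exp, se_exp, beta_out, se_out,
                           eaf_exp = NA_real_, eaf_out = NA_real_,
                           pval_exp = NA_real_, pval_out = NA_real_,
                           n_exp = NA_real_, n_out = NA_real_,
                           n_case_exp = NA_real_, n_control_exp = NA_real_,
                           n_case_out = NA_real_, n_control_out = NA_real_,
                           exposure_name = "exposure",
                           outcome_name = "outcome",
                           exposure_type = "continuous",
                           outcome_type = "continuous",
                           second_order_se = FALSE) {
  # zero SEs are tolerated here (exact-arithmetic test cases, SIMEX
  # identities); tables read from disk are validated strictly instead
  stopifnot(all(se_exp >= 0), all(se_out >= 0), all(beta_exp != 0))
  d <- data.frame(snp = as.character(snp),
                  beta_exp = beta_exp, se_exp = se_exp,
                  pval_exp = pval_exp, eaf_exp = eaf_exp, n_exp = n_exp,
                  n_case_exp = n_case_exp, n_control_exp = n_control_exp,
                  beta_out = beta_out, se_out = se_out,
                  pval_out = pval_out, eaf_out = eaf_out, n_out = n_out,
                  n_case_out = n_case_out, n_control_out = n_control_out,
                  stringsAsFactors = FALSE)
  d$ratio <- d$beta_out / d$beta_exp
  d$ratio_se <- if (second_order_se)
    sqrt(d$se_out^2 / d$beta_exp^2 +
         d$beta_out^2 * d$se_exp^2 / d$beta_exp^4)
  else d$se_out / abs(d$beta_exp)
  d$status <- "kept"
  d$drop_reason <- "none"
  structure(d, exposure_name = exposure_name, outcome_name = outcome_name,
            exposure_type = exposure_type, outcome_type = outcome_type,
            n_kept = nrow(d),
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s, %d kept / %d instruments\n",
              attr(x, "exposure_name"), attr(x, "outcome_name"),
              attr(x, "n_kept"), nrow(x)))
  cols <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out",
            "ratio", "ratio_se", "status", "drop_reason")
  print(utils::head(as.data.frame(x)[cols], 10L))
  invisible(x)
}

# kept-rows view used by every estimator
kept <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  set[set$status == "kept", , drop = FALSE]
}

n_kept <- function(set) sum(set$status == "kept")

# rebuild a harmonized_set from a row subset, preserving metadata
subset_hset <- function(set, idx) {
  out <- set[idx, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("exposure_name", "outcome_name", "exposure_type",
              "outcome_type"))
    attr(out, a) <- attr(set, a)
  attr(out, "n_kept") <- sum(out$status == "kept")
  class(out) <- c("harmonized_set", "data.frame")
  out
}

#' Harmonize exposure instruments with an outcome table
#'
#' Aligns each instrument SNP's outcome association to the exposure's effect
#' allele. SNPs absent from the outcome are dropped (`missing_in_outcome`);
#' matching alleles are kept unchanged; swapped alleles (exposure effect
#' allele equals outcome other allele and vice versa) negate the outcome
#' beta and complement its frequency; palindromic A/T and C/G pairs are
#' resolved by effect-allele frequency only when both frequencies lie
#' outside `eaf_window`, otherwise dropped (`ambiguous_palindrome`); any
#' other allele configuration is dropped (`allele_mismatch`). No strand
#' flipping is attempted for non-palindromic SNPs and no proxy lookup is
#' performed. Kept instruments carry the Wald `ratio` and first-order
#' `ratio_se` (see [harmonized_set()]).
#'
#' @param exposure_instruments [sumstat_table] of selected instruments.
#' @param outcome [sumstat_table] for the outcome trait.
#' @param eaf_window frequency ambiguity window for palindromic SNPs
#'   (default `c(0.42, 0.58)`): inside it strand cannot be inferred.
#' @param second_order_se see [harmonized_set()].
#' @return A `harmonized_set` containing one row per input instrument,
#'   kept or dropped with a reason code.
#' @export
harmonize <- function(exposure_instruments, outcome,
                      eaf_window = c(0.42, 0.58), second_order_se = FALSE) {
  stopifnot(inherits(exposure_instruments, "sumstat_table"),
            inherits(outcome, "sumstat_table"))
  ex <- as.data.frame(exposure_instruments)
  ou <- as.data.frame(outcome)
  m <- match(ex$snp, ou$snp)

  nL <- nrow(ex)
  status <- rep("kept", nL)
  reason <- rep("none", nL)
  beta_out <- ou$beta[m]; se_out <- ou$se[m]
  pval_out <- ou$pval[m]; eaf_out <- ou$eaf[m]
  n_out <- ou$n[m]; n_case_out <- ou$n_case[m]; n_control_out <- ou$n_control[m]
  ea_o <- ou$effect_allele[m]; oa_o <- ou$other_allele[m]

  drop <- function(i, why) {
    status[i] <<- "dropped"; reason[i] <<- why
  }
  miss <- is.na(m)
  drop(miss, "missing_in_outcome")

  pal <- palindromic(ex$effect_allele, ex$other_allele)
  idx <- which(!miss)
  for (i in idx) {
    same <- ea_o[i] == ex$effect_allele[i] && oa_o[i] == ex$other_allele[i]
    swap <- ea_o[i] == ex$other_allele[i] && oa_o[i] == ex$effect_allele[i]
    if (!same && !swap) { drop(i, "allele_mismatch"); next }
    if (swap) {
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
    }
    if (pal[i]) {
      # strand is ambiguous: allele labels carry no information, use eafs
      fe <- ex$eaf[i]; fo <- eaf_out[i]
      inside <- function(f) f > eaf_window[1] & f < eaf_window[2]
      if (is.na(fe) || is.na(fo) || inside(fe) || inside(fo)) {
        drop(i, "ambiguous_palindrome"); next
      }
      if ((fe < 0.5) != (fo < 0.5)) {       # frequencies disagree: flip strand
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
    }
  }
  zero <- status == "kept" & ex$beta == 0
  if (any(zero)) {
    message("harmonize: dropping ", sum(zero),
            " SNP(s) with zero exposure effect (undefined Wald ratio)")
    drop(which(zero), "undefined_ratio")
  }

  keep_i <- status == "kept"
  ratio <- ratio_se <- rep(NA_real_, nL)
  if (any(keep_i)) {
    ratio[keep_i] <- beta_out[keep_i] / ex$beta[keep_i]
    ratio_se[keep_i] <- if (second_order_se)
      sqrt(se_out[keep_i]^2 / ex$beta[keep_i]^2 +
           beta_out[keep_i]^2 * ex$se[keep_i]^2 / ex$beta[keep_i]^4)
    else se_out[keep_i] / abs(ex$beta[keep_i])
  }

  d <- data.frame(snp = ex$snp,
                  beta_exp = ex$beta, se_exp = ex$se, pval_exp = ex$pval,
                  eaf_exp = ex$eaf, n_exp = ex$n,
                  n_case_exp = ex$n_case, n_control_exp = ex$n_control,
                  beta_out = beta_out, se_out = se_out, pval_out = pval_out,
                  eaf_out = eaf_out, n_out = n_out,
                  n_case_out = n_case_out, n_control_out = n_control_out,
                  ratio = ratio, ratio_se = ratio_se,
                  status = status, drop_reason = reason,
                  stringsAsFactors = FALSE)
  structure(d,
            exposure_name = attr(exposure_instruments, "trait_name"),
            outcome_name = attr(outcome, "trait_name"),
            exposure_type = attr(exposure_instruments, "trait_type"),
            outcome_type = attr(outcome, "trait_type"),
            n_kept = sum(keep_i),
            class = c("harmonized_set", "data.frame"))
}
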