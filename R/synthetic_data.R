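# Synthetic two-sample GWAS summary statistics with known causal structure.
#
# The generator emulates the situation the pipeline is built for: L
# LD-independent index SNPs, each genome-wide significant for the exposure,
# looked up in an independent outcome GWAS of (possibly) different size.
# Effects are on the standardized scale, so se = (2 p (1-p) N)^(-1/2); the
# effect allele is coded as the exposure-increasing allele, as in published
# index-SNP lists.

#' Define a simulation scenario
#'
#' @param L number of instrument SNPs (all genome-wide significant by
#'   construction).
#' @param theta true causal effect of exposure on outcome.
#' @param theta_rev reverse causal effect (outcome on exposure), default 0.
#' @param sigma_gamma SD of true SNP-exposure effects before the
#'   significance constraint (default 0.03 on the standardized scale,
#'   giving per-SNP variance explained and F statistics comparable to
#'   published psychiatric/substance-use instruments at N ~ 1e5).
#' @param pi_inv fraction of invalid (pleiotropic) instruments in `[0, 1]`.
#' @param mu_alpha,sigma_alpha mean/SD of direct pleiotropic effects on the
#'   outcome (`mu_alpha != 0` gives directional pleiotropy).
#' @param q_inside regression of the pleiotropic effect on instrument
#'   strength; 0 means InSIDE holds.
#' @param n_exp,n_out GWAS sample sizes.
#' @param binary_exposure,binary_outcome flags; binary traits report
#'   case/control counts (`case_frac_*` of N) and betas read as log-odds.
#' @param case_frac_exp,case_frac_out case fractions for binary traits.
#' @param maf_range allele-frequency bounds, default `c(0.1, 0.9)`.
#' @param prop_palindromic fraction of SNPs assigned A/T or C/G allele
#'   pairs (exercises harmonization), default 0.
#' @param prop_swapped fraction of SNPs whose outcome table swaps the
#'   allele coding (beta negated, frequency complemented), default 0.
#' @param reverse_instruments if `TRUE`, the drawn per-SNP effect acts
#'   directly on the *outcome* and reaches the exposure only through the
#'   feedback `theta_rev` (instruments proximal to the outcome); the
#'   significance constraint then applies to the induced exposure
#'   association, so the SNPs still pass instrument selection.
#' @param seed RNG seed.
#' @return list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(L = 50L, theta = 0, theta_rev = 0,
                                sigma_gamma = 0.03, pi_inv = 0,
                                mu_alpha = 0, sigma_alpha = 0, q_inside = 0,
                                n_exp = 1e5, n_out = 1e5,
                                binary_exposure = FALSE,
                                binary_outcome = FALSE,
                                case_frac_exp = 0.5, case_frac_out = 0.5,
                                maf_range = c(0.1, 0.9),
                                prop_palindromic = 0, prop_swapped = 0,
                                reverse_instruments = FALSE, seed = NULL) {
  stopifnot(L >= 1, pi_inv >= 0, pi_inv <= 1, n_exp >= 2, n_out >= 2,
            sigma_gamma > 0, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] < 1,
            maf_range[1] <= maf_range[2],
            prop_palindromic >= 0, prop_palindromic <= 1,
            prop_swapped >= 0, prop_swapped <= 1)
  structure(list(L = as.integer(L), theta = theta, theta_rev = theta_rev,
                 sigma_gamma = sigma_gamma, pi_inv = pi_inv,
                 mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
                 q_inside = q_inside, n_exp = n_exp, n_out = n_out,
                 binary_exposure = binary_exposure,
                 binary_outcome = binary_outcome,
                 case_frac_exp = case_frac_exp,
                 case_frac_out = case_frac_out,
                 maf_range = maf_range,
                 prop_palindromic = prop_palindromic,
                 prop_swapped = prop_swapped,
                 reverse_instruments = reverse_instruments, seed = seed),
            class = "simulation_scenario")
}

# allele pairs cycled deterministically over non-palindromic combinations
NONPAL_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                      c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
PAL_PAIRS <- rbind(c("A", "T"), c("C", "G"), c("T", "A"), c("G", "C"))

# z threshold for two-sided p < 5e-8
GWS_Z <- stats::qnorm(2.5e-8, lower.tail = FALSE)

#' Simulate a pair of two-sample summary-statistics tables
#'
#' Generates exposure and outcome [sumstat_table]s under a
#' [simulation_scenario]. For each SNP: allele frequency uniform on
#' `maf_range`; the true SNP-exposure effect is `|N(0, sigma_gamma^2)|`
#' (effect allele = exposure-increasing allele), resampled (bounded at 1000
#' rounds) until the *expected* exposure p-value at `n_exp` is below 5e-8,
#' so selection at the genome-wide threshold retains all `L` SNPs; with
#' probability `pi_inv` the SNP receives a direct outcome effect
#' `mu_alpha + q_inside * gamma + N(0, sigma_alpha^2)`. Observed effects
#' are the true effects plus independent normal noise with
#' `se = (2 p (1-p) n_eff)^(-1/2)` per sample (two-sample independence);
#' binary traits use `n_eff = 4/(1/n_case + 1/n_control)`.
#'
#' @param scenario a [simulation_scenario].
#' @return list with elements `exposure` and `outcome`, both
#'   [sumstat_table]s; true per-SNP parameters are attached to the result
#'   as attribute `"truth"` (data.frame `snp`, `gamma`, `alpha`,
#'   `invalid`).
#' @export
simulate_sumstats <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  s <- scenario
  with_seed(s$seed, {
    L <- s$L
    p <- stats::runif(L, s$maf_range[1], s$maf_range[2])
    n_eff <- function(n, binary, frac) {
      if (!binary) return(rep(n, L))
      rep(4 / (1 / (frac * n) + 1 / ((1 - frac) * n)), L)
    }
    ne_exp <- n_eff(s$n_exp, s$binary_exposure, s$case_frac_exp)
    ne_out <- n_eff(s$n_out, s$binary_outcome, s$case_frac_out)
    se_exp <- 1 / sqrt(2 * p * (1 - p) * ne_exp)
    se_out <- 1 / sqrt(2 * p * (1 - p) * ne_out)

    # exposure-side association induced per true effect draw g
    exp_assoc <- if (s$reverse_instruments)
      function(g) s$theta_rev * g else function(g) g
    gamma <- rep(NA_real_, L)
    pending <- seq_len(L)
    for (round in seq_len(1000L)) {
      if (!length(pending)) break
      draw <- abs(stats::rnorm(length(pending), 0, s$sigma_gamma))
      ok <- abs(exp_assoc(draw)) / se_exp[pending] > GWS_Z
      gamma[pending[ok]] <- draw[ok]
      pending <- pending[!ok]
    }
    if (length(pending))
      stop_mrb(paste0("scenario infeasible: sigma_gamma = %g cannot reach ",
                      "genome-wide significance at n_exp = %g for %d SNP(s) ",
                      "after 1000 resampling rounds"),
               s$sigma_gamma, s$n_exp, length(pending),
               class = "scenario_infeasible_error")

    invalid <- stats::runif(L) < s$pi_inv
    alpha <- ifelse(invalid,
                    s$mu_alpha + s$q_inside * gamma +
                      stats::rnorm(L, 0, s$sigma_alpha), 0)
    if (s$reverse_instruments) {
      mu_out <- gamma + alpha
      mu_exp <- s$theta_rev * mu_out
    } else {
      mu_out <- s$theta * gamma + alpha
      mu_exp <- gamma + s$theta_rev * mu_out
    }
    beta_exp <- stats::rnorm(L, mu_exp, se_exp)
    beta_out <- stats::rnorm(L, mu_out, se_out)

    snp <- sprintf("rs%07d", seq_len(L))
    n_pal <- floor(s$prop_palindromic * L)
    alleles <- matrix(NA_character_, L, 2)
    if (n_pal > 0)
      alleles[seq_len(n_pal), ] <-
        PAL_PAIRS[(seq_len(n_pal) - 1L) %% nrow(PAL_PAIRS) + 1L, ]
    if (n_pal < L) {
      rest <- seq.int(n_pal + 1L, L)
      alleles[rest, ] <-
        NONPAL_PAIRS[(seq_along(rest) - 1L) %% nrow(NONPAL_PAIRS) + 1L, ]
    }

    mk <- function(b, se, eaf, ea, oa, n, binary, frac) {
      df <- data.frame(snp = snp, effect_allele = ea, other_allele = oa,
                       eaf = eaf, beta = b, se = se,
                       pval = 2 * stats::pnorm(-abs(b) / se),
                       n = n, stringsAsFactors = FALSE)
      if (binary) {
        df$n_case <- round(frac * n)
        df$n_control <- round((1 - frac) * n)
      }
      df
    }
    exp_df <- mk(beta_exp, se_exp, p, alleles[, 1], alleles[, 2],
                 s$n_exp, s$binary_exposure, s$case_frac_exp)
    # outcome table: a deterministic leading fraction gets swapped coding
    n_swap <- floor(s$prop_swapped * L)
    swap <- seq_len(L) <= n_swap
    out_df <- mk(ifelse(swap, -beta_out, beta_out), se_out,
                 ifelse(swap, 1 - p, p),
                 ifelse(swap, alleles[, 2], alleles[, 1]),
                 ifelse(swap, alleles[, 1], alleles[, 2]),
                 s$n_out, s$binary_outcome, s$case_frac_out)

    res <- list(
      exposure = sumstat_table(exp_df, trait_name = "sim_exposure",
                               trait_type = if (s$binary_exposure) "binary"
                                            else "continuous"),
      outcome = sumstat_table(out_df, trait_name = "sim_outcome",
                              trait_type = if (s$binary_outcome) "binary"
                                           else "continuous"))
    attr(res, "truth") <- data.frame(snp = snp, gamma = gamma, alpha = alpha,
                                     invalid = invalid,
                                     stringsAsFactors = FALSE)
    res
  })
}

#' Run a parameter-recovery suite over scenarios
#'
#' Repeatedly simulates each scenario, runs instrument selection,
#' harmonization and the requested estimators, and summarizes per
#' scenario x estimator: mean bias against the scenario's true `theta`,
#' RMSE, empirical SE (SD of the point estimates, with its Monte-Carlo SE),
#' 95% CI coverage and rejection rate at alpha = 0.05 (for estimators with
#' analytic SEs: IVW and MR-Egger).
#'
#' @param scenarios a [simulation_scenario] or list of them.
#' @param n_reps replicates per scenario.
#' @param seed master seed; each scenario x replicate derives its own.
#' @param estimators subset of `c("ivw", "weighted_median",
#'   "weighted_mode", "egger")`.
#' @return data.frame with one row per scenario x estimator; columns
#'   `scenario`, `estimator`, `theta`, `n_reps`, `mean_estimate`,
#'   `mean_bias`, `rmse`, `empirical_se`, `mc_se`, `coverage`,
#'   `rejection_rate` (coverage/rejection `NA` for bootstrap-SE methods,
#'   whose SEs are not recomputed here for speed).
#' @export
recovery_suite <- function(scenarios, n_reps = 100L, seed = 1L,
                           estimators = c("ivw", "weighted_median",
                                          "weighted_mode", "egger")) {
  if (inherits(scenarios, "simulation_scenario")) scenarios <- list(scenarios)
  estimators <- match.arg(estimators, several.ok = TRUE)
  out <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    est_mat <- matrix(NA_real_, n_reps, length(estimators),
                      dimnames = list(NULL, estimators))
    cover <- reject <- matrix(NA, n_reps, length(estimators),
                              dimnames = list(NULL, estimators))
    for (j in seq_len(n_reps)) {
      sc$seed <- (seed + 104729L * si + j) %% 2147483647L
      sim <- simulate_sumstats(sc)
      ins <- suppressMessages(select_instruments(sim$exposure))
      hs <- harmonize(ins, sim$outcome)
      k <- kept(hs)
      w <- 1 / k$ratio_se^2
      for (e in estimators) {
        est <- switch(e,
          ivw = mr_ivw(hs),
          egger = mr_egger(hs),
          weighted_median = list(beta = weighted_median_point(k$ratio, w),
                                 se = NA_real_, pval = NA_real_),
          weighted_mode = list(beta = weighted_mode_point(k$ratio, w),
                               se = NA_real_, pval = NA_real_))
        est_mat[j, e] <- est$beta
        if (!is.na(est$se)) {
          cover[j, e] <- (est$beta - Z95 * est$se) <= sc$theta &
                         sc$theta <= (est$beta + Z95 * est$se)
          reject[j, e] <- est$pval < 0.05
        }
      }
    }
    for (e in estimators) {
      x <- est_mat[, e]
      out[[length(out) + 1L]] <- data.frame(
        scenario = si, estimator = e, theta = sc$theta, n_reps = n_reps,
        mean_estimate = mean(x), mean_bias = mean(x) - sc$theta,
        rmse = sqrt(mean((x - sc$theta)^2)), empirical_se = stats::sd(x),
        mc_se = stats::sd(x) / sqrt(n_reps),
        coverage = mean(cover[, e]), rejection_rate = mean(reject[, e]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
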