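---
title: "Methods: the two-sample MR battery, its policy, and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-sample MR battery, its policy, and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrbattery)
```

# The model

Two-sample Mendelian randomization treats a set of $L$ LD-independent SNPs
as instruments for an exposure $X$. The generative picture is

$$\hat\beta_{Xi} \sim N(\gamma_i,\ \sigma_{Xi}^2), \qquad
  \hat\beta_{Yi} \sim N(\theta\gamma_i + \alpha_i,\ \sigma_{Yi}^2),$$

with $\gamma_i$ the SNP's effect on the exposure, $\theta$ the causal effect
of interest, and $\alpha_i$ a direct (horizontally pleiotropic) effect on
the outcome. Exposure and outcome associations come from non-overlapping
samples, so their errors are independent. A valid instrument has
$\alpha_i = 0$; the three instrument assumptions are (1) association with
the exposure, (2) independence from confounders, and (3) no effect on the
outcome except through the exposure.

The per-SNP Wald ratio $\hat\theta_i = \hat\beta_{Yi}/\hat\beta_{Xi}$ has
first-order standard error $\sigma_{Yi}/|\hat\beta_{Xi}|$ (a second-order
variant adding $\hat\beta_{Yi}^2\sigma_{Xi}^2/\hat\beta_{Xi}^4$ is available
via `second_order_se = TRUE` but off by default, since the first-order form
is what underlies the conventional IVW weights).

## Estimators

* **IVW (fixed effect).** $\hat\theta = \sum w_i\hat\theta_i / \sum w_i$,
  $w_i = 1/\mathrm{se}(\hat\theta_i)^2$, $\mathrm{se} = (\sum w_i)^{-1/2}$;
  equivalently WLS of $\hat\beta_{Yi}$ on $\hat\beta_{Xi}$ through the
  origin with weights $1/\sigma_{Yi}^2$. No heterogeneity inflation is
  applied (a multiplicative random-effects variant, `mr_ivw_mre()`, exists
  but is never used by the default policy). P-values are two-sided normal.
* **Weighted median.** The inverse-variance-weighted 50% quantile of the
  ordered ratios, interpolating the cumulative weight minus half of each
  SNP's own weight; consistent when invalid instruments carry < 50% of the
  weight. SEs by parametric bootstrap (resampling $\hat\beta_{Xi}$,
  $\hat\beta_{Yi}$ from normals with their reported SEs), seeded.
* **Weighted mode.** Argmax of a weighted normal-kernel density over the
  ratios, bandwidth $\varphi \cdot 0.9\min(s_w, \mathrm{MAD}_w/0.6745)
  \, n^{-1/5}$ with $\varphi = 1$ by default. When the weighted MAD is
  exactly zero but the SD is not (half-degenerate inputs) the SD is used;
  when all ratios coincide the common value is returned directly. The
  argmax is located on a 512-point grid and refined by golden-section
  search to a tolerance of $10^{-9}$ bandwidths.
* **MR-Egger.** WLS of $\hat\beta_{Yi}$ on $\hat\beta_{Xi}$ *with*
  intercept, weights $1/\sigma_{Yi}^2$, after orienting every instrument so
  $\hat\beta_{Xi} > 0$ (the intercept — the average directional pleiotropic
  effect — is only interpretable under a fixed orientation convention).
  Coefficient SEs use the WLS convention with the residual SD floored at 1
  (no under-dispersion); p-values use $t_{n-2}$, the small-sample
  convention.
* **GSMR.** Generalized least squares over the ratio vector with covariance
  $V_{ij} = r_{ij}\,\mathrm{se}_i\,\mathrm{se}_j$ built from the LD
  correlations; reduces exactly to IVW under identity LD. Preceded by HEIDI
  filtering (below).

## Diagnostics and filters

* **Cochran's Q** on the ratios with IVW weights; $\chi^2_{n-1}$ upper
  tail.
* **I²_GX** quantifies NOME violation (regression dilution of Egger):
  $Q_{GX} = \sum ((|\hat\beta_{Xi}| - \bar\beta_w)/\sigma_{Xi})^2$ on
  Egger-oriented effects, $I^2 = \max(0, (Q_{GX} - (n-1))/Q_{GX})$. The
  statistic is cited in the applied literature without a formula; this
  $(Q-df)/Q$ form is the standard one and is what the package documents
  and tests.
* **SIMEX** refits Egger on data with inflated measurement error
  ($\sqrt\lambda\,\sigma_{Xi}$ noise added to $\hat\beta_{Xi}$, $B$
  replicates per grid point, default grid $\{0, 0.5, 1, 1.5, 2\}$,
  $B = 1000$), fits a quadratic in $(1+\lambda)$ through the averaged
  coefficients and extrapolates to $\lambda = -1$. Because the extrapolated
  value is a fixed linear functional of the per-grid-point means, the
  jackknife over replicates is exact and cheap. With all
  $\sigma_{Xi} = 0$ the naive fit is returned unchanged.
* **Steiger filtering** compares per-SNP variance explained,
  $r^2 = t^2/(t^2 + n_\mathrm{eff} - 2)$ with $t = \hat\beta/\mathrm{se}$
  and $n_\mathrm{eff} = 4/(1/n_\mathrm{case} + 1/n_\mathrm{control})$ for
  binary traits, on the observed scale. Liability-scale conversion is out
  of scope and noted as a limitation. Exact ties are kept and flagged —
  conservative toward retaining instruments.
* **HEIDI** takes the instrument with the largest $|\hat\beta_{Xi}/
  \sigma_{Xi}|$ as reference (ties: lowest exposure p, then lexicographic
  id), tests each other SNP's ratio difference against it with a
  $\chi^2_1$ statistic whose variance term subtracts twice the LD-induced
  covariance, and removes SNPs with $p < 0.01$ in a single pass. Threshold
  and single-pass behaviour are documented defaults (the method is named
  in the applied literature without parameters) and configurable.

## The reporting policy

`decision_policy()` collects every gate: instruments at $P < 5\times10^{-8}$
(strict), greedy LD pruning at $r^2 \ge 0.001$ when a matrix is supplied
(otherwise the input is trusted as pre-clumped index SNPs, with a logged
message); MR-Egger and GSMR only at $\ge 10$ instruments; the Egger entry is
the full fit when $I^2_{GX} > 0.9$, the SIMEX fit when
$0.6 \le I^2_{GX} \le 0.9$, and suppressed with a reason below 0.6 (band
boundaries were stated without open/closed conventions; both SIMEX edges
are closed here). IVW, weighted median and weighted mode always run at
$\ge 3$ instruments; below 3 the direction is marked not-estimable with
diagnostics retained. All reported estimators are re-run on the
Steiger-filtered subset. No multiple-testing correction is applied to the
reported p-values; the rendered table carries a Bonferroni column for
reference only.

The **evidence grade** is an explicit interpretation layer, not a claim
inherited from any publication: `no-clear-evidence` when IVW $p \ge
\alpha$; otherwise `consistent-evidence` when every reported sensitivity
estimate shares IVW's sign, `weak-evidence` when at least half do,
`inconsistent` otherwise. The per-method sign-agreement vector is attached
so a reader can apply their own rule.

## Harmonization choices

Outcome effects are aligned to the exposure's effect allele: matching
alleles pass unchanged; swapped alleles negate the beta and complement the
frequency; palindromic (A/T, C/G) SNPs carry no strand information in their
labels, so orientation is inferred from allele frequencies only when both
sides fall outside the ambiguity window (0.42, 0.58) — inside it, or with a
missing frequency, the SNP is dropped as `ambiguous_palindrome`. Any other
configuration is `allele_mismatch`; no strand-flipping of non-palindromic
alleles and no proxy-SNP search is attempted (instruments missing from the
outcome are dropped and counted). The window is configurable; (0.42, 0.58)
mirrors common two-sample MR practice.

# The simulator: what it emulates and what it does not

`simulate_sumstats()` produces the summary statistics of $L$ pre-clumped
index SNPs: allele frequency $p_i \sim U(\texttt{maf\_range})$, standard
errors $(2p_i(1-p_i)N)^{-1/2}$ on the standardized-trait scale (effective
$N$ for binary traits), true exposure effects
$\gamma_i = |N(0, \sigma_\gamma^2)|$ resampled (bounded at 1000 rounds)
until the *expected* exposure p-value beats $5\times10^{-8}$, pleiotropic
effects $\alpha_i = \mu_\alpha + q\,\gamma_i + N(0, \sigma_\alpha^2)$ for a
random fraction $\pi_\mathrm{inv}$, and independent observation noise on
both sides.

Three modelling decisions deserve emphasis:

* **Effect alleles are exposure-increasing** ($\gamma_i \ge 0$). Published
  index-SNP lists are conventionally reported for the trait-increasing
  allele, and directional pleiotropy is only *directional* relative to such
  an orientation: with sign-symmetric $\gamma$, a constant $\mu_\alpha$
  produces ratio biases $\alpha/\gamma$ of both signs that cancel in IVW,
  which is not the phenomenon the robustness battery is meant to expose.
* **No winner's curse by default.** Significance is enforced on the true
  effect, mimicking replicated index SNPs, so observed effects are unbiased
  given $\gamma$; a marginal SNP can therefore occasionally miss the
  *observed* threshold and selection may retain slightly fewer than $L$.
  Selection-on-observed-beta is deliberately not the default.
* **Reverse-causation scenarios** set `reverse_instruments = TRUE`: the
  drawn effect acts on the outcome and reaches the exposure only through
  the feedback $\theta_\mathrm{rev}$, with the significance constraint
  applied to the induced exposure association (so the SNPs still pass
  instrument selection). A single forward formula cannot produce
  selected instruments that are more predictive of the outcome, because
  selection forces the exposure-side effect to be large.

Default $\sigma_\gamma = 0.03$ at $N = 10^5$ gives per-SNP exposure
variance explained of roughly 0.05–0.15% and mean F statistics in the
tens-to-hundreds — the instrument strength typical of current psychiatric
and substance-use GWAS (total $r^2$ of ~0.5–1% over ~10 SNPs). For the
directional-pleiotropy separation scenario used in the acceptance tests,
the unstated scales were fixed once at $\sigma_\gamma = 0.1$,
$N_\mathrm{out} = 1.2\times10^6$, $\sigma_\alpha = 0.01$: the
strong-instrument, very-large-outcome-GWAS regime (the scale of current
smoking-initiation GWAS), which is the regime in which weighted-median
robustness holds at finite noise rather than only asymptotically. With
noisier ratios the weighted median of a directionally contaminated mixture
sits at an upper quantile of the valid cluster and is visibly biased — a
property of the estimator, not a defect of the implementation.

What the generator does **not** emulate: LD between instruments (an LD
matrix can be supplied to the pipeline, but generated SNPs are
independent), winner's curse (optional, off), sample overlap between the
two GWAS, population stratification, liability-scale subtleties of binary
traits, and real allele-frequency spectra. A green simulation test
therefore establishes correct estimator behaviour under the stated
generative model — not robustness to everything real data can do.

# Numerical choices and degenerate inputs

* 95% intervals use the fixed factor 1.96 (reporting convention), so
  `ci = beta ± 1.96 se` holds exactly by construction.
* p-values: normal for IVW/median/mode/GSMR, $t_{n-2}$ for Egger and SIMEX.
* Zero p-values on input are clamped to the smallest positive double and
  flagged (`pval_zero_clamped`) so downstream log transforms are safe.
* A kept instrument with $\hat\beta_{Xi} = 0$ has no Wald ratio; it is
  dropped with reason `undefined_ratio` and logged.
* GSMR's ratio covariance is checked by eigendecomposition; condition
  number $> 10^{12}$ or a non-positive eigenvalue triggers a $10^{-10}$
  ridge with a warning, and a Cholesky failure after that is a
  conditioning error suggesting pruning. Perfectly redundant instruments
  ($r = 1$) thus collapse gracefully to the single-SNP estimate.
* HEIDI variance terms at or below machine epsilon yield $p = 1$ (no
  evidence of heterogeneity), covering duplicated instruments.
* All stochastic components (bootstrap, SIMEX, simulator) take explicit
  seeds, save and restore the caller's RNG state, and derive per-replicate
  seeds arithmetically, so the full pipeline is a pure function of
  (inputs, policy) and byte-identical under a fixed seed.
* Tables round-trip through disk at 10 significant digits (`%.10g`).

# Known limitations

Proxy-SNP lookup, multivariable MR, latent-causal-variable modelling,
genetic-correlation estimation and liability-scale Steiger $r^2$ are out of
scope. The Egger SE convention (residual SD floored at 1) and the SIMEX
quadratic extrapolant are documented defaults rather than settled theory;
both are configurable at the call sites that matter. The evidence grade
compresses a multi-estimator table into four labels and should be read
alongside the full table, never instead of it.
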