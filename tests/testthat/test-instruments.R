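test_that("select_instruments applies the strict 5e-8 threshold", {
  tab <- make_table(data.frame(
    snp = c("rs1", "rs2", "rs3"),
    effect_allele = "A", other_allele = "G",
    beta = 0.05, se = 0.005, pval = c(4.9e-8, 5.1e-8, 5e-8), n = 1e5))
  expect_message(sel <- select_instruments(tab), "pre-pruned")
  expect_equal(sel$snp, "rs1")  # 5e-8 itself is excluded (strict <)
  expect_error(select_instruments(tab, p_threshold = 1e-10),
               "1e-10", class = "empty_instrument_error")
})

test_that("LD pruning keeps the lowest-p SNP of a correlated pair", {
  tab <- make_table(data.frame(
    snp = c("rs1", "rs2", "rs3"),
    effect_allele = "A", other_allele = "G",
    beta = 0.05, se = 0.005, pval = c(1e-9, 1e-10, 1e-11), n = 1e5))
  r <- diag(3); dimnames(r) <- list(tab$snp, tab$snp)
  # identity LD: everything kept
  expect_setequal(select_instruments(tab, ld = ld_matrix(r))$snp, tab$snp)
  # rs1-rs2 in LD (r = 0.9): greedy oracle on the pair keeps the lower p (rs2)
  r[1, 2] <- r[2, 1] <- 0.9
  kept <- select_instruments(tab, ld = ld_matrix(r))$snp
  expect_setequal(kept, c("rs2", "rs3"))
  expect_error(select_instruments(tab, ld = ld_matrix(diag(2),
                                                      c("rs1", "rs2"))),
               class = "coverage_error")
})

outcome_for <- function(exposure, effect_allele, other_allele,
                        beta = 0.05, eaf = 0.3) {
  make_table(data.frame(
    snp = exposure$snp, effect_allele = effect_allele,
    other_allele = other_allele, eaf = eaf, beta = beta, se = 0.01,
    pval = 0.5, n = 1e5))
}

test_that("harmonize handles identity, swap, palindromes and mismatch", {
  exp_tab <- make_table(data.frame(
    snp = sprintf("rs%d", 1:5),
    effect_allele = c("A", "A", "A", "A", "C"),
    other_allele  = c("G", "G", "T", "T", "G"),
    eaf = c(0.3, 0.3, 0.50, 0.3, 0.2),
    beta = 0.05, se = 0.005, pval = 1e-9, n = 1e5))
  out_tab <- make_table(data.frame(
    snp = sprintf("rs%d", 1:5),
    effect_allele = c("A", "G", "A", "A", "C"),
    other_allele  = c("G", "A", "T", "T", "A"),
    eaf = c(0.3, 0.7, 0.50, 0.25, 0.2),
    beta = 0.05, se = 0.01, pval = 0.5, n = 1e5))
  hs <- harmonize(exp_tab, out_tab)
  # rs1 identity: unchanged
  expect_equal(hs$beta_out[1], 0.05)
  # rs2 swapped alleles: beta negated, eaf complemented
  expect_equal(hs$beta_out[2], -0.05)
  expect_equal(hs$eaf_out[2], 0.3)
  # rs3 palindromic with eaf 0.50: inside ambiguity window
  expect_equal(hs$drop_reason[3], "ambiguous_palindrome")
  # rs4 palindromic, both eafs outside window and on the same side: kept
  expect_equal(hs$status[4], "kept")
  expect_equal(hs$beta_out[4], 0.05)
  # rs5 outcome alleles C/A do not match exposure C/G
  expect_equal(hs$drop_reason[5], "allele_mismatch")
  # kept rows satisfy the ratio invariant
  k <- hs[hs$status == "kept", ]
  expect_equal(k$ratio, k$beta_out / k$beta_exp, tolerance = 1e-12)
  expect_equal(k$ratio_se, k$se_out / abs(k$beta_exp), tolerance = 1e-12)
  expect_equal(attr(hs, "n_kept"), sum(hs$status == "kept"))
})

test_that("palindromic SNPs on opposite frequency sides are strand-flipped", {
  exp_tab <- make_table(data.frame(
    snp = "rs1", effect_allele = "A", other_allele = "T",
    eaf = 0.2, beta = 0.05, se = 0.005, pval = 1e-9, n = 1e5))
  out_tab <- outcome_for(exp_tab, "A", "T", beta = 0.04, eaf = 0.8)
  hs <- harmonize(exp_tab, out_tab)
  expect_equal(hs$status, "kept")
  expect_equal(hs$beta_out, -0.04)
  expect_equal(hs$eaf_out, 0.2)
})

test_that("missing outcome SNPs and zero exposure effects are dropped", {
  exp_tab <- make_table(data.frame(
    snp = c("rs1", "rs2"), effect_allele = "A", other_allele = "G",
    eaf = 0.3, beta = c(0, 0.05), se = 0.005, pval = 1e-9, n = 1e5))
  out_tab <- make_table(data.frame(
    snp = "rs1", effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = 0.05, se = 0.01, pval = 0.5, n = 1e5))
  expect_message(hs <- harmonize(exp_tab, out_tab), "undefined")
  expect_equal(hs$drop_reason, c("undefined_ratio", "missing_in_outcome"))
  expect_equal(attr(hs, "n_kept"), 0)
})

test_that("harmonization is idempotent and sign-coherent", {
  sim <- simulate_sumstats(std_scenario(L = 20, theta = 0.1, seed = 11,
                                        prop_palindromic = 0.2,
                                        prop_swapped = 0.3))
  hs1 <- harmonize(sim$exposure, sim$outcome)
  # idempotence: harmonizing the already-aligned pair changes nothing
  aligned_out <- sim$outcome
  k <- match(hs1$snp, aligned_out$snp)
  aligned_out$beta[k] <- hs1$beta_out
  aligned_out$effect_allele[k] <- sim$exposure$effect_allele
  aligned_out$other_allele[k] <- sim$exposure$other_allele
  aligned_out$eaf[k] <- hs1$eaf_out
  hs2 <- harmonize(sim$exposure, aligned_out)
  keep <- hs1$status == "kept"
  expect_equal(hs2$beta_out[keep], hs1$beta_out[keep], tolerance = 1e-12)
  # sign coherence: negating the outcome's allele roles and beta is a no-op
  neg_out <- sim$outcome
  neg_out$beta <- -neg_out$beta
  neg_out$eaf <- 1 - neg_out$eaf
  tmp <- neg_out$effect_allele
  neg_out$effect_allele <- neg_out$other_allele
  neg_out$other_allele <- tmp
  hs3 <- harmonize(sim$exposure, neg_out)
  expect_equal(hs3$status, hs1$status)
  expect_equal(hs3$beta_out[keep], hs1$beta_out[keep], tolerance = 1e-12)
  # count conservation
  expect_equal(sum(hs1$status == "kept") + sum(hs1$status == "dropped"),
               nrow(sim$exposure))
})
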