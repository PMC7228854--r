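# Fixtures are built in code; nothing is read from disk except what a test
# itself writes to tempfiles.

make_table <- function(df, trait_type = "continuous", trait_name = "trait") {
  sumstat_table(df, trait_name = trait_name, trait_type = trait_type)
}

# a small fully-valid exposure-style table
basic_table <- function(n = 5, p_scale = 1e-10, trait_type = "continuous") {
  make_table(data.frame(
    snp = sprintf("rs%d", seq_len(n)),
    effect_allele = rep(c("A", "C", "G", "T"), length.out = n),
    other_allele = rep(c("G", "T", "A", "C"), length.out = n),
    eaf = seq(0.2, 0.8, length.out = n),
    beta = seq(0.02, 0.06, length.out = n),
    se = rep(0.005, n),
    pval = p_scale * seq_len(n),
    n = rep(1e5, n)), trait_type = trait_type)
}

# harmonized set straight from components (all kept)
make_hset <- function(beta_exp, se_exp, beta_out, se_out, ...) {
  harmonized_set(snp = sprintf("rs%d", seq_along(beta_exp)),
                 beta_exp = beta_exp, se_exp = se_exp,
                 beta_out = beta_out, se_out = se_out, ...)
}

# harmonized set with chosen Wald ratios and ratio SEs (unit exposure effects)
ratio_hset <- function(ratio, ratio_se, ...) {
  make_hset(beta_exp = rep(1, length(ratio)),
            se_exp = rep(1e-6, length(ratio)),
            beta_out = ratio, se_out = ratio_se, ...)
}

# random instance for the linear-algebra oracles
random_hset <- function(n, seed) {
  set.seed(seed)
  make_hset(beta_exp = stats::runif(n, 0.02, 0.1) *
              sample(c(-1, 1), n, replace = TRUE),
            se_exp = stats::runif(n, 0.002, 0.01),
            beta_out = stats::rnorm(n, 0, 0.05),
            se_out = stats::runif(n, 0.005, 0.03))
}

std_scenario <- function(...) simulation_scenario(...)

# forward pass of the pipeline front end, quiet
sim_hset <- function(scenario) {
  sim <- simulate_sumstats(scenario)
  harmonize(suppressMessages(select_instruments(sim$exposure)), sim$outcome)
}

# deterministic table pair with exactly L instruments surviving the pipeline
exact_tables <- function(L, beta_ratio = 0.2, spread = TRUE) {
  set.seed(1000 + L)
  be <- seq(0.03, 0.08, length.out = L)
  if (spread) be <- be + runif(L, 0, 0.01)
  exp_tab <- make_table(data.frame(
    snp = sprintf("rs%d", seq_len(L)),
    effect_allele = "A", other_allele = "G",
    eaf = seq(0.15, 0.85, length.out = L),
    beta = be, se = 0.004, pval = 1e-9, n = 1e5))
  out_tab <- make_table(data.frame(
    snp = exp_tab$snp, effect_allele = "A", other_allele = "G",
    eaf = exp_tab$eaf, beta = beta_ratio * be + rnorm(L, 0, 0.005),
    se = 0.005, pval = 0.5, n = 1e5))
  list(exposure = exp_tab, outcome = out_tab)
}
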