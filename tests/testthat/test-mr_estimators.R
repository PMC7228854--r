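test_that("IVW: single SNP equals the Wald ratio; equal weights average", {
  hs <- make_hset(beta_exp = 0.05, se_exp = 0.005,
                  beta_out = 0.02, se_out = 0.01)
  est <- mr_ivw(hs)
  expect_equal(est$beta, 0.02 / 0.05)
  expect_equal(est$se, 0.01 / 0.05)

  hs2 <- ratio_hset(ratio = c(0.2, 0.4), ratio_se = c(0.1, 0.1))
  expect_equal(mr_ivw(hs2)$beta, 0.3)
  empty <- subset_hset <- hs[0, ]
  expect_error(mr_ivw(structure(empty, class = class(hs), n_kept = 0)),
               class = "insufficient_instruments_error")
})

test_that("IVW matches the weighted origin-regression normal equations", {
  for (seed in 1:5) {
    hs <- random_hset(20, seed)
    w <- 1 / hs$se_out^2
    oracle <- sum(w * hs$beta_exp * hs$beta_out) / sum(w * hs$beta_exp^2)
    expect_equal(mr_ivw(hs)$beta, oracle, tolerance = 1e-10)
  }
})

test_that("weighted median: symmetric case, constant input, bootstrap SE", {
  hs <- ratio_hset(c(1, 2, 3), rep(0.5, 3))
  est <- mr_weighted_median(hs, n_boot = 200, seed = 1)
  expect_equal(est$beta, 2)
  expect_true(est$se > 0)

  hs2 <- ratio_hset(rep(0.7, 4), rep(0.2, 4))
  est2 <- mr_weighted_median(hs2, n_boot = 200, seed = 1)
  expect_equal(est2$beta, 0.7)
  expect_true(est2$se > 0)
  expect_error(mr_weighted_median(ratio_hset(c(1, 2), c(1, 1))),
               class = "insufficient_instruments_error")
})

test_that("weighted median is permutation- and split-weight-invariant", {
  set.seed(3)
  r <- rnorm(9); s <- runif(9, 0.1, 0.5)
  base <- mr_weighted_median(ratio_hset(r, s), n_boot = 0)$beta
  perm <- sample(9)
  expect_equal(mr_weighted_median(ratio_hset(r[perm], s[perm]),
                                  n_boot = 0)$beta, base, tolerance = 1e-9)
  # duplicating an instrument with its weight halved (se * sqrt(2)) is a no-op
  dup <- mr_weighted_median(
    ratio_hset(c(r, r[1]), c(s[1] * sqrt(2), s[-1], s[1] * sqrt(2))),
    n_boot = 0)$beta
  expect_equal(dup, base, tolerance = 1e-9)
})

test_that("weighted mode finds the dominant cluster and is stable in phi", {
  # point mass
  expect_equal(mr_weighted_mode(ratio_hset(rep(0.4, 5), rep(0.1, 5)),
                                n_boot = 0)$beta, 0.4)
  # 7 ratios near 0.10, 3 near 0.50: mode sits at the big cluster
  set.seed(7)
  r <- c(0.10 + rnorm(7, 0, 0.005), 0.50 + rnorm(3, 0, 0.005))
  s <- rep(0.05, 10)
  hs <- ratio_hset(r, s)
  est <- mr_weighted_mode(hs, n_boot = 0)
  # independent grid-search oracle over the raw kernel density
  w <- rep(1 / 0.05^2, 10); w <- w / sum(w)
  mu <- sum(w * r); wsd <- sqrt(sum(w * (r - mu)^2))
  med <- sort(r)[5:6]; med <- mean(med)  # equal weights: plain median
  wmad <- stats::median(abs(r - med)) / 0.6745
  h <- 0.9 * min(wsd, wmad) * 10^(-1 / 5)
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 20000)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - r) / h)), numeric(1))
  oracle <- grid[which.max(dens)]
  expect_equal(est$beta, oracle, tolerance = 1e-3)
  expect_lt(abs(est$beta - 0.10), h)
  # doubling phi within a single tight cluster moves the argmax < 1e-3
  single <- ratio_hset(0.2 + rnorm(8, 0, 0.001), rep(0.05, 8))
  m1 <- mr_weighted_mode(single, phi = 1, n_boot = 0)$beta
  m2 <- mr_weighted_mode(single, phi = 2, n_boot = 0)$beta
  expect_lt(abs(m1 - m2), 1e-3)
  expect_error(mr_weighted_mode(ratio_hset(c(1, 2, 3), rep(0, 3)),
                                n_boot = 0),
               class = "degenerate_weights_error")
})

test_that("Egger recovers an exact affine relation and matches WLS oracle", {
  be <- c(0.02, 0.05, 0.08)
  hs <- make_hset(beta_exp = be, se_exp = rep(0.001, 3),
                  beta_out = 0.01 + 0.2 * be, se_out = rep(0.01, 3))
  est <- mr_egger(hs)
  expect_equal(est$beta, 0.2, tolerance = 1e-12)
  expect_equal(est$intercept, 0.01, tolerance = 1e-12)

  for (seed in 6:10) {
    hs <- random_hset(20, seed)
    flip <- hs$beta_exp < 0
    be <- abs(hs$beta_exp)
    bo <- ifelse(flip, -hs$beta_out, hs$beta_out)
    X <- cbind(1, be); w <- 1 / hs$se_out^2
    oracle <- solve(t(X) %*% (w * X), t(X) %*% (w * bo))
    est <- mr_egger(hs)
    expect_equal(est$intercept, oracle[1], tolerance = 1e-10)
    expect_equal(est$beta, oracle[2], tolerance = 1e-10)
  }
})

test_that("Egger recovers theta and mean pleiotropy under InSIDE", {
  # directional pleiotropy on every SNP, independent of instrument strength
  n_rep <- 300
  slopes <- ints <- numeric(n_rep)
  set.seed(42)
  for (i in seq_len(n_rep)) {
    gamma <- runif(50, 0.03, 0.1)
    alpha <- 0.02 + rnorm(50, 0, 0.01)
    se_out <- rep(0.005, 50)
    hs <- make_hset(beta_exp = gamma, se_exp = rep(1e-4, 50),
                    beta_out = rnorm(50, 0.1 * gamma + alpha, se_out),
                    se_out = se_out)
    f <- mr_egger(hs)
    slopes[i] <- f$beta; ints[i] <- f$intercept
  }
  expect_lt(abs(mean(slopes) - 0.1), 3 * sd(slopes) / sqrt(n_rep) + 0.005)
  expect_lt(abs(mean(ints) - 0.02), 3 * sd(ints) / sqrt(n_rep) + 0.002)
})

test_that("estimators are scale- and sign-equivariant in the outcome", {
  hs <- random_hset(15, seed = 99)
  k <- 2.5
  scaled <- make_hset(hs$beta_exp, hs$se_exp, k * hs$beta_out, k * hs$se_out)
  flipped <- make_hset(hs$beta_exp, hs$se_exp, -hs$beta_out, hs$se_out)
  for (f in list(mr_ivw, mr_egger,
                 function(s) mr_weighted_median(s, n_boot = 0),
                 function(s) mr_weighted_mode(s, n_boot = 0))) {
    base <- f(hs)
    # 1e-6 accommodates the weighted mode's numeric argmax refinement
    expect_equal(f(scaled)$beta, k * base$beta, tolerance = 1e-6)
    expect_equal(f(flipped)$beta, -base$beta, tolerance = 1e-6)
    if (!is.na(base$se))
      expect_equal(f(scaled)$se, k * base$se, tolerance = 1e-8)
  }
})

test_that("mr_estimate invariants: CI at 1.96 SE, OR transforms", {
  est <- mr_ivw(random_hset(10, 1))
  expect_equal(est$ci_low, est$beta - 1.96 * est$se, tolerance = 1e-9)
  expect_equal(est$ci_high, est$beta + 1.96 * est$se, tolerance = 1e-9)
  o <- logodds_to_or(0.12, 0.02, 0.22)
  expect_equal(o$or_value, exp(0.12))
  expect_equal(o$or_ci, exp(c(0.02, 0.22)))
  expect_equal(logodds_to_or(0, -1, 1)$or_value, 1)
})
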