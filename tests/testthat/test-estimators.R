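# Estimator correctness against independent oracles and known constructions.

test_that("Wald ratio matches arithmetic and its delta-method se", {
  est <- wald_ratio(list(beta_exp = 0.1, se_exp = 0.02,
                         beta_out = 0.05, se_out = 0.01))
  expect_equal(est$beta, 0.5)

  # zero exposure uncertainty: se collapses to se_out/|beta_exp|
  est2 <- wald_ratio(list(beta_exp = 0.2, se_exp = 0,
                          beta_out = 0.1, se_out = 0.04))
  expect_equal(est2$se, 0.2)

  # finite-difference propagation oracle on a random row
  set.seed(42)
  row <- list(beta_exp = 0.31, se_exp = 0.022, beta_out = 0.12,
              se_out = 0.05)
  f <- function(bx, by) by / bx
  eps <- 1e-6
  g_bx <- (f(row$beta_exp + eps, row$beta_out) -
             f(row$beta_exp - eps, row$beta_out)) / (2 * eps)
  g_by <- (f(row$beta_exp, row$beta_out + eps) -
             f(row$beta_exp, row$beta_out - eps)) / (2 * eps)
  se_num <- sqrt(g_bx^2 * row$se_exp^2 + g_by^2 * row$se_out^2)
  expect_equal(wald_ratio(row)$se, se_num, tolerance = 1e-6)

  expect_error(wald_ratio(list(beta_exp = 0, se_exp = 1, beta_out = 1,
                               se_out = 1)),
               class = "mrmediate_undefined_ratio_error")
})

test_that("IVW on one SNP equals the Wald ratio; homogeneous ratios collapse", {
  h <- random_hset(1, seed = 2)
  expect_equal(ivw(h)$beta, wald_ratio(h[1, ])$beta)

  # all SNPs share ratio r: beta = r, Q = 0, fixed == random
  bx <- c(0.2, 0.3, 0.4)
  h2 <- harmonized_set(paste0("rs", 1:3), bx, rep(0.01, 3),
                       0.5 * bx, rep(0.02, 3))
  f <- ivw(h2, "fixed"); r <- ivw(h2, "multiplicative_random")
  expect_equal(f$beta, 0.5)
  expect_equal(f$extra$q_stat, 0, tolerance = 1e-20)
  expect_equal(f$se, r$se)
})

test_that("IVW matches the closed-form WLS oracle to 1e-10", {
  for (seed in 1:20) {
    h <- random_hset(10, seed = seed)
    w <- 1 / h$se_out^2
    orc <- wls_oracle(matrix(h$beta_exp, ncol = 1), h$beta_out, w)
    est_f <- ivw(h, "fixed")
    expect_equal(est_f$beta, orc$coef, tolerance = 1e-10)
    expect_equal(est_f$se, sqrt(orc$cov_unscaled[1, 1]), tolerance = 1e-10)
    est_r <- ivw(h, "multiplicative_random")
    scale <- max(1, sqrt(orc$rss / (nrow(h) - 1)))
    expect_equal(est_r$se, sqrt(orc$cov_unscaled[1, 1]) * scale,
                 tolerance = 1e-10)
  }
})

test_that("Egger recovers exact linear data and matches the WLS oracle", {
  bx <- seq(0.1, 0.5, length.out = 8)
  h <- harmonized_set(paste0("rs", 1:8), bx, rep(0.01, 8),
                      0.02 + 0.4 * bx, rep(0.03, 8))
  est <- mr_egger(h)
  expect_equal(est$beta, 0.4, tolerance = 1e-12)
  expect_equal(est$extra$egger_intercept, 0.02, tolerance = 1e-12)
  expect_equal(est$extra$residual_scale, 1)  # floored: exact fit

  for (seed in 1:20) {
    h <- random_hset(12, seed = seed + 100)
    flip <- sign(h$beta_exp)
    X <- cbind(1, h$beta_exp * flip)
    orc <- wls_oracle(X, h$beta_out * flip, 1 / h$se_out^2)
    est <- mr_egger(h)
    expect_equal(est$beta, orc$coef[2], tolerance = 1e-10)
    expect_equal(est$extra$egger_intercept, orc$coef[1], tolerance = 1e-10)
    scale <- max(1, sqrt(orc$rss / (nrow(h) - 2)))
    expect_equal(est$se, sqrt(orc$cov_unscaled[2, 2]) * scale,
                 tolerance = 1e-10)
    expect_equal(est$extra$intercept_se,
                 sqrt(orc$cov_unscaled[1, 1]) * scale, tolerance = 1e-10)
  }
})

test_that("weighted median interpolates cumulative weights and is robust", {
  # equal weights, ratios {1,2,3} -> 2
  h <- harmonized_set(paste0("rs", 1:3), rep(1, 3), rep(1e-9, 3),
                      c(1, 2, 3), rep(0.1, 3))
  expect_equal(weighted_median(h, n_boot = 50, seed = 1)$beta, 2)

  # one wild outlier among 9 concordant stays in the concordant cluster
  set.seed(8)
  bx <- runif(10, 0.2, 0.5)
  by <- 0.5 * bx
  by[10] <- 8 * bx[10]
  h2 <- harmonized_set(paste0("rs", 1:10), bx, rep(0.01, 10),
                       by, rep(0.02, 10))
  est <- weighted_median(h2, n_boot = 100, seed = 2)
  expect_lt(abs(est$beta - 0.5), 0.1)

  # oracle equivalence and bootstrap determinism
  h3 <- random_hset(20, seed = 55)
  r <- h3$beta_out / h3$beta_exp
  v <- h3$se_out^2 / h3$beta_exp^2 + h3$beta_out^2 * h3$se_exp^2 /
    h3$beta_exp^4
  expect_equal(weighted_median(h3, n_boot = 100, seed = 9)$beta,
               wmedian_oracle(r, 1 / v), tolerance = 1e-12)
  e1 <- weighted_median(h3, n_boot = 200, seed = 10)
  e2 <- weighted_median(h3, n_boot = 200, seed = 10)
  expect_identical(e1$se, e2$se)
})

test_that("mode estimators find the plurality cluster and match the grid oracle", {
  # identical ratios: point mass
  h <- harmonized_set(paste0("rs", 1:4), rep(0.3, 4), rep(0.01, 4),
                      rep(0.12, 4), rep(0.02, 4))
  expect_equal(mode_estimate(h, n_boot = 20, seed = 1)$beta, 0.4,
               tolerance = 1e-9)

  # 7 ratios near 0.5, 3 near 3.0 -> mode near 0.5
  set.seed(12)
  r <- c(rnorm(7, 0.5, 0.02), rnorm(3, 3, 0.02))
  h2 <- harmonized_set(paste0("rs", 1:10), rep(1, 10), rep(0.01, 10),
                       r, rep(0.05, 10))
  est <- mode_estimate(h2, weighted = FALSE, n_boot = 20, seed = 3)
  expect_lt(abs(est$beta - 0.5), 0.2)

  # grid oracle equivalence, weighted and simple
  h3 <- random_hset(15, seed = 77)
  rat <- h3$beta_out / h3$beta_exp
  v <- h3$se_out^2 / h3$beta_exp^2 + h3$beta_out^2 * h3$se_exp^2 /
    h3$beta_exp^4
  for (wflag in c(TRUE, FALSE)) {
    w <- if (wflag) 1 / v else rep(1, 15)
    est <- mode_estimate(h3, weighted = wflag, n_boot = 20, seed = 4)
    expect_equal(est$beta, mode_oracle(rat, w), tolerance = 1e-3)
  }
})

test_that("OR conversion follows exp(beta +/- 1.96 se) and is monotone", {
  est <- ivw(random_hset(5, seed = 3))
  est$beta <- 0; est$se <- 0.1
  est <- to_odds_ratio(est)
  expect_equal(est$or_, 1)
  expect_equal(est$ci_low, exp(-qnorm(0.975) * 0.1))
  expect_equal(est$ci_high, exp(qnorm(0.975) * 0.1))
  # idempotent
  expect_equal(to_odds_ratio(est), est)

  # display convention: log(1.04) with the CI half-width of (1.01, 1.07)
  b <- log(1.04); s <- (log(1.07) - log(1.01)) / (2 * qnorm(0.975))
  est$beta <- b; est$se <- s
  est <- to_odds_ratio(est)
  expect_equal(round(est$or_, 2), 1.04)
  expect_equal(round(est$ci_low, 2), 1.01)
  expect_equal(round(est$ci_high, 2), 1.07)

  set.seed(6)
  betas <- sort(rnorm(20))
  ors <- exp(betas)
  expect_true(all(diff(ors) > 0))
})

test_that("estimators are invariant to row order and per-SNP sign flips", {
  h <- random_hset(12, seed = 91)
  perm <- sample.int(12)
  hp <- harmonized_set(h$snp_id[perm], h$beta_exp[perm], h$se_exp[perm],
                       h$beta_out[perm], h$se_out[perm])
  flip <- sample(c(-1, 1), 12, replace = TRUE)
  hf <- harmonized_set(h$snp_id, flip * h$beta_exp, h$se_exp,
                       flip * h$beta_out, h$se_out)
  for (href in list(hp, hf)) {
    expect_equal(ivw(h)$beta, ivw(href)$beta, tolerance = 1e-12)
    expect_equal(ivw(h)$se, ivw(href)$se, tolerance = 1e-12)
    expect_equal(mr_egger(h)$beta, mr_egger(href)$beta, tolerance = 1e-12)
  }
  # median/mode point estimates are order/sign invariant too
  expect_equal(weighted_median(h, 50, seed = 1)$beta,
               weighted_median(hf, 50, seed = 1)$beta, tolerance = 1e-12)
})

test_that("directional pleiotropy under InSiDE biases IVW but not the Egger slope", {
  set.seed(1234)
  theta <- 0.1; alpha_mean <- 0.01
  n_rep <- 300
  ivw_est <- egger_est <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    bx <- runif(50, 0.15, 0.45)
    alpha <- rnorm(50, alpha_mean, 0.003)  # direct effects independent of bx
    by <- theta * bx + alpha + rnorm(50, 0, 0.01)
    h <- harmonized_set(paste0("rs", 1:50), bx, rep(1e-6, 50), by,
                        rep(0.01, 50))
    ivw_est[i] <- ivw(h)$beta
    egger_est[i] <- mr_egger(h)$beta
  }
  mc_se_egger <- sd(egger_est) / sqrt(n_rep)
  mc_se_ivw <- sd(ivw_est) / sqrt(n_rep)
  expect_lt(abs(mean(egger_est) - theta), 3 * mc_se_egger)
  expect_gt(mean(ivw_est) - theta, 3 * mc_se_ivw)  # upward-biased
})
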