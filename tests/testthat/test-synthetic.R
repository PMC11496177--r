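# The synthetic study generator: determinism, null calibration, truth wiring.

test_that("same config and seed give byte-identical studies", {
  cfg <- sim_config(seed = 101, n_snp = 10, n_null_snp = 20)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(as.data.frame(s1$exposure), as.data.frame(s2$exposure))
  expect_identical(as.data.frame(s1$outcome), as.data.frame(s2$outcome))
  expect_identical(s1$truth$gamma, s2$truth$gamma)

  tmp1 <- withr::local_tempfile(); tmp2 <- withr::local_tempfile()
  write_summary_stats(s1$mediator, tmp1)
  write_summary_stats(s2$mediator, tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))
})

test_that("truth encodes the decomposition and proportion identities", {
  cfg <- sim_config(seed = 5, theta_total = 0.05, beta_a = 0.3,
                    beta_b = 0.02)
  st <- simulate_study(cfg)
  expect_equal(st$truth$direct + st$truth$beta_a * st$truth$beta_b,
               st$truth$theta_total)
  expect_equal(st$truth$true_proportion_pct, 100 * 0.3 * 0.02 / 0.05)
  expect_equal(length(st$truth$gamma), cfg$n_snp)
  expect_true(all(abs(st$truth$gamma) >= cfg$gamma_sd))
})

test_that("null-SNP p-values are uniform (KS test at alpha 0.01)", {
  cfg <- sim_config(seed = 77, n_snp = 5, n_snp_med = 5, n_null_snp = 10000)
  st <- simulate_study(cfg)
  nulls <- st$truth$owner == 0L
  p_exp <- st$exposure$pvalue[nulls]
  ks <- suppressWarnings(ks.test(p_exp, "punif"))
  expect_gt(ks$p.value, 0.01)
  ks_out <- suppressWarnings(ks.test(st$outcome$pvalue[nulls], "punif"))
  expect_gt(ks_out$p.value, 0.01)
})

test_that("SE scaling tracks sample size and case fraction", {
  cfg <- sim_config(seed = 3, n_snp = 5, n_null_snp = 5)
  st <- simulate_study(cfg)
  maf <- st$exposure$eaf
  expect_equal(st$exposure$se, 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exp))
  cf <- cfg$case_fraction_out
  expect_equal(st$outcome$se,
               1 / sqrt(2 * maf * (1 - maf) * cfg$n_out * cf * (1 - cf)))
})

test_that("pipeline IVW recovers the planted total effect on a precise study", {
  cfg <- sim_config(seed = 19, n_snp = 40, n_null_snp = 20,
                    n_exp = 5e5, n_out = 5e6)
  st <- simulate_study(cfg)
  rep <- run_pair(st$exposure, st$outcome, st$panel,
                  pipeline_config(seed = 2, n_boot = 50, presso_nsim = 50))
  est <- rep$estimates[rep$estimates$method == "ivw", ]
  expect_lt(abs(est$beta - cfg$theta_total), 3 * est$se)
})

test_that("beta_a = 0 yields zero true proportion and a null mediated estimate", {
  cfg <- sim_config(seed = 23, beta_a = 0, n_snp = 30, n_null_snp = 10)
  st <- simulate_study(cfg)
  expect_equal(st$truth$true_proportion_pct, 0)
  pc <- pipeline_config(seed = 4, n_boot = 50, presso_nsim = 50)
  exp_rep <- run_pair(st$exposure, st$outcome, st$panel, pc)
  med_rep <- run_pair(st$mediator, st$outcome, st$panel, pc)
  leg <- run_pair(st$exposure, st$mediator, st$panel, pc)
  tri <- two_step_mediation(ivw(leg$hset), ivw(med_rep$hset),
                            ivw(exp_rep$hset))
  expect_true(tri$mediated_ci[1] <= 0 && 0 <= tri$mediated_ci[2])
})

test_that("LD echo blocks are clumped down to one variant per block", {
  cfg <- sim_config(seed = 55, n_snp = 10, n_null_snp = 0,
                    ld = list(n_blocks = 4, block_size = 3, within_r2 = 0.9))
  st <- simulate_study(cfg)
  expect_equal(nrow(st$exposure), 10 + 10 + 4 * 2)
  clumped <- ld_clump(filter_by_pvalue(st$exposure, 1e-5), st$panel,
                      0.001, 10000)
  # no retained pair may sit in one echo block
  base <- sub("_e[0-9]+$", "", clumped$snp_id)
  expect_false(any(duplicated(base)))
})

test_that("palindrome injection produces strand-ambiguous variants", {
  cfg <- sim_config(seed = 66, n_snp = 50, n_null_snp = 0,
                    palindrome_frac = 0.5)
  st <- simulate_study(cfg)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  frac <- mean(st$exposure$other_allele ==
                 comp[st$exposure$effect_allele])
  expect_gt(frac, 0.3); expect_lt(frac, 0.7)
})

test_that("fixture suite writes four studies with a manifest that round-trips", {
  tmp <- withr::local_tempdir()
  manifest <- suppressMessages(make_fixture_suite(tmp, seed = 11))
  files <- list.files(tmp)
  for (nm in c("clean", "directional", "outlier", "weak")) {
    for (role in c("exposure", "mediator", "outcome")) {
      expect_true(paste0(nm, "_", role, ".tsv") %in% files)
    }
  }
  back <- read_manifest(file.path(tmp, "manifest.tsv"))
  expect_equal(back[["clean.theta_total"]], manifest[["clean.theta_total"]])
  expect_equal(back[["clean.true_proportion_pct"]],
               manifest[["clean.true_proportion_pct"]])

  # weak-instrument fixture: at least half the instruments fail F >= 10
  weak <- read_summary_stats(file.path(tmp, "weak_exposure.tsv"))
  f <- (weak$beta / weak$se)^2
  iv_rows <- utils::head(order(weak$pvalue), 30)  # instrument candidates
  expect_gte(mean(f[iv_rows] < 10), 0.5)
})

test_that("the directional-pleiotropy fixture shows a significant Egger intercept", {
  cfg <- sim_config(pleiotropy = list(mode = "directional", sd = 0.003,
                                      mean = 0.015),
                    seed = 20240101)
  st <- simulate_study(cfg)
  ivs <- suppressMessages(select_instruments(st$exposure, st$panel))
  h <- suppressMessages(harmonize(ivs, st$outcome))
  eg <- mr_egger(h)
  expect_lt(eg$extra$intercept_p, 0.05)
  # and the clean study at the same scale does not
  st0 <- simulate_study(sim_config(seed = 20240101))
  h0 <- suppressMessages(harmonize(
    suppressMessages(select_instruments(st0$exposure, st0$panel)),
    st0$outcome))
  expect_gt(mr_egger(h0)$extra$intercept_p, 0.05)
})
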