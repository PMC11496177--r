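# Instrument selection: p-value screen, LD clumping, F filter, harmonization.

test_that("p-value screen keeps exactly the sub-threshold rows in order", {
  tab <- random_summary_stats(100, seed = 3)
  out <- filter_by_pvalue(tab, 0.3)
  expect_equal(out$snp_id, tab$snp_id[tab$pvalue < 0.3])

  two <- tab[1:2, ]
  two$pvalue <- c(1e-6, 1e-4)
  two <- summary_stats(two)
  kept <- filter_by_pvalue(two, 1e-5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$pvalue, 1e-6)
})

test_that("clumping drops the linked weaker SNP and keeps unlinked pairs", {
  df <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1",
                   pos = c(1e6, 1.5e6), effect_allele = "A",
                   other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.01,
                   pvalue = c(1e-8, 1e-6), n = 1000)
  tab <- summary_stats(df)
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(df$snp_id, df$snp_id))
  pan <- ld_panel(df$snp_id, r2)
  out <- ld_clump(tab, pan, 0.001, 10000)
  expect_equal(out$snp_id, "rs1")

  pan0 <- ld_panel(df$snp_id, diag(2))
  expect_equal(ld_clump(tab, pan0, 0.001, 10000)$snp_id, c("rs1", "rs2"))
})

test_that("clumping is order-invariant and never retains a violating pair", {
  set.seed(5)
  for (rep in 1:10) {
    tab <- random_summary_stats(20)
    # block-diagonal panel over position-sorted variants
    ord <- order(tab$chrom, tab$pos)
    blocks <- split(tab$snp_id[ord], rep(1:5, each = 4))
    r2 <- diag(1, 20)
    dimnames(r2) <- list(tab$snp_id, tab$snp_id)
    for (b in blocks) {
      r2[b, b] <- runif(1, 0.2, 0.95)
    }
    diag(r2) <- 1
    pan <- ld_panel(tab$snp_id, r2)
    out <- ld_clump(tab, pan, 0.1, 5000)

    shuffled <- summary_stats(as.data.frame(tab)[sample.int(20), ],
                              trait_id = trait_id(tab))
    out2 <- ld_clump(shuffled, pan, 0.1, 5000)
    expect_setequal(out$snp_id, out2$snp_id)

    if (nrow(out) >= 2) {
      pairs <- t(combn(nrow(out), 2))
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        violates <- out$chrom[i] == out$chrom[j] &&
          abs(out$pos[i] - out$pos[j]) <= 5000 * 1000 &&
          ld_r2(pan, out$snp_id[i], out$snp_id[j]) >= 0.1
        expect_false(violates)
      }
    }
  }
})

test_that("F statistics use (beta/se)^2 and the F < 10 rule removes weak rows", {
  df <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1", pos = c(1L, 2L),
                   effect_allele = "A", other_allele = "G", eaf = 0.3,
                   beta = c(0.1, 0.01), se = 0.02, pvalue = 0.5, n = 100)
  ivs <- compute_f_statistics(summary_stats(df))
  expect_equal(ivs$snp_id, "rs1")
  expect_equal(ivs$f_stat, 25)  # (0.1/0.02)^2

  tab <- random_summary_stats(50, seed = 9)
  ivs <- compute_f_statistics(tab)
  expect_setequal(ivs$snp_id, tab$snp_id[(tab$beta / tab$se)^2 >= 10])
})

test_that("selection chain is idempotent", {
  st <- simulate_study(sim_config(seed = 31, n_snp = 25,
                                  ld = list(n_blocks = 5, block_size = 3,
                                            within_r2 = 0.8)))
  once <- select_instruments(st$exposure, st$panel)
  tab_once <- summary_stats(as.data.frame(once)[, 1:10], trait_id = "exposure")
  twice <- select_instruments(tab_once, st$panel)
  expect_equal(as.data.frame(twice), as.data.frame(once))
})

make_pair <- function(ea_x, oa_x, ea_y, oa_y, beta_out = 0.3,
                      eaf_x = 0.3, eaf_y = 0.3) {
  exp_df <- data.frame(snp_id = "rs1", chrom = "1", pos = 100L,
                       effect_allele = ea_x, other_allele = oa_x,
                       eaf = eaf_x, beta = 0.2, se = 0.02, pvalue = 1e-8,
                       n = 1000)
  out_df <- data.frame(snp_id = "rs1", chrom = "1", pos = 100L,
                       effect_allele = ea_y, other_allele = oa_y,
                       eaf = eaf_y, beta = beta_out, se = 0.05, pvalue = 0.01,
                       n = 5000)
  list(exposure = summary_stats(exp_df, "x"),
       outcome = summary_stats(out_df, "y"))
}

test_that("harmonize flips the outcome beta when alleles are swapped", {
  p <- make_pair("A", "G", "G", "A")
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(h$beta_out, -0.3)
  expect_equal(h$eaf_out, 0.7)

  p2 <- make_pair("A", "G", "A", "G")
  expect_equal(harmonize(p2$exposure, p2$outcome)$beta_out, 0.3)

  # strand-flipped report of the same orientation: no sign change
  p3 <- make_pair("A", "G", "T", "C")
  expect_equal(harmonize(p3$exposure, p3$outcome)$beta_out, 0.3)
})

test_that("palindromic variants follow the policy", {
  amb <- make_pair("A", "T", "A", "T", eaf_x = 0.5, eaf_y = 0.5)
  expect_error(harmonize(amb$exposure, amb$outcome, "drop"),
               class = "mrmediate_insufficient_instruments")
  expect_error(harmonize(amb$exposure, amb$outcome, "infer_by_eaf"),
               class = "mrmediate_insufficient_instruments")

  # informative frequencies, same strand: retained with no flip
  inf <- make_pair("A", "T", "A", "T", eaf_x = 0.10, eaf_y = 0.12)
  h <- harmonize(inf$exposure, inf$outcome, "infer_by_eaf")
  expect_equal(h$beta_out, 0.3)

  # informative frequencies on opposite sides: treated as flipped
  opp <- make_pair("A", "T", "A", "T", eaf_x = 0.10, eaf_y = 0.88)
  h2 <- harmonize(opp$exposure, opp$outcome, "infer_by_eaf")
  expect_equal(h2$beta_out, -0.3)
})

test_that("mismatching allele pairs and absent variants are dropped with counts", {
  p <- make_pair("A", "G", "A", "C")
  expect_error(harmonize(p$exposure, p$outcome),
               class = "mrmediate_insufficient_instruments")
  err <- tryCatch(harmonize(p$exposure, p$outcome), error = identity)
  expect_equal(unname(err$counts["allele_mismatch"]), 1)
})

test_that("harmonization is involution-safe: flipping exposure alleles leaves estimates unchanged", {
  st <- simulate_study(sim_config(seed = 17, n_snp = 20, n_null_snp = 10))
  ivs <- select_instruments(st$exposure, st$panel)
  h1 <- harmonize(ivs, st$outcome)

  flipped <- as.data.frame(ivs)[, 1:10]
  tmp <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  ivs2 <- compute_f_statistics(summary_stats(flipped, "exposure"))
  h2 <- harmonize(ivs2, st$outcome)

  expect_equal(ivw(h1)$beta, ivw(h2)$beta, tolerance = 1e-12)
  expect_equal(ivw(h1)$se, ivw(h2)$se, tolerance = 1e-12)
  expect_equal(mr_egger(h1)$beta, mr_egger(h2)$beta, tolerance = 1e-12)
})
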