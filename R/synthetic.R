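# Synthetic GWAS summary-statistic studies with a known
# exposure -> mediator -> outcome causal chain.
#
# Summary statistics are generated directly, without individual-level
# genotypes: the standard large-sample scale for a per-allele effect on a
# standardized continuous trait is se = 1/sqrt(2 maf (1-maf) n), additionally
# divided by sqrt(cf (1-cf)) for a binary (logistic) outcome with case
# fraction cf. Instruments get true effects drawn from a normal truncated
# away from zero so that the F > 10 filter keeps them, mirroring the
# post-selection instrument sets real pipelines operate on.

#' Configuration for a synthetic mediation study
#'
#' Defaults emulate the scale of a molecular-trait mediation study: a small
#' exposure GWAS (n = 3757), a moderate mediator GWAS (n = 8299), and a large
#' binary-outcome GWAS (n = 977,323 with case fraction 47,309/977,323). True
#' effects default to a total exposure-to-outcome log-OR of 0.04 per SD,
#' an exposure-to-mediator effect of 0.2 SD/SD and a mediator-to-outcome
#' log-OR of 0.033 per SD, giving a true mediated proportion of 16.5%.
#'
#' @param n_snp exposure instrument count.
#' @param n_snp_med mediator-specific instrument count (the mediator needs
#'   its own instruments for the mediator-to-outcome leg; the exposure's
#'   instruments reach the outcome through the direct path too and would be
#'   pleiotropic for that leg).
#' @param n_null_snp unassociated variants included in every table.
#' @param gamma_sd SD of true instrument effects; draws are truncated to
#'   `|effect| >= gamma_sd` so instruments are strong.
#' @param theta_total true total exposure-to-outcome effect (log-OR per SD).
#' @param beta_a true exposure-to-mediator effect (SD per SD).
#' @param beta_b true mediator-to-outcome effect (log-OR per SD).
#' @param pleiotropy list(mode = "none"/"balanced"/"directional", sd, mean):
#'   per-instrument direct effects on the outcome (and mediator) bypassing
#'   the exposure. "balanced" draws from N(0, sd^2); "directional" from
#'   N(mean, sd^2).
#' @param n_exp,n_med,n_out GWAS sample sizes driving the SE scale.
#' @param case_fraction_out case fraction of the binary outcome GWAS.
#' @param ld list(n_blocks, block_size, within_r2): the first `n_blocks`
#'   exposure instruments each gain `block_size - 1` correlated "echo"
#'   variants at r^2 = within_r2 within 10 kb, for clumping tests. Across
#'   blocks r^2 = 0.
#' @param palindrome_frac fraction of variants given strand-ambiguous (A/T or
#'   C/G) allele pairs, for harmonization tests.
#' @param seed mandatory integer seed.
#' @return a `sim_config` list; `direct` is derived so that
#'   `theta_total = direct + beta_a * beta_b` by construction.
#' @export
sim_config <- function(n_snp = 30, n_snp_med = n_snp, n_null_snp = 100,
                       gamma_sd = 0.15, theta_total = 0.04,
                       beta_a = 0.2, beta_b = 0.033,
                       pleiotropy = list(mode = "none", sd = 0, mean = 0),
                       n_exp = 3757, n_med = 8299, n_out = 977323,
                       case_fraction_out = 47309 / 977323,
                       ld = list(n_blocks = 0, block_size = 1,
                                 within_r2 = 0.8),
                       palindrome_frac = 0, seed) {
  assert_that(!missing(seed), "seed is mandatory", "mrmediate_config_error")
  assert_that(gamma_sd >= 0 && pleiotropy$sd >= 0,
              "effect SDs must be non-negative", "mrmediate_config_error")
  pleiotropy$mode <- match.arg(pleiotropy$mode,
                               c("none", "balanced", "directional"))
  structure(list(
    n_snp = n_snp, n_snp_med = n_snp_med, n_null_snp = n_null_snp,
    gamma_sd = gamma_sd, theta_total = theta_total,
    beta_a = beta_a, beta_b = beta_b,
    direct = theta_total - beta_a * beta_b,
    pleiotropy = pleiotropy,
    n_exp = n_exp, n_med = n_med, n_out = n_out,
    case_fraction_out = case_fraction_out,
    ld = ld, palindrome_frac = palindrome_frac, seed = as.integer(seed)
  ), class = "sim_config")
}

# truncated normal: |x| >= lower, sd-scaled
rtrunc_away <- function(n, sd, lower) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(0, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    x <- stats::rnorm(length(need), 0, sd)
    ok <- abs(x) >= lower
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

draw_alleles <- function(m, palindrome_frac) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ea <- sample(bases, m, replace = TRUE)
  is_pal <- stats::runif(m) < palindrome_frac
  oa <- vapply(seq_len(m), function(i) {
    if (is_pal[i]) comp[[ea[i]]]
    else sample(setdiff(bases, c(ea[i], comp[[ea[i]]])), 1)
  }, character(1))
  data.frame(effect_allele = ea, other_allele = oa,
             stringsAsFactors = FALSE)
}

draw_pleiotropy <- function(n, pleio) {
  switch(pleio$mode,
         none = rep(0, n),
         balanced = stats::rnorm(n, 0, pleio$sd),
         directional = stats::rnorm(n, pleio$mean, pleio$sd))
}

make_trait_table <- function(roster, true_beta, se, trait_id) {
  beta_hat <- stats::rnorm(nrow(roster), true_beta, se)
  p <- 2 * stats::pnorm(-abs(beta_hat / se))
  summary_stats(data.frame(
    snp_id = roster$snp_id, chrom = roster$chrom, pos = roster$pos,
    effect_allele = roster$effect_allele, other_allele = roster$other_allele,
    eaf = roster$eaf, beta = beta_hat, se = se,
    pvalue = pmax(p, .Machine$double.xmin), n = roster$n,
    stringsAsFactors = FALSE), trait_id = trait_id)
}

#' Simulate a full mediation scan study
#'
#' Generates one shared variant roster and per-trait summary-statistic tables
#' for: the causal exposure, `n_decoy_exposures` decoy exposures (own
#' instruments, no effect on mediators or outcome), the true mediator,
#' `n_decoy_mediators` decoy mediators (own instruments, no outcome effect),
#' and the outcome. Every table covers the whole roster, as a genome-wide
#' GWAS would. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @param n_decoy_exposures,n_decoy_mediators decoy trait counts (default 0).
#' @return list with `exposures` (list of `summary_stats`, causal first),
#'   `mediators` (true first), `outcome`, `panel` (`ld_panel`) and `truth`
#'   (`sim_truth`: per-variant effects and the generating parameters,
#'   including `true_proportion_pct = 100 beta_a beta_b / theta_total`).
#' @export
simulate_scan_study <- function(config, n_decoy_exposures = 0,
                                n_decoy_mediators = 0) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config$case_fraction_out

  n_exp_traits <- 1 + n_decoy_exposures
  n_med_traits <- 1 + n_decoy_mediators
  m <- n_exp_traits * config$n_snp + n_med_traits * config$n_snp_med +
    config$n_null_snp

  owner <- c(rep(seq_len(n_exp_traits), each = config$n_snp),
             rep(-seq_len(n_med_traits), each = config$n_snp_med),
             rep(0L, config$n_null_snp))

  roster <- data.frame(
    snp_id = sprintf("rs%05d", seq_len(m)),
    chrom = as.character(rep_len(1:22, m)),
    pos = sample.int(2.4e8, m) + 1e6,
    eaf = stats::runif(m, 0.05, 0.5),
    stringsAsFactors = FALSE)
  roster <- cbind(roster, draw_alleles(m, config$palindrome_frac))

  # true per-variant effects on each trait
  gamma <- matrix(0, m, n_exp_traits)   # on exposures
  delta <- matrix(0, m, n_med_traits)   # instrument effects on mediators
  for (t in seq_len(n_exp_traits)) {
    idx <- owner == t
    gamma[idx, t] <- rtrunc_away(sum(idx), config$gamma_sd, config$gamma_sd)
  }
  for (t in seq_len(n_med_traits)) {
    idx <- owner == -t
    delta[idx, t] <- rtrunc_away(sum(idx), config$gamma_sd, config$gamma_sd)
  }

  # pleiotropic direct effects of the causal exposure's instruments
  causal_idx <- which(owner == 1L)
  alpha_out <- numeric(m)
  alpha_med <- numeric(m)
  alpha_out[causal_idx] <- draw_pleiotropy(length(causal_idx),
                                           config$pleiotropy)
  alpha_med[causal_idx] <- draw_pleiotropy(length(causal_idx),
                                           config$pleiotropy)

  true_med <- delta  # mediator true effects: own instruments...
  true_med[, 1] <- true_med[, 1] + gamma[, 1] * config$beta_a + alpha_med
  true_out <- gamma[, 1] * config$theta_total +
    delta[, 1] * config$beta_b + alpha_out

  # LD echo blocks: correlated companions of the first n_blocks causal
  # exposure instruments, with attenuated true effects r * beta_parent
  block_pairs <- NULL
  if (config$ld$n_blocks > 0 && config$ld$block_size > 1) {
    parents <- causal_idx[seq_len(min(config$ld$n_blocks,
                                      length(causal_idx)))]
    rho <- sqrt(config$ld$within_r2)
    n_echo <- config$ld$block_size - 1
    for (p in parents) {
      ids <- paste0(roster$snp_id[p], "_e", seq_len(n_echo))
      add <- roster[rep(p, n_echo), , drop = FALSE]
      add$snp_id <- ids
      add$pos <- roster$pos[p] + seq_len(n_echo) * 1000
      roster <- rbind(roster, add)
      gamma <- rbind(gamma, rho * gamma[rep(p, n_echo), , drop = FALSE])
      delta <- rbind(delta, rho * delta[rep(p, n_echo), , drop = FALSE])
      true_med <- rbind(true_med,
                        rho * true_med[rep(p, n_echo), , drop = FALSE])
      true_out <- c(true_out, rho * true_out[rep(p, n_echo)])
      owner <- c(owner, rep(99L, n_echo))
      block_pairs <- rbind(block_pairs,
                           expand.grid(a = c(roster$snp_id[p], ids),
                                       b = c(roster$snp_id[p], ids),
                                       stringsAsFactors = FALSE))
    }
    m <- nrow(roster)
    rownames(roster) <- NULL
  }

  base_se <- 1 / sqrt(2 * roster$eaf * (1 - roster$eaf))
  se_exp <- base_se / sqrt(config$n_exp)
  se_med <- base_se / sqrt(config$n_med)
  se_out <- base_se / sqrt(config$n_out * cf * (1 - cf))

  exposures <- lapply(seq_len(n_exp_traits), function(t) {
    r <- roster; r$n <- config$n_exp
    make_trait_table(r, gamma[, t],
                     se_exp, if (t == 1) "exposure" else paste0("decoy_exp_", t - 1))
  })
  mediators <- lapply(seq_len(n_med_traits), function(t) {
    r <- roster; r$n <- config$n_med
    make_trait_table(r, true_med[, t],
                     se_med, if (t == 1) "mediator" else paste0("decoy_med_", t - 1))
  })
  r <- roster; r$n <- config$n_out
  outcome <- make_trait_table(r, true_out, se_out, "outcome")

  # The LD panel covers instrument-candidate variants (suggestive p in any
  # trait) plus all echo-block members, as a reference-panel extract for
  # clumping would; variants outside it are unlinked by construction anyway.
  pmin_all <- do.call(pmin, c(lapply(exposures, `[[`, "pvalue"),
                              lapply(mediators, `[[`, "pvalue"),
                              list(outcome$pvalue)))
  cand <- roster$snp_id[pmin_all < 1e-3]
  if (!is.null(block_pairs)) {
    cand <- union(cand, unique(c(block_pairs$a, block_pairs$b)))
  }
  cand <- roster$snp_id[roster$snp_id %in% cand]  # keep roster order
  r2 <- diag(1, length(cand))
  dimnames(r2) <- list(cand, cand)
  if (!is.null(block_pairs)) {
    r2[cbind(block_pairs$a, block_pairs$b)] <- config$ld$within_r2
    diag(r2) <- 1
  }
  panel <- ld_panel(cand, r2,
                    positions = roster$pos[match(cand, roster$snp_id)])

  truth <- structure(list(
    gamma = gamma[causal_idx, 1], snp_id = roster$snp_id,
    owner = owner,
    alpha_out = c(alpha_out, rep(0, nrow(roster) - length(alpha_out))),
    theta_total = config$theta_total, beta_a = config$beta_a,
    beta_b = config$beta_b, direct = config$direct,
    true_proportion_pct = 100 * config$beta_a * config$beta_b /
      config$theta_total,
    config = config
  ), class = "sim_truth")

  list(exposures = exposures, mediators = mediators, outcome = outcome,
       panel = panel, truth = truth)
}

#' Simulate one exposure/mediator/outcome trio
#'
#' Convenience wrapper around [simulate_scan_study()] with no decoy traits.
#'
#' @param config a [sim_config()].
#' @return list with `exposure`, `mediator`, `outcome` (`summary_stats`),
#'   `panel` (`ld_panel`) and `truth` (`sim_truth`).
#' @export
simulate_study <- function(config) {
  s <- simulate_scan_study(config, 0, 0)
  list(exposure = s$exposures[[1]], mediator = s$mediators[[1]],
       outcome = s$outcome, panel = s$panel, truth = s$truth)
}

#' Write a canonical fixture suite to disk
#'
#' Four small studies covering the behaviours the pipeline must handle —
#' clean, directional pleiotropy, a single planted outlier, and weak
#' instruments (where at least half the instruments fail F >= 10) — plus a
#' flat key-value manifest of generating truths.
#'
#' @param out_dir writable directory (created if absent).
#' @param seed root seed (default 20240101).
#' @return invisibly, the manifest as a named list.
#' @export
make_fixture_suite <- function(out_dir, seed = 20240101) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfgs <- list(
    clean = sim_config(seed = split_seed(seed, "clean")),
    directional = sim_config(
      pleiotropy = list(mode = "directional", sd = 0.003, mean = 0.015),
      seed = split_seed(seed, "directional")),
    outlier = sim_config(seed = split_seed(seed, "outlier")),
    weak = sim_config(gamma_sd = 0.012, n_exp = 500,
                      seed = split_seed(seed, "weak"))
  )
  manifest <- list()
  for (nm in names(cfgs)) {
    st <- simulate_study(cfgs[[nm]])
    if (nm == "outlier") {
      # plant one grossly pleiotropic instrument: shift its outcome beta
      iv <- which(st$truth$owner == 1L)[1]
      st$outcome$beta[iv] <- st$outcome$beta[iv] + 0.15
      st$outcome$pvalue[iv] <-
        2 * stats::pnorm(-abs(st$outcome$beta[iv] / st$outcome$se[iv]))
      manifest[[paste0(nm, ".outlier_snp")]] <- st$outcome$snp_id[iv]
    }
    for (role in c("exposure", "mediator", "outcome")) {
      write_summary_stats(st[[role]],
                          file.path(out_dir, paste0(nm, "_", role, ".tsv")))
    }
    write_ld_panel(st$panel, file.path(out_dir, paste0(nm, "_ld.tsv")))
    manifest[[paste0(nm, ".theta_total")]] <- st$truth$theta_total
    manifest[[paste0(nm, ".beta_a")]] <- st$truth$beta_a
    manifest[[paste0(nm, ".beta_b")]] <- st$truth$beta_b
    manifest[[paste0(nm, ".true_proportion_pct")]] <-
      st$truth$true_proportion_pct
    manifest[[paste0(nm, ".seed")]] <- cfgs[[nm]]$seed
  }
  writeLines(paste(names(manifest), unlist(lapply(manifest, as.character)),
                   sep = "\t"),
             file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

#' Read a fixture-suite manifest
#' @param path manifest file path.
#' @return named list; numeric values parsed as numeric.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(kv, function(x) {
    v <- suppressWarnings(as.numeric(x[2]))
    if (is.na(v)) x[2] else v
  })
  names(out) <- vapply(kv, `[`, character(1), 1)
  out
}

#' Add a correlated echo block around an index variant
#'
#' Appends `block_size - 1` variants in LD (`r^2 = within_r2`) with the given
#' index variant to a table and panel: each echo sits within 10 kb, carries a
#' correlated effect `sqrt(within_r2) * beta_index` plus fresh noise, and a
#' slightly larger p-value so that greedy clumping retains the index.
#'
#' @param table a `summary_stats`.
#' @param panel the matching `ld_panel`.
#' @param snp_id index variant id.
#' @param block_size total block size including the index.
#' @param within_r2 squared correlation of echoes with the index (and with
#'   each other).
#' @return list(table, panel) with echoes appended.
#' @export
add_ld_block <- function(table, panel, snp_id, block_size = 3,
                         within_r2 = 0.8) {
  i <- match(snp_id, table$snp_id)
  assert_that(!is.na(i), "index snp not in table", "mrmediate_config_error")
  n_echo <- block_size - 1
  if (n_echo <= 0) return(list(table = table, panel = panel))
  echo <- as.data.frame(table)[rep(i, n_echo), , drop = FALSE]
  echo$snp_id <- paste0(table$snp_id[i], "_e", seq_len(n_echo))
  echo$pos <- table$pos[i] + seq_len(n_echo) * 1000
  echo$beta <- sqrt(within_r2) * table$beta[i] +
    stats::rnorm(n_echo, 0, table$se[i] * sqrt(1 - within_r2))
  echo$pvalue <- pmin(1, 2 * stats::pnorm(-abs(echo$beta / echo$se)))
  new_tab <- summary_stats(rbind(as.data.frame(table), echo),
                           trait_id = trait_id(table))
  ids <- c(panel$snp_ids, echo$snp_id)
  r2 <- diag(1, length(ids))
  dimnames(r2) <- list(ids, ids)
  r2[panel$snp_ids, panel$snp_ids] <- panel$r2
  block <- c(table$snp_id[i], echo$snp_id)
  r2[block, block] <- within_r2
  diag(r2) <- 1
  list(table = new_tab, panel = ld_panel(ids, r2))
}
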