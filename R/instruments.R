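# Instrumental-variable selection and exposure/outcome harmonization.
#
# The selection chain follows standard two-sample MR practice: a genome-wide
# screen at p < 1e-5, greedy LD clumping (r^2 < 0.001 within +/-10,000 kb),
# and removal of weak instruments with F < 10.

#' Screen variants on their exposure p-value
#'
#' @param table a `summary_stats` object.
#' @param threshold keep rows with `pvalue` strictly below this (default
#'   `1e-5`, the conventional screen for molecular-trait exposures).
#' @return filtered `summary_stats`, input order preserved.
#' @export
filter_by_pvalue <- function(table, threshold = 1e-5) {
  stopifnot(inherits(table, "summary_stats"))
  assert_that(is.numeric(threshold) && threshold > 0 && threshold < 1 ||
                threshold == 1,
              "threshold must lie in (0, 1]", "mrmediate_config_error")
  out <- table[table$pvalue < threshold, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, trait_id = trait_id(table),
            class = c("summary_stats", "data.frame"))
}

#' Greedy LD clumping
#'
#' PLINK-style clumping: repeatedly take the remaining variant with the
#' smallest p-value as the index, then discard every remaining variant on the
#' same chromosome within `window_kb` of it whose r^2 with the index is at
#' least `r2_threshold`. Ties on p-value break by smaller position, then
#' lexicographic `snp_id`, making the result independent of input row order.
#'
#' @param table a `summary_stats` object.
#' @param panel an `ld_panel`. Variants absent from the panel are treated as
#'   unlinked, with a message.
#' @param r2_threshold squared-correlation cutoff (default 0.001).
#' @param window_kb half-window in kilobases around the index SNP
#'   (default 10000).
#' @return clumped `summary_stats`, retained rows in original table order.
#' @export
ld_clump <- function(table, panel, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(table, "summary_stats"), inherits(panel, "ld_panel"))
  assert_that(r2_threshold >= 0 && r2_threshold <= 1,
              "r2_threshold must lie in [0, 1]", "mrmediate_config_error")
  assert_that(window_kb >= 0, "window_kb must be non-negative",
              "mrmediate_config_error")
  if (nrow(table) == 0) return(table)

  absent <- setdiff(table$snp_id, panel$snp_ids)
  if (length(absent) > 0) {
    log_note("ld_clump: %d variant(s) absent from LD panel, treated as unlinked",
             length(absent))
  }

  ord <- order(table$pvalue, table$pos, table$snp_id)
  remaining <- ord
  keep <- integer(0)
  while (length(remaining) > 0) {
    idx <- remaining[1]
    keep <- c(keep, idx)
    remaining <- remaining[-1]
    if (length(remaining) == 0) break
    same_chr <- table$chrom[remaining] == table$chrom[idx]
    in_window <- abs(table$pos[remaining] - table$pos[idx]) <= window_kb * 1000
    linked <- ld_r2(panel, table$snp_id[remaining],
                    rep(table$snp_id[idx], length(remaining))) >= r2_threshold
    remaining <- remaining[!(same_chr & in_window & linked)]
  }
  out <- table[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, trait_id = trait_id(table),
            class = c("summary_stats", "data.frame"))
}

#' Per-variant instrument-strength F statistics and weak-instrument filter
#'
#' The per-SNP F statistic is approximated by the squared Wald z,
#' `(beta/se)^2` — the standard large-sample form. Variants with F below
#' `min_f` (default 10, the conventional weak-instrument cutoff) are removed.
#'
#' @param table a `summary_stats` object.
#' @param min_f minimum F to retain (default 10).
#' @return an `instrument_set`: the surviving rows with an `f_stat` column and
#'   the exposure's trait id.
#' @export
compute_f_statistics <- function(table, min_f = 10) {
  stopifnot(inherits(table, "summary_stats"))
  f <- (table$beta / table$se)^2
  keep <- f >= min_f
  out <- as.data.frame(table)[keep, , drop = FALSE]
  out$f_stat <- f[keep]
  rownames(out) <- NULL
  structure(out, trait_id = trait_id(table),
            class = c("instrument_set", "data.frame"))
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> exposure '%s': %d instruments, min F = %.1f\n",
              attr(x, "trait_id"), nrow(x),
              if (nrow(x)) min(x$f_stat) else NA_real_))
  invisible(x)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

flip_allele <- function(a) c(A = "T", T = "A", C = "G", G = "C")[a]

#' Harmonize exposure instruments with outcome summary statistics
#'
#' Joins on `snp_id` and aligns the outcome effect to the exposure's effect
#' allele: when the outcome's effect allele equals the exposure's other allele
#' (directly or after strand flip), the outcome beta's sign is flipped.
#' Palindromic variants (A/T, C/G) are strand-ambiguous; by default they are
#' dropped. Under `palindrome_policy = "infer_by_eaf"` they are kept when both
#' effect-allele frequencies fall outside \[0.42, 0.58\] (frequencies then
#' identify the strand); ambiguous ones are still dropped. Allele pairs that
#' match neither directly nor after strand flip are dropped.
#'
#' @param exposure an `instrument_set` (or `summary_stats`) for the exposure.
#' @param outcome a `summary_stats` for the outcome.
#' @param palindrome_policy `"drop"` (default) or `"infer_by_eaf"`.
#' @param eaf_window ambiguity band for eaf-based strand inference.
#' @return a `harmonized_set`: data.frame with columns snp_id, beta_exp,
#'   se_exp, beta_out, se_out, eaf_exp, eaf_out, plus attributes `exposure_id`,
#'   `outcome_id` and `drop_counts`.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop", "infer_by_eaf"),
                      eaf_window = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(outcome, "summary_stats"))
  exp_df <- as.data.frame(exposure)
  out_df <- as.data.frame(outcome)

  m <- match(exp_df$snp_id, out_df$snp_id)
  n_missing <- sum(is.na(m))
  if (n_missing > 0) {
    log_note("harmonize: %d instrument(s) absent from outcome GWAS, dropped",
             n_missing)
  }
  exp_df <- exp_df[!is.na(m), , drop = FALSE]
  out_df <- out_df[m[!is.na(m)], , drop = FALSE]

  ea_x <- exp_df$effect_allele; oa_x <- exp_df$other_allele
  ea_y <- out_df$effect_allele; oa_y <- out_df$other_allele
  pal <- is_palindromic(ea_x, oa_x)

  same <- ea_y == ea_x & oa_y == oa_x
  swapped <- ea_y == oa_x & oa_y == ea_x
  same_flipped <- ea_y == flip_allele(ea_x) & oa_y == flip_allele(oa_x)
  swap_flipped <- ea_y == flip_allele(oa_x) & oa_y == flip_allele(ea_x)

  # For palindromic SNPs the four cases collapse pairwise and allele codes
  # cannot identify the strand; resolve by eaf or drop.
  action <- rep(NA_character_, nrow(exp_df))  # "keep", "flip", "drop"
  action[same | same_flipped] <- "keep"
  action[(swapped | swap_flipped) & is.na(action)] <- "flip"
  mismatch <- is.na(action)
  action[mismatch] <- "drop"

  if (any(pal)) {
    if (palindrome_policy == "drop") {
      action[pal] <- "drop"
    } else {
      lo <- eaf_window[1]; hi <- eaf_window[2]
      eaf_x <- exp_df$eaf; eaf_y <- out_df$eaf
      informative <- !is.na(eaf_x) & !is.na(eaf_y) &
        (eaf_x < lo | eaf_x > hi) & (eaf_y < lo | eaf_y > hi)
      # Same strand reported: frequencies agree in orientation; flipped
      # strand shows as complementary frequency, equivalent to an allele swap.
      agree <- (eaf_x < 0.5) == (eaf_y < 0.5)
      action[pal] <- ifelse(informative[pal],
                            ifelse(agree[pal], "keep", "flip"),
                            "drop")
    }
  }

  drop_counts <- c(
    missing_in_outcome = n_missing,
    allele_mismatch = sum(mismatch & action == "drop" & !pal),
    palindromic = sum(pal & action == "drop")
  )

  kept <- action != "drop"
  if (sum(kept) == 0) {
    insufficient_instruments(
      sprintf("no variants survive harmonization (missing: %d, mismatch: %d, palindromic: %d)",
              drop_counts[1], drop_counts[2], drop_counts[3]),
      counts = drop_counts)
  }

  sign_out <- ifelse(action[kept] == "flip", -1, 1)
  h <- data.frame(
    snp_id = exp_df$snp_id[kept],
    beta_exp = exp_df$beta[kept],
    se_exp = exp_df$se[kept],
    beta_out = sign_out * out_df$beta[kept],
    se_out = out_df$se[kept],
    eaf_exp = exp_df$eaf[kept],
    eaf_out = ifelse(sign_out < 0, 1 - out_df$eaf[kept], out_df$eaf[kept]),
    stringsAsFactors = FALSE
  )
  rownames(h) <- NULL
  structure(h,
            exposure_id = attr(exposure, "trait_id") %||% "exposure",
            outcome_id = trait_id(outcome),
            drop_counts = drop_counts,
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d variants\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"), nrow(x)))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Assemble a harmonized set directly from aligned effects
#'
#' Convenience constructor for already-aligned exposure/outcome effect pairs
#' (simulation studies, tests).
#'
#' @param snp_id,beta_exp,se_exp,beta_out,se_out aligned per-variant vectors.
#' @param exposure_id,outcome_id trait labels.
#' @return a `harmonized_set`.
#' @export
harmonized_set <- function(snp_id, beta_exp, se_exp, beta_out, se_out,
                           exposure_id = "exposure", outcome_id = "outcome") {
  assert_that(all(se_exp > 0) && all(se_out > 0),
              "standard errors must be positive", "mrmediate_config_error")
  h <- data.frame(snp_id = as.character(snp_id), beta_exp = beta_exp,
                  se_exp = se_exp, beta_out = beta_out, se_out = se_out,
                  eaf_exp = NA_real_, eaf_out = NA_real_,
                  stringsAsFactors = FALSE)
  structure(h, exposure_id = exposure_id, outcome_id = outcome_id,
            drop_counts = c(missing_in_outcome = 0L, allele_mismatch = 0L,
                            palindromic = 0L),
            class = c("harmonized_set", "data.frame"))
}

#' Full instrument-selection chain
#'
#' p-value screen, LD clumping, then F filtering, in that order. Idempotent:
#' applying it to its own output returns the same set.
#'
#' @param table exposure `summary_stats`.
#' @param panel `ld_panel` for clumping.
#' @param iv_pvalue,clump_r2,clump_kb,min_f thresholds (see the individual
#'   steps for defaults).
#' @return an `instrument_set`.
#' @export
select_instruments <- function(table, panel, iv_pvalue = 1e-5,
                               clump_r2 = 0.001, clump_kb = 10000,
                               min_f = 10) {
  screened <- filter_by_pvalue(table, iv_pvalue)
  clumped <- ld_clump(screened, panel, clump_r2, clump_kb)
  compute_f_statistics(clumped, min_f)
}
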