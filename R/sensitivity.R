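# Heterogeneity, pleiotropy and outlier diagnostics: Cochran's Q, the
# MR-Egger intercept test, leave-one-out refits, and an MR-PRESSO-style
# global / outlier / distortion test based on parametric simulation.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (ratio_j - beta_ivw_fixed)^2` over per-variant Wald ratios,
#' with `w_j` the inverse variance of each ratio under the no-measurement-
#' error (NOME) approximation, `var(ratio_j) = se_out_j^2 / beta_exp_j^2`,
#' and the fixed-effect IVW estimate computed under the same weights. This is
#' algebraically identical to the weighted RSS of the zero-intercept IVW
#' regression, so `Q = (n_snp - 1) * scale^2` for the multiplicative
#' random-effects residual scale (before flooring at 1). Under homogeneity Q
#' is chi-square with `n_snp - 1` df; p < 0.05 conventionally flags
#' heterogeneity.
#'
#' @param hset a `harmonized_set` with at least two rows.
#' @return list with `q_stat`, `q_df`, `q_pvalue`.
#' @export
cochran_q <- function(hset) {
  n <- nrow(hset)
  if (n < 2) insufficient_instruments("Cochran's Q requires >= 2 variants")
  re <- ratio_estimates(hset)
  w <- hset$beta_exp^2 / hset$se_out^2
  beta_fixed <- sum(w * re$ratio) / sum(w)
  q <- sum(w * (re$ratio - beta_fixed)^2)
  list(q_stat = q, q_df = n - 1L,
       q_pvalue = stats::pchisq(q, df = n - 1, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimator `n_snp` times, each omitting one variant, to
#' expose estimates driven by a single instrument. A fit is flagged when its
#' 95% CI no longer supports the full-set estimate's sign conclusion.
#'
#' @param hset a `harmonized_set` with at least three rows.
#' @param variant IVW variant, passed through to [ivw()].
#' @return data.frame with one row per omitted variant: dropped_snp_id, beta,
#'   se, pvalue, ci_low, ci_high (log scale), flagged.
#' @export
leave_one_out <- function(hset, variant = "multiplicative_random") {
  n <- nrow(hset)
  if (n < 3) insufficient_instruments("leave-one-out requires >= 3 variants")
  full <- ivw(hset, variant)
  z <- stats::qnorm(0.975)
  rows <- lapply(seq_len(n), function(j) {
    fit <- ivw(hset[-j, , drop = FALSE], variant)
    lo <- fit$beta - z * fit$se
    hi <- fit$beta + z * fit$se
    # flag if omitting this variant overturns the full fit's sign conclusion
    full_sig <- full$pvalue < 0.05
    flagged <- if (full_sig) {
      !(lo > 0 & full$beta > 0) && !(hi < 0 & full$beta < 0)
    } else FALSE
    data.frame(dropped_snp_id = hset$snp_id[j], beta = fit$beta, se = fit$se,
               pvalue = fit$pvalue, ci_low = lo, ci_high = hi,
               flagged = flagged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

presso_rss <- function(bx, by, se_out) {
  # leave-one-out expected outcome effects under the no-pleiotropy model
  n <- length(bx)
  w <- 1 / se_out^2
  contrib <- numeric(n)
  for (j in seq_len(n)) {
    slope <- sum(w[-j] * bx[-j] * by[-j]) / sum(w[-j] * bx[-j]^2)
    contrib[j] <- w[j] * (by[j] - slope * bx[j])^2
  }
  list(rss = sum(contrib), contrib = contrib)
}

#' MR-PRESSO-style pleiotropy residual sum and outlier test
#'
#' Three tests built on the weighted residual sum of squares (RSS) of each
#' variant's outcome effect around its leave-one-out IVW prediction:
#' \describe{
#'   \item{global}{observed RSS compared with `n_sim` parametric simulations
#'     drawn under no pleiotropy; `global_p` is the empirical upper-tail
#'     proportion, floored at `1/(n_sim + 1)`.}
#'   \item{outlier}{each variant's observed RSS contribution against its own
#'     simulated distribution; per-variant empirical p-values are
#'     Bonferroni-adjusted and variants below `outlier_alpha` are flagged.}
#'   \item{distortion}{the change in IVW slope after removing flagged
#'     outliers, compared against removals of equally many randomly chosen
#'     variants; two-sided empirical p.}
#' }
#'
#' @param hset a `harmonized_set` with at least four rows.
#' @param n_sim parametric simulations (default 1000).
#' @param seed integer seed (mandatory; recorded in the result).
#' @param outlier_alpha significance level for the Bonferroni-adjusted
#'   per-variant test (default 0.05).
#' @return list with `global_rss_obs`, `global_p`, `outlier_snp_ids`,
#'   `outlier_p` (named, Bonferroni-adjusted), `distortion_p`,
#'   `beta_outlier_corrected`, `n_sim`, `seed`.
#' @export
mr_presso <- function(hset, n_sim = 1000, seed, outlier_alpha = 0.05) {
  n <- nrow(hset)
  if (n < 4) insufficient_instruments("MR-PRESSO requires >= 4 variants")
  assert_that(!missing(seed), "seed is mandatory for MR-PRESSO",
              "mrmediate_config_error")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  bx <- hset$beta_exp; by <- hset$beta_out
  sx <- hset$se_exp; sy <- hset$se_out
  obs <- presso_rss(bx, by, sy)

  # expected outcome effect for each variant under its leave-one-out slope
  w <- 1 / sy^2
  expected <- vapply(seq_len(n), function(j) {
    slope <- sum(w[-j] * bx[-j] * by[-j]) / sum(w[-j] * bx[-j]^2)
    slope * bx[j]
  }, numeric(1))

  sim_rss <- numeric(n_sim)
  sim_contrib <- matrix(0, n_sim, n)
  for (s in seq_len(n_sim)) {
    bx_s <- stats::rnorm(n, bx, sx)
    by_s <- stats::rnorm(n, expected, sy)
    r <- presso_rss(bx_s, by_s, sy)
    sim_rss[s] <- r$rss
    sim_contrib[s, ] <- r$contrib
  }
  global_p <- max(mean(sim_rss >= obs$rss), 1 / (n_sim + 1))

  p_raw <- vapply(seq_len(n), function(j) {
    max(mean(sim_contrib[, j] >= obs$contrib[j]), 1 / (n_sim + 1))
  }, numeric(1))
  p_adj <- pmin(p_raw * n, 1)
  names(p_adj) <- hset$snp_id
  outliers <- hset$snp_id[p_adj < outlier_alpha]

  beta_raw <- ivw(hset, "multiplicative_random")$beta
  beta_corrected <- NA_real_
  distortion_p <- NA_real_
  if (length(outliers) > 0 && length(outliers) < n - 1) {
    keep <- !(hset$snp_id %in% outliers)
    beta_corrected <- ivw(hset[keep, , drop = FALSE],
                          "multiplicative_random")$beta
    d_obs <- beta_raw - beta_corrected
    n_out <- length(outliers)
    d_null <- vapply(seq_len(n_sim), function(s) {
      drop_idx <- sample.int(n, n_out)
      beta_raw - ivw(hset[-drop_idx, , drop = FALSE],
                     "multiplicative_random")$beta
    }, numeric(1))
    distortion_p <- max(mean(abs(d_null) >= abs(d_obs)), 1 / (n_sim + 1))
  }

  list(global_rss_obs = obs$rss, global_p = global_p,
       outlier_snp_ids = outliers, outlier_p = p_adj,
       distortion_p = distortion_p, beta_outlier_corrected = beta_corrected,
       n_sim = n_sim, seed = seed)
}

#' Full sensitivity report for a harmonized set
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, leave-one-out refits and
#' (given at least four variants) the MR-PRESSO-style diagnostics. Headline
#' estimates are never replaced by outlier-corrected ones automatically; the
#' correction is surfaced for the analyst.
#'
#' @param hset a `harmonized_set`.
#' @param seed integer seed for the stochastic diagnostics.
#' @param presso_nsim MR-PRESSO simulation count (default 1000).
#' @param alpha significance threshold used for flags (default 0.05).
#' @return a `sensitivity_report` list.
#' @export
sensitivity_report <- function(hset, seed, presso_nsim = 1000, alpha = 0.05) {
  q <- cochran_q(hset)
  eg <- if (nrow(hset) >= 3) mr_egger(hset) else NULL
  loo <- if (nrow(hset) >= 3) leave_one_out(hset) else NULL
  presso <- if (nrow(hset) >= 4) {
    mr_presso(hset, n_sim = presso_nsim, seed = split_seed(seed, "presso"))
  } else NULL
  structure(list(
    q_stat = q$q_stat, q_df = q$q_df, q_pvalue = q$q_pvalue,
    heterogeneity = q$q_pvalue < alpha,
    egger_intercept = eg$extra$egger_intercept,
    egger_intercept_se = eg$extra$intercept_se,
    egger_intercept_p = eg$extra$intercept_p,
    pleiotropy = if (!is.null(eg)) eg$extra$intercept_p < alpha else NA,
    loo = loo, presso = presso, alpha = alpha, seed = seed
  ), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> Q = %.3f (df %d, p = %.3g); Egger intercept p = %s; %s\n",
              x$q_stat, x$q_df, x$q_pvalue,
              if (is.null(x$egger_intercept_p)) "NA" else
                sprintf("%.3g", x$egger_intercept_p),
              if (!is.null(x$presso))
                sprintf("PRESSO global p = %.3g, %d outlier(s)",
                        x$presso$global_p, length(x$presso$outlier_snp_ids))
              else "PRESSO not run"))
  invisible(x)
}
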