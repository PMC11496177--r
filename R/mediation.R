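# Two-step MR mediation: product-of-coefficients mediated effect with
# delta-method (Sobel) confidence intervals, mediation proportion,
# Benjamini-Hochberg evidence tiering, and a binary-outcome power calculator.

#' Sobel (first-order delta) interval for a product of coefficients
#'
#' The mediated effect is the product `beta_a * beta_b` of the
#' exposure-to-mediator and mediator-to-outcome effects, estimated in
#' non-overlapping samples and hence treated as independent. Its first-order
#' delta-method (Sobel) standard error is
#' `sqrt(beta_b^2 se_a^2 + beta_a^2 se_b^2)`; setting `second_order = TRUE`
#' adds the exact product-variance term `se_a^2 se_b^2`.
#'
#' @param beta_a,se_a exposure-to-mediator effect and its standard error.
#' @param beta_b,se_b mediator-to-outcome effect and its standard error.
#' @param level CI coverage (default 0.95).
#' @param second_order include the second-order variance term.
#' @return list with `mediated`, `se`, `ci` (length-2), `p`.
#' @export
sobel_ci <- function(beta_a, se_a, beta_b, se_b, level = 0.95,
                     second_order = FALSE) {
  assert_that(se_a >= 0 && se_b >= 0, "standard errors must be non-negative",
              "mrmediate_config_error")
  mediated <- beta_a * beta_b
  v <- beta_b^2 * se_a^2 + beta_a^2 * se_b^2
  if (second_order) v <- v + se_a^2 * se_b^2
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- c(mediated - z * se, mediated + z * se)
  p <- if (se == 0) as.numeric(mediated == 0) else
    2 * stats::pnorm(-abs(mediated / se))
  list(mediated = mediated, se = se, ci = ci, p = p)
}

#' Mediation proportion with a delta-method interval
#'
#' `100 * mediated / total` percent, with the delta-method variance of a
#' ratio of independent estimates:
#' `(mediated/total)^2 (se_med^2/mediated^2 + se_total^2/total^2)`.
#' Proportions are reported signed; when the mediated and total effects have
#' opposite signs the result carries an `inconsistent` flag rather than a
#' silent absolute value.
#'
#' @param mediated,se_med mediated effect and its standard error.
#' @param total,se_total total effect and its standard error (must be
#'   non-zero).
#' @param level CI coverage (default 0.95).
#' @return list with `proportion_pct`, `se_pct`, `ci` (percent scale),
#'   `inconsistent`.
#' @export
mediation_proportion <- function(mediated, se_med, total, se_total,
                                 level = 0.95) {
  assert_that(total != 0, "mediation proportion undefined for total = 0",
              "mrmediate_undefined_proportion_error")
  prop <- mediated / total
  se_prop <- if (mediated == 0) {
    se_med / abs(total)
  } else {
    abs(prop) * sqrt(se_med^2 / mediated^2 + se_total^2 / total^2)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(proportion_pct = 100 * prop,
       se_pct = 100 * se_prop,
       ci = 100 * c(prop - z * se_prop, prop + z * se_prop),
       inconsistent = sign(mediated) * sign(total) < 0)
}

#' Assemble a two-step MR mediation result
#'
#' Decomposes the total exposure-to-outcome effect into a mediated component
#' `beta_a * beta_b` (product of the exposure-to-mediator and
#' mediator-to-outcome effects) and a direct component `total - mediated`.
#' All three input estimates must be on the log-OR / linear scale and come
#' from IVW fits by default.
#'
#' @param est_a exposure-to-mediator `mr_estimate`.
#' @param est_b mediator-to-outcome `mr_estimate`.
#' @param est_total exposure-to-outcome `mr_estimate`.
#' @param exposure_id,mediator_id,outcome_id trait labels.
#' @param level CI coverage (default 0.95).
#' @param second_order passed to [sobel_ci()].
#' @return a `mediation_result` list; `direct + mediated = total` exactly.
#' @export
two_step_mediation <- function(est_a, est_b, est_total,
                               exposure_id = "exposure",
                               mediator_id = "mediator",
                               outcome_id = "outcome",
                               level = 0.95, second_order = FALSE) {
  for (e in list(est_a, est_b, est_total)) {
    assert_that(inherits(e, "mr_estimate"),
                "all three legs must be mr_estimate objects (missing leg?)",
                "mrmediate_incomplete_triangle_error")
  }
  sob <- sobel_ci(est_a$beta, est_a$se, est_b$beta, est_b$se,
                  level = level, second_order = second_order)
  prop <- mediation_proportion(sob$mediated, sob$se,
                               est_total$beta, est_total$se, level = level)
  structure(list(
    exposure_id = exposure_id, mediator_id = mediator_id,
    outcome_id = outcome_id,
    beta_a = est_a$beta, se_a = est_a$se, p_a = est_a$pvalue,
    beta_b = est_b$beta, se_b = est_b$se, p_b = est_b$pvalue,
    total = est_total$beta, se_total = est_total$se, p_total = est_total$pvalue,
    mediated = sob$mediated, se_mediated = sob$se, mediated_ci = sob$ci,
    mediated_p = sob$p,
    direct = est_total$beta - sob$mediated,
    proportion_pct = prop$proportion_pct, proportion_ci = prop$ci,
    inconsistent = prop$inconsistent,
    methods = c(a = est_a$method, b = est_b$method, total = est_total$method)
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s -> %s -> %s\n", x$exposure_id,
              x$mediator_id, x$outcome_id))
  cat(sprintf("  mediated effect %.3g (%.3g, %.3g), p = %.3g\n",
              x$mediated, x$mediated_ci[1], x$mediated_ci[2], x$mediated_p))
  cat(sprintf("  proportion mediated %.1f%% (%.2f%%, %.2f%%)%s\n",
              x$proportion_pct, x$proportion_ci[1], x$proportion_ci[2],
              if (x$inconsistent) " [inconsistent-mediation]" else ""))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted ascending,
#' `adj_i = min_{j >= i} (p_j * m / j)` capped at 1, returned in the original
#' order.
#'
#' @param pvalues numeric vector in (0, 1].
#' @return adjusted values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  assert_that(all(pvalues > 0 & pvalues <= 1), "p-values must lie in (0, 1]",
              "mrmediate_config_error")
  ord <- order(pvalues)
  adj <- pvalues[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Evidence tier from a p-value and its FDR
#'
#' Three-tier rule: `"causal"` when FDR < 0.05; `"suggestive"` when FDR >=
#' 0.05 but p < 0.05; `"none"` when p >= 0.05.
#'
#' @param pvalue,fdr values in (0, 1]. Vectorized.
#' @param fdr_alpha,p_alpha tier thresholds (defaults 0.05).
#' @return character vector of tiers.
#' @export
classify_evidence <- function(pvalue, fdr, fdr_alpha = 0.05, p_alpha = 0.05) {
  ifelse(fdr < fdr_alpha, "causal",
         ifelse(pvalue < p_alpha, "suggestive", "none"))
}

#' Statistical power for MR with a binary outcome
#'
#' Large-sample approximation in the style of the mRnd calculator:
#' `power = Phi(-z_{1-alpha/2} + |log OR| * sqrt(n r2 cf (1 - cf)))`
#' where `n` is the outcome sample size, `cf` the case fraction, `r2` the
#' variance in the exposure explained by the instruments, and OR the
#' hypothesized causal odds ratio per exposure SD.
#'
#' @param n outcome GWAS sample size.
#' @param case_fraction proportion of cases in (0, 1).
#' @param r2 instrument-explained exposure variance in (0, 1).
#' @param or_hypothesized causal odds ratio to detect.
#' @param alpha two-sided significance level (default 0.05).
#' @return power in \[0, 1\].
#' @export
mr_power <- function(n, case_fraction, r2, or_hypothesized, alpha = 0.05) {
  assert_that(r2 > 0 && r2 < 1, "r2 must lie in (0, 1)",
              "mrmediate_config_error")
  assert_that(case_fraction > 0 && case_fraction < 1,
              "case_fraction must lie in (0, 1)", "mrmediate_config_error")
  ncp <- abs(log(or_hypothesized)) *
    sqrt(n * r2 * case_fraction * (1 - case_fraction))
  stats::pnorm(-stats::qnorm(1 - alpha / 2) + ncp)
}

#' Instrument-explained variance from effect sizes and allele frequencies
#'
#' `R^2 = sum_j 2 maf_j (1 - maf_j) beta_j^2` for a standardized exposure —
#' the input the power calculator expects. Also returns the corresponding
#' regression F statistic `R^2 (n - 2) / (1 - R^2)` when a sample size is
#' given.
#'
#' @param beta,eaf per-variant effects and effect-allele frequencies.
#' @param n exposure sample size (optional).
#' @return list with `r2` and `f_stat` (NA without `n`).
#' @export
instrument_r2 <- function(beta, eaf, n = NULL) {
  maf <- pmin(eaf, 1 - eaf)
  r2 <- sum(2 * maf * (1 - maf) * beta^2)
  f <- if (is.null(n)) NA_real_ else r2 * (n - 2) / (1 - r2)
  list(r2 = r2, f_stat = f)
}
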