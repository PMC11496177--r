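# Summary-data MR estimators: Wald ratio, IVW, MR-Egger, weighted median,
# weighted/simple mode. All return an `mr_estimate` on the log-OR (or linear)
# scale with the OR-scale fields filled by to_odds_ratio().

new_mr_estimate <- function(method, beta, se, pvalue, n_snp, extra = list()) {
  est <- structure(
    list(method = method, beta = beta, se = se, pvalue = pvalue,
         n_snp = n_snp, or_ = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
         extra = extra),
    class = "mr_estimate")
  to_odds_ratio(est)
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: beta = %.4g (se %.4g), OR = %.3f (%.3f, %.3f), p = %.3g, n_snp = %d\n",
              x$method, x$beta, x$se, x$or_, x$ci_low, x$ci_high,
              x$pvalue, x$n_snp))
  invisible(x)
}

#' Fill the odds-ratio-scale fields of an estimate
#'
#' `or_ = exp(beta)` with a Wald 95% interval
#' `exp(beta -/+ 1.96 se)`. Idempotent.
#'
#' @param estimate an `mr_estimate`.
#' @return the estimate with `or_`, `ci_low`, `ci_high` filled.
#' @export
to_odds_ratio <- function(estimate) {
  z <- stats::qnorm(0.975)
  estimate$or_ <- exp(estimate$beta)
  estimate$ci_low <- exp(estimate$beta - z * estimate$se)
  estimate$ci_high <- exp(estimate$beta + z * estimate$se)
  estimate
}

#' Single-variant Wald ratio
#'
#' Causal estimate from one instrument: `beta_out / beta_exp`, with a
#' first-order delta-method standard error
#' `sqrt(se_out^2 / beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)` and a
#' normal two-sided p-value.
#'
#' @param row one row of a `harmonized_set` (or any list with beta_exp,
#'   se_exp, beta_out, se_out).
#' @return an `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(row) {
  assert_that(row$beta_exp != 0, "Wald ratio undefined for beta_exp = 0",
              "mrmediate_undefined_ratio_error")
  beta <- row$beta_out / row$beta_exp
  se <- sqrt(row$se_out^2 / row$beta_exp^2 +
               row$beta_out^2 * row$se_exp^2 / row$beta_exp^4)
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("wald", beta, se, p, 1L)
}

ratio_estimates <- function(hset) {
  ratio <- hset$beta_out / hset$beta_exp
  # first-order variance of the per-SNP ratio
  var_ratio <- hset$se_out^2 / hset$beta_exp^2 +
    hset$beta_out^2 * hset$se_exp^2 / hset$beta_exp^4
  list(ratio = ratio, var = var_ratio)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted least squares of `beta_out` on `beta_exp` through the origin with
#' weights `1/se_out^2` — the meta-analysis of per-variant Wald ratios and the
#' primary estimator of the pipeline. The fixed-effect variant uses residual
#' scale 1; the multiplicative random-effects variant (default) inflates the
#' standard error by `max(1, sqrt(Q / (n - 1)))`, never deflating below the
#' fixed-effect value.
#'
#' @param hset a `harmonized_set` with at least one row; a single row
#'   delegates to [wald_ratio()].
#' @param variant `"multiplicative_random"` (default) or `"fixed"`.
#' @return an `mr_estimate` with method `"ivw"`; `extra` carries the Cochran
#'   Q statistic, its df, and the residual scale applied.
#' @export
ivw <- function(hset, variant = c("multiplicative_random", "fixed")) {
  variant <- match.arg(variant)
  n <- nrow(hset)
  if (n < 1) insufficient_instruments("IVW requires at least one variant")
  if (n == 1) return(wald_ratio(hset[1, ]))

  w <- 1 / hset$se_out^2
  fit <- stats::lm(beta_out ~ 0 + beta_exp, data = hset, weights = w)
  beta <- unname(stats::coef(fit)[1])
  se_fixed <- sqrt(1 / sum(w * hset$beta_exp^2))
  q <- sum(w * (hset$beta_out - beta * hset$beta_exp)^2)
  scale <- if (variant == "multiplicative_random") {
    max(1, sqrt(q / (n - 1)))
  } else 1
  se <- se_fixed * scale
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("ivw", beta, se, p, n,
                  extra = list(variant = variant, q_stat = q, q_df = n - 1L,
                               residual_scale = scale))
}

#' MR-Egger regression
#'
#' Weighted least squares of `beta_out` on `beta_exp` with a free intercept
#' and weights `1/se_out^2`, after re-orienting every variant so
#' `beta_exp >= 0`. The slope estimates the causal effect under the InSiDE
#' assumption; the intercept estimates average directional pleiotropy.
#' Standard errors use residual scale `max(1, estimated scale)` and p-values
#' the t distribution with `n_snp - 2` df.
#'
#' @param hset a `harmonized_set` with at least three rows.
#' @return an `mr_estimate` with method `"egger"`; `extra` carries
#'   `egger_intercept`, `intercept_se`, `intercept_p` and the residual scale.
#' @export
mr_egger <- function(hset) {
  n <- nrow(hset)
  if (n < 3) insufficient_instruments("MR-Egger requires at least 3 variants")
  flip <- sign(hset$beta_exp)
  flip[flip == 0] <- 1
  bx <- hset$beta_exp * flip
  by <- hset$beta_out * flip
  w <- 1 / hset$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  scale <- max(1, sm$sigma)
  beta <- unname(stats::coef(fit)["bx"])
  intercept <- unname(stats::coef(fit)["(Intercept)"])
  se_unscaled <- sqrt(diag(sm$cov.unscaled))  # sigma-free (X'WX)^{-1} diag
  se_beta <- unname(se_unscaled["bx"]) * scale
  se_int <- unname(se_unscaled["(Intercept)"]) * scale
  p_beta <- 2 * stats::pt(-abs(beta / se_beta), df = n - 2)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df = n - 2)
  new_mr_estimate("egger", beta, se_beta, p_beta, n,
                  extra = list(egger_intercept = intercept,
                               intercept_se = se_int,
                               intercept_p = p_int,
                               residual_scale = scale))
}

weighted_quantile <- function(x, w, q = 0.5) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  # cumulative weight at each point, centred: interpolate across the steps
  cw <- cumsum(w) - w / 2
  if (q <= cw[1]) return(x[1])
  if (q >= cw[length(cw)]) return(x[length(x)])
  stats::approx(cw, x, xout = q)$y
}

boot_draws <- function(hset, n_boot, seed, estimator) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- nrow(hset)
  vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(n, hset$beta_exp, hset$se_exp)
    by <- stats::rnorm(n, hset$beta_out, hset$se_out)
    estimator(bx, by)
  }, numeric(1))
}

#' Weighted-median estimator
#'
#' The weighted 50th percentile of the per-variant Wald ratios, weights
#' proportional to the inverse first-order variance of each ratio. Consistent
#' when variants carrying at least half the weight are valid instruments. The
#' standard error comes from a parametric bootstrap: each `beta_exp` and
#' `beta_out` is redrawn from a normal with its own standard error and the
#' weighted median recomputed.
#'
#' @param hset a `harmonized_set` with at least three rows.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap (mandatory; recorded in
#'   `extra$seed`).
#' @return an `mr_estimate` with method `"weighted_median"`.
#' @export
weighted_median <- function(hset, n_boot = 1000, seed) {
  n <- nrow(hset)
  if (n < 3) insufficient_instruments("weighted median requires >= 3 variants")
  assert_that(!missing(seed), "seed is mandatory for the bootstrap",
              "mrmediate_config_error")
  est_fun <- function(bx, by) {
    r <- by / bx
    v <- hset$se_out^2 / bx^2 + by^2 * hset$se_exp^2 / bx^4
    weighted_quantile(r, 1 / v, 0.5)
  }
  re <- ratio_estimates(hset)
  beta <- weighted_quantile(re$ratio, 1 / re$var, 0.5)
  draws <- boot_draws(hset, n_boot, seed, est_fun)
  se <- stats::sd(draws)
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("weighted_median", beta, se, p, n,
                  extra = list(n_boot = n_boot, seed = seed))
}

mode_argmax <- function(ratio, w, bandwidth_factor) {
  w <- w / sum(w)
  s <- stats::mad(ratio)
  if (s == 0) s <- stats::sd(ratio)
  if (is.na(s) || s == 0) return(ratio[1])  # point mass
  h <- bandwidth_factor * 0.9 * s * length(ratio)^(-1 / 5)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 4096)
  dens <- colSums(w * stats::dnorm(outer(ratio, grid, "-") / h)) # / h cancels
  grid[which.max(dens)]
}

#' Mode-based estimator (weighted and simple mode)
#'
#' The argmax of a normal-kernel density over the per-variant Wald ratios —
#' the "largest cluster" estimate, consistent when the most common ratio value
#' comes from valid instruments. `weighted = TRUE` weights each ratio by its
#' inverse first-order variance; `FALSE` gives the simple mode. Bandwidth is
#' `bandwidth_factor` times a modified Silverman rule using the median
#' absolute deviation of the ratios. Standard error by parametric bootstrap
#' as in [weighted_median()].
#'
#' @param hset a `harmonized_set` with at least three rows.
#' @param weighted inverse-variance weights (TRUE, default) or uniform.
#' @param bandwidth_factor multiplier on the Silverman bandwidth (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed (mandatory).
#' @return an `mr_estimate` with method `"weighted_mode"` or `"simple_mode"`.
#' @export
mode_estimate <- function(hset, weighted = TRUE, bandwidth_factor = 1,
                          n_boot = 1000, seed) {
  n <- nrow(hset)
  if (n < 3) insufficient_instruments("mode estimator requires >= 3 variants")
  assert_that(!missing(seed), "seed is mandatory for the bootstrap",
              "mrmediate_config_error")
  assert_that(bandwidth_factor > 0, "bandwidth_factor must be positive",
              "mrmediate_config_error")
  est_fun <- function(bx, by) {
    r <- by / bx
    w <- if (weighted) {
      1 / (hset$se_out^2 / bx^2 + by^2 * hset$se_exp^2 / bx^4)
    } else rep(1, length(r))
    mode_argmax(r, w, bandwidth_factor)
  }
  re <- ratio_estimates(hset)
  w0 <- if (weighted) 1 / re$var else rep(1, n)
  beta <- mode_argmax(re$ratio, w0, bandwidth_factor)
  draws <- boot_draws(hset, n_boot, seed, est_fun)
  se <- stats::sd(draws)
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
                  beta, se, p, n,
                  extra = list(n_boot = n_boot, seed = seed,
                               bandwidth_factor = bandwidth_factor))
}

#' Run the full estimator battery on a harmonized set
#'
#' IVW (the primary estimator), MR-Egger, weighted median, weighted mode and
#' simple mode, each on the log-OR scale with OR-scale columns.
#'
#' @param hset a `harmonized_set`.
#' @param seed integer seed for the bootstrap-based estimators.
#' @param n_boot bootstrap replicates (default 1000).
#' @param ivw_variant passed to [ivw()].
#' @return data.frame, one row per method: exposure, outcome, method, n_snp,
#'   beta, se, or_, ci_low, ci_high, pvalue.
#' @export
mr_all_methods <- function(hset, seed, n_boot = 1000,
                           ivw_variant = "multiplicative_random") {
  ests <- list(ivw(hset, ivw_variant))
  if (nrow(hset) >= 3) {
    ests <- c(ests, list(
      mr_egger(hset),
      weighted_median(hset, n_boot, seed = split_seed(seed, "wmedian")),
      mode_estimate(hset, weighted = TRUE, n_boot = n_boot,
                    seed = split_seed(seed, "wmode")),
      mode_estimate(hset, weighted = FALSE, n_boot = n_boot,
                    seed = split_seed(seed, "smode"))
    ))
  }
  do.call(rbind, lapply(ests, function(e) {
    data.frame(exposure = attr(hset, "exposure_id"),
               outcome = attr(hset, "outcome_id"),
               method = e$method, n_snp = e$n_snp, beta = e$beta, se = e$se,
               or_ = e$or_, ci_low = e$ci_low, ci_high = e$ci_high,
               pvalue = e$pvalue, stringsAsFactors = FALSE)
  }))
}
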