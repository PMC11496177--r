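# Shared generators for random tables and harmonized sets.

random_summary_stats <- function(n, trait = "t", seed = NULL,
                                 palindrome_frac = 0) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ea <- sample(bases, n, replace = TRUE)
  oa <- vapply(seq_len(n), function(i) {
    if (runif(1) < palindrome_frac) comp[[ea[i]]]
    else sample(setdiff(bases, c(ea[i], comp[[ea[i]]])), 1)
  }, character(1))
  summary_stats(data.frame(
    snp_id = sprintf("rs%04d", sample.int(9999, n)),
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(2e8, n),
    effect_allele = ea, other_allele = oa,
    eaf = runif(n, 0.05, 0.95),
    beta = rnorm(n, 0, 0.1),
    se = runif(n, 0.01, 0.05),
    pvalue = runif(n),
    n = sample(1000:10000, n, replace = TRUE)
  ), trait_id = trait)
}

random_hset <- function(n, theta = 0.3, se_out_range = c(0.02, 0.08),
                        se_exp_range = c(0.01, 0.03), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bx_true <- runif(n, 0.1, 0.5) * sample(c(-1, 1), n, replace = TRUE)
  se_exp <- runif(n, se_exp_range[1], se_exp_range[2])
  se_out <- runif(n, se_out_range[1], se_out_range[2])
  harmonized_set(
    snp_id = sprintf("rs%03d", seq_len(n)),
    beta_exp = rnorm(n, bx_true, se_exp),
    se_exp = se_exp,
    beta_out = rnorm(n, theta * bx_true, se_out),
    se_out = se_out)
}

# independent normal-equations WLS oracle: returns coef and unscaled
# covariance for design X, response y, weights w
wls_oracle <- function(X, y, w) {
  XtWX <- t(X) %*% (X * w)
  XtWy <- t(X) %*% (y * w)
  coef <- solve(XtWX, XtWy)
  list(coef = drop(coef), cov_unscaled = solve(XtWX),
       rss = sum(w * (y - drop(X %*% coef))^2))
}

# brute-force greedy clumping oracle, written independently of ld_clump
clump_oracle <- function(table, panel, r2_threshold, window_kb) {
  df <- as.data.frame(table)
  kept <- character(0)
  pool <- df[order(df$pvalue, df$pos, df$snp_id), ]
  while (nrow(pool) > 0) {
    idx <- pool[1, ]
    kept <- c(kept, idx$snp_id)
    pool <- pool[-1, , drop = FALSE]
    if (nrow(pool) == 0) break
    drop <- rep(FALSE, nrow(pool))
    for (k in seq_len(nrow(pool))) {
      if (pool$chrom[k] != idx$chrom) next
      if (abs(pool$pos[k] - idx$pos) > window_kb * 1000) next
      r2 <- ld_r2(panel, pool$snp_id[k], idx$snp_id)
      if (r2 >= r2_threshold) drop[k] <- TRUE
    }
    pool <- pool[!drop, , drop = FALSE]
  }
  sort(kept)
}

# cumulative-weight interpolation oracle for the weighted median
wmedian_oracle <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]
  wn <- w[o] / sum(w)
  cum <- cumsum(wn) - wn / 2
  if (0.5 <= cum[1]) return(r[1])
  if (0.5 >= cum[length(cum)]) return(r[length(r)])
  below <- max(which(cum <= 0.5))
  above <- below + 1
  r[below] + (r[above] - r[below]) * (0.5 - cum[below]) /
    (cum[above] - cum[below])
}

# dense-grid argmax oracle for the kernel-mode estimator
mode_oracle <- function(ratio, w, bandwidth_factor = 1, n_grid = 20001) {
  w <- w / sum(w)
  s <- mad(ratio)
  if (s == 0) s <- sd(ratio)
  h <- bandwidth_factor * 0.9 * s * length(ratio)^(-1 / 5)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = n_grid)
  dens <- sapply(grid, function(g) sum(w * dnorm(g, ratio, h)))
  grid[which.max(dens)]
}

# brute-force BH adjustment straight from the step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  out <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- sum(p <= p[i])  # maximal rank among ties
    cands <- sapply(seq_len(m), function(j) {
      rj <- sum(p <= p[j])
      if (rj >= rank_i) p[j] * m / rj else Inf
    })
    out[i] <- min(1, min(cands))
  }
  out
}
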