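# Orchestration: instrument selection -> harmonization -> estimators ->
# sensitivity for one exposure/outcome pair, and the two-step mediation scan
# over exposure and mediator families.

#' Pipeline configuration
#'
#' Collects every threshold of the workflow. Defaults follow common
#' molecular-trait MR practice: instrument screen at p < 1e-5, clumping at
#' r^2 < 0.001 within 10,000 kb, weak-instrument cutoff F < 10, exposure and
#' mediator screens reported at p < 0.01 with Benjamini-Hochberg tiering at
#' FDR < 0.05, and exposure-to-mediator legs tested at p < 0.05.
#'
#' @param iv_pvalue,clump_r2,clump_kb,min_f instrument-selection thresholds.
#' @param palindrome_policy `"drop"` or `"infer_by_eaf"` (see [harmonize()]).
#' @param ivw_variant `"multiplicative_random"` (default) or `"fixed"`.
#' @param screen_alpha p-value at which screened associations are reported.
#' @param fdr_alpha FDR threshold of the "causal" evidence tier.
#' @param leg_alpha p-value threshold for exposure-to-mediator legs.
#' @param n_boot bootstrap replicates for median/mode estimators.
#' @param presso_nsim MR-PRESSO simulation count.
#' @param direction `"forward"`, `"reverse"` (exposure and outcome tables
#'   swapped, same thresholds) or `"both"`.
#' @param seed mandatory root seed; all stochastic stages derive their
#'   streams from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(iv_pvalue = 1e-5, clump_r2 = 0.001,
                            clump_kb = 10000, min_f = 10,
                            palindrome_policy = "drop",
                            ivw_variant = "multiplicative_random",
                            screen_alpha = 0.01, fdr_alpha = 0.05,
                            leg_alpha = 0.05, n_boot = 1000,
                            presso_nsim = 1000,
                            direction = c("forward", "reverse", "both"),
                            seed) {
  assert_that(!missing(seed), "seed is mandatory", "mrmediate_config_error")
  direction <- match.arg(direction)
  assert_that(iv_pvalue > 0 && iv_pvalue < 1 && clump_r2 >= 0 &&
                clump_r2 <= 1 && clump_kb >= 0 && min_f >= 0,
              "threshold out of range", "mrmediate_config_error")
  structure(list(iv_pvalue = iv_pvalue, clump_r2 = clump_r2,
                 clump_kb = clump_kb, min_f = min_f,
                 palindrome_policy = palindrome_policy,
                 ivw_variant = ivw_variant, screen_alpha = screen_alpha,
                 fdr_alpha = fdr_alpha, leg_alpha = leg_alpha,
                 n_boot = n_boot, presso_nsim = presso_nsim,
                 direction = direction, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(x)
    paste(format(x, digits = 15), collapse = ","), character(1)),
    collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)))
}

pair_skip <- function(reason, exposure_id, outcome_id, counts = NULL) {
  structure(list(skipped = TRUE, reason = reason, exposure_id = exposure_id,
                 outcome_id = outcome_id, counts = counts),
            class = "pair_skip")
}

#' Run one exposure/outcome MR pair
#'
#' Instrument selection, harmonization, the full estimator battery, and the
#' sensitivity report. Any stage ending with too few instruments produces a
#' structured skip record (never an error), carrying the stage counts.
#'
#' @param exposure,outcome `summary_stats` tables.
#' @param panel an `ld_panel` for clumping.
#' @param config a [pipeline_config()].
#' @param direction `"forward"` (default from config) or `"reverse"`, which
#'   swaps the exposure and outcome tables under the same thresholds.
#' @return a `pair_report` list: `estimates` (tidy data.frame over methods),
#'   `sensitivity`, `hset`, `counts` (variants surviving each stage),
#'   `seed`, `config_hash` — or a `pair_skip`.
#' @export
run_pair <- function(exposure, outcome, panel, config,
                     direction = config$direction) {
  if (identical(direction, "reverse")) {
    tmp <- exposure; exposure <- outcome; outcome <- tmp
  }
  eid <- trait_id(exposure); oid <- trait_id(outcome)
  counts <- c(input = nrow(exposure))
  screened <- filter_by_pvalue(exposure, config$iv_pvalue)
  counts["screened"] <- nrow(screened)
  if (nrow(screened) == 0) {
    return(pair_skip("no variants pass the instrument p-value screen",
                     eid, oid, counts))
  }
  clumped <- ld_clump(screened, panel, config$clump_r2, config$clump_kb)
  counts["clumped"] <- nrow(clumped)
  ivs <- compute_f_statistics(clumped, config$min_f)
  counts["strong"] <- nrow(ivs)
  if (nrow(ivs) == 0) {
    return(pair_skip("weak instruments: all F below threshold",
                     eid, oid, counts))
  }
  hset <- tryCatch(
    harmonize(ivs, outcome, palindrome_policy = config$palindrome_policy),
    mrmediate_insufficient_instruments = function(e) NULL)
  if (is.null(hset)) {
    return(pair_skip("no variants survive harmonization", eid, oid, counts))
  }
  counts["harmonized"] <- nrow(hset)

  pair_seed <- split_seed(config$seed, paste0("pair:", eid, "->", oid))
  estimates <- mr_all_methods(hset, seed = pair_seed, n_boot = config$n_boot,
                              ivw_variant = config$ivw_variant)
  sens <- if (nrow(hset) >= 2) {
    sensitivity_report(hset, seed = pair_seed,
                       presso_nsim = config$presso_nsim)
  } else NULL
  structure(list(skipped = FALSE, exposure_id = eid, outcome_id = oid,
                 estimates = estimates, sensitivity = sens, hset = hset,
                 counts = counts, seed = pair_seed,
                 config_hash = config_hash(config)),
            class = "pair_report")
}

#' @export
print.pair_report <- function(x, ...) {
  cat(sprintf("<pair_report> %s -> %s (%d instruments)\n", x$exposure_id,
              x$outcome_id, nrow(x$hset)))
  print(x$estimates)
  invisible(x)
}

#' @export
print.pair_skip <- function(x, ...) {
  cat(sprintf("<pair_skip> %s -> %s: %s\n", x$exposure_id, x$outcome_id,
              x$reason))
  invisible(x)
}

ivw_row <- function(report) {
  if (inherits(report, "pair_skip")) return(NULL)
  est <- report$estimates[report$estimates$method == "ivw", , drop = FALSE][1, ]
  est
}

screen_family <- function(reports, fdr_alpha, screen_alpha) {
  rows <- do.call(rbind, Filter(Negate(is.null), lapply(reports, ivw_row)))
  if (is.null(rows) || nrow(rows) == 0) {
    return(data.frame())
  }
  rows$fdr <- bh_fdr(rows$pvalue)
  rows$tier <- classify_evidence(rows$pvalue, rows$fdr,
                                 fdr_alpha = fdr_alpha)
  rows$reported <- rows$pvalue < screen_alpha
  rows
}

#' Two-step MR mediation scan
#'
#' The full study workflow over trait families:
#' \enumerate{
#'   \item exposure family vs outcome, IVW-screened with
#'     Benjamini-Hochberg FDR within the family;
#'   \item mediator family vs outcome, likewise;
#'   \item for each surviving (exposure, mediator) pair, the
#'     exposure-to-mediator leg at `leg_alpha`;
#'   \item a [two_step_mediation()] decomposition for every surviving
#'     triangle.
#' }
#' Exposures/mediators survive a screen when reported at `screen_alpha` and
#' not tiered `"none"`. The scan is invariant to the ordering of the input
#' lists and deterministic under the config seed.
#'
#' @param exposures,mediators lists of `summary_stats` tables.
#' @param outcome a `summary_stats` table.
#' @param panel an `ld_panel`.
#' @param config a [pipeline_config()].
#' @return a `scan_report`: `exposure_screen` and `mediator_screen`
#'   (tidy data.frames with fdr and tier), `legs`, `mediation` (data.frame,
#'   Table-style), `mediation_results` (list of `mediation_result`),
#'   `pair_reports`, `counts`, `seed`, `config_hash`.
#' @export
run_mediation_scan <- function(exposures, mediators, outcome, panel, config) {
  stopifnot(length(exposures) >= 1, length(mediators) >= 1)
  exp_ids <- vapply(exposures, trait_id, character(1))
  med_ids <- vapply(mediators, trait_id, character(1))
  names(exposures) <- exp_ids
  names(mediators) <- med_ids
  # order-invariance: process in lexicographic trait order
  exposures <- exposures[order(exp_ids)]
  mediators <- mediators[order(med_ids)]

  exp_reports <- lapply(exposures, run_pair, outcome = outcome,
                        panel = panel, config = config,
                        direction = "forward")
  med_reports <- lapply(mediators, run_pair, outcome = outcome,
                        panel = panel, config = config,
                        direction = "forward")

  exp_screen <- screen_family(exp_reports, config$fdr_alpha,
                              config$screen_alpha)
  med_screen <- screen_family(med_reports, config$fdr_alpha,
                              config$screen_alpha)
  surviving <- function(screen) {
    if (nrow(screen) == 0) character(0) else
      screen$exposure[screen$reported & screen$tier != "none"]
  }
  exp_keep <- surviving(exp_screen)
  med_keep <- surviving(med_screen)

  legs <- list()
  triangles <- list()
  med_rows <- list()
  for (e in exp_keep) {
    for (m in med_keep) {
      leg <- run_pair(exposures[[e]], mediators[[m]], panel, config,
                      direction = "forward")
      legs[[paste(e, m, sep = "->")]] <- leg
      leg_est <- ivw_row(leg)
      if (is.null(leg_est) || leg_est$pvalue >= config$leg_alpha) next
      est_a <- ivw(leg$hset, config$ivw_variant)
      est_b <- ivw(med_reports[[m]]$hset, config$ivw_variant)
      est_t <- ivw(exp_reports[[e]]$hset, config$ivw_variant)
      tri <- two_step_mediation(est_a, est_b, est_t,
                                exposure_id = e, mediator_id = m,
                                outcome_id = trait_id(outcome))
      triangles[[paste(e, m, sep = "->")]] <- tri
      med_rows[[length(med_rows) + 1L]] <- data.frame(
        exposure = e, mediator = m, outcome = trait_id(outcome),
        mediated = tri$mediated, mediated_ci_low = tri$mediated_ci[1],
        mediated_ci_high = tri$mediated_ci[2], mediated_p = tri$mediated_p,
        total = tri$total, direct = tri$direct,
        proportion_pct = tri$proportion_pct,
        proportion_ci_low = tri$proportion_ci[1],
        proportion_ci_high = tri$proportion_ci[2],
        inconsistent = tri$inconsistent, stringsAsFactors = FALSE)
    }
  }

  structure(list(
    exposure_screen = exp_screen, mediator_screen = med_screen,
    exposures_surviving = exp_keep, mediators_surviving = med_keep,
    legs = legs, mediation_results = triangles,
    mediation = if (length(med_rows)) do.call(rbind, med_rows) else
      data.frame(),
    pair_reports = list(exposures = exp_reports, mediators = med_reports),
    counts = c(exposures = length(exposures), mediators = length(mediators),
               exposures_surviving = length(exp_keep),
               mediators_surviving = length(med_keep),
               triangles = length(triangles)),
    seed = config$seed, config_hash = config_hash(config)
  ), class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat("<scan_report>\n")
  print(x$counts)
  if (nrow(x$mediation) > 0) {
    cat("mediation triangles:\n")
    print(x$mediation)
  }
  invisible(x)
}

write_tsv_provenance <- function(df, path, config) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash=%s seed=%d", config_hash(config),
                     config$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Write the scan report's forest and mediation tables
#'
#' estimates.tsv (all methods for every screened pair), sensitivity.tsv,
#' loo.tsv and mediation.tsv, each prefixed with a provenance comment line
#' carrying the config hash and root seed.
#'
#' @param report a `scan_report`.
#' @param out_dir output directory (created if needed).
#' @param config the `pipeline_config` used.
#' @return invisibly, the vector of file paths.
#' @export
write_scan_report <- function(report, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_reports <- c(report$pair_reports$exposures,
                   report$pair_reports$mediators)
  ok <- Filter(function(r) !inherits(r, "pair_skip"), all_reports)
  est <- do.call(rbind, c(lapply(ok, `[[`, "estimates"),
                          make.row.names = FALSE))
  sens <- do.call(rbind, lapply(ok, function(r) {
    s <- r$sensitivity
    if (is.null(s)) return(NULL)
    data.frame(exposure = r$exposure_id, outcome = r$outcome_id,
               q_stat = s$q_stat, q_df = s$q_df, q_pvalue = s$q_pvalue,
               egger_intercept = s$egger_intercept %||% NA_real_,
               egger_intercept_p = s$egger_intercept_p %||% NA_real_,
               presso_global_p = if (is.null(s$presso)) NA_real_ else
                 s$presso$global_p,
               presso_outliers = if (is.null(s$presso)) "" else
                 paste(s$presso$outlier_snp_ids, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  loo <- do.call(rbind, lapply(ok, function(r) {
    if (is.null(r$sensitivity$loo)) return(NULL)
    cbind(exposure = r$exposure_id, outcome = r$outcome_id,
          r$sensitivity$loo)
  }))
  paths <- c(estimates = file.path(out_dir, "estimates.tsv"),
             sensitivity = file.path(out_dir, "sensitivity.tsv"),
             loo = file.path(out_dir, "loo.tsv"),
             mediation = file.path(out_dir, "mediation.tsv"))
  write_tsv_provenance(est, paths["estimates"], config)
  write_tsv_provenance(sens %||% data.frame(), paths["sensitivity"], config)
  write_tsv_provenance(loo %||% data.frame(), paths["loo"], config)
  write_tsv_provenance(report$mediation, paths["mediation"], config)
  invisible(paths)
}
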