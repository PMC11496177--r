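# Reading, validating and writing GWAS summary-statistic tables and LD panels.
#
# Canonical on-disk format: tab-separated with fixed header
#   snp_id chrom pos effect_allele other_allele eaf beta se pvalue n
# Coordinates are 1-based (GWAS-catalog convention). Only biallelic SNPs with
# single-base alleles are accepted; indels and multi-allelic records are
# rejected at read time.

CANONICAL_COLUMNS <- c("snp_id", "chrom", "pos", "effect_allele",
                       "other_allele", "eaf", "beta", "se", "pvalue", "n")

#' Construct a validated summary-statistic table
#'
#' The central per-trait container: one row per variant with its effect-allele
#' association (`beta` is a log-odds ratio for binary traits, SD units for
#' continuous traits). Rows violating the invariants (non-ACGT or identical
#' alleles, `se <= 0`, `pvalue` outside (0, 1], out-of-range `eaf`, duplicate
#' `snp_id`) are dropped with a message; passing rows are never mutated beyond
#' upper-casing alleles.
#'
#' @param df data.frame holding (a subset of) the canonical columns.
#' @param trait_id character label for the trait.
#' @return a `summary_stats` object: a data.frame with canonical columns and a
#'   `trait_id` attribute.
#' @export
summary_stats <- function(df, trait_id = "trait") {
  stopifnot(is.data.frame(df))
  for (col in c("eaf", "n")) if (is.null(df[[col]])) df[[col]] <- NA_real_
  missing <- setdiff(setdiff(CANONICAL_COLUMNS, c("eaf", "n")), names(df))
  assert_that(length(missing) == 0,
              paste0("missing mandatory column(s): ",
                     paste(missing, collapse = ", ")),
              class = "mrmediate_config_error")
  df <- df[, CANONICAL_COLUMNS, drop = FALSE]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "n")) {
    df[[col]] <- as.numeric(df[[col]])
  }

  n_in <- nrow(df)
  ok <- !is.na(df$snp_id) & !is.na(df$beta) & !is.na(df$se) & !is.na(df$pvalue)
  ok <- ok & df$effect_allele %in% c("A", "C", "G", "T")
  ok <- ok & df$other_allele %in% c("A", "C", "G", "T")
  ok <- ok & df$effect_allele != df$other_allele
  ok <- ok & df$se > 0
  ok <- ok & df$pvalue > 0 & df$pvalue <= 1
  ok <- ok & (is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1))
  ok[is.na(ok)] <- FALSE
  ok <- ok & !duplicated(df$snp_id)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) < n_in) {
    log_note("summary_stats[%s]: dropped %d of %d rows failing validation",
             trait_id, n_in - nrow(df), n_in)
  }
  rownames(df) <- NULL
  structure(df, trait_id = trait_id, class = c("summary_stats", "data.frame"))
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> trait '%s': %d variants\n",
              attr(x, "trait_id"), nrow(x)))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Trait label of a summary-statistic table
#' @param x a `summary_stats` object.
#' @return character trait id.
#' @export
trait_id <- function(x) attr(x, "trait_id")

#' Read a GWAS summary-statistic table
#'
#' Reads a tab- or comma-separated file (delimiter sniffed from the header
#' line), renames columns via `column_map`, and validates through
#' [summary_stats()].
#'
#' @param path file path.
#' @param column_map named character vector mapping file column names to
#'   canonical names, e.g. `c(ES = "beta", SE = "se", P = "pvalue")`. Columns
#'   already canonically named need no entry.
#' @param trait_id trait label; defaults to the file name without extension.
#' @return a `summary_stats` object.
#' @export
read_summary_stats <- function(path, column_map = NULL, trait_id = NULL) {
  assert_that(file.exists(path), paste0("file not found: ", path),
              class = "mrmediate_io_error")
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  if (!is.null(column_map)) {
    absent <- setdiff(names(column_map), names(df))
    assert_that(length(absent) == 0,
                paste0("column_map names absent from file: ",
                       paste(absent, collapse = ", ")),
                class = "mrmediate_config_error")
    names(df)[match(names(column_map), names(df))] <- unname(column_map)
  }
  tid <- trait_id %||% sub("\\.[^.]*$", "", basename(path))
  out <- summary_stats(df, trait_id = tid)
  assert_that(nrow(out) > 0, paste0("no valid rows in ", path),
              class = "mrmediate_empty_input_error")
  out
}

#' Write a summary-statistic table in the canonical TSV format
#'
#' `read_summary_stats(write_summary_stats(x))` reproduces `x` exactly.
#'
#' @param table a `summary_stats` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(table, path) {
  stopifnot(inherits(table, "summary_stats"))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Construct an LD panel
#'
#' Pairwise squared-correlation (r^2) matrix over a set of SNPs, as produced
#' from a reference panel such as 1000 Genomes Europeans. Unstated pairs are
#' unlinked (r^2 = 0).
#'
#' @param snp_ids character vector of SNP ids.
#' @param r2 symmetric matrix of squared correlations in \[0, 1\] with unit
#'   diagonal, dimnames matching `snp_ids`.
#' @param positions optional base-pair positions aligned with `snp_ids`.
#' @return an `ld_panel` object.
#' @export
ld_panel <- function(snp_ids, r2, positions = NULL) {
  snp_ids <- as.character(snp_ids)
  r2 <- as.matrix(r2)
  assert_that(nrow(r2) == length(snp_ids) && ncol(r2) == length(snp_ids),
              "r2 dimensions must match snp_ids", "mrmediate_format_error")
  if (length(snp_ids) > 0) {
    assert_that(max(abs(r2 - t(r2))) <= 1e-9, "r2 matrix is not symmetric",
                "mrmediate_format_error")
    r2 <- (r2 + t(r2)) / 2
    diag(r2) <- 1
  }
  assert_that(all(r2 >= 0 & r2 <= 1), "r2 entries must lie in [0, 1]",
              "mrmediate_format_error")
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, r2 = r2, positions = positions),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("<ld_panel> %d SNPs, %d linked pairs (r2 > 0)\n",
              length(x$snp_ids),
              (sum(x$r2 > 0) - length(x$snp_ids)) / 2))
  invisible(x)
}

#' Pairwise r-squared lookup
#'
#' @param panel an `ld_panel`.
#' @param a,b SNP id vectors (recycled). SNPs absent from the panel are
#'   treated as unlinked (r^2 = 0, and 1 with themselves).
#' @return numeric vector of r^2 values.
#' @export
ld_r2 <- function(panel, a, b) {
  out <- ifelse(a == b, 1, 0)
  ia <- match(a, panel$snp_ids)
  ib <- match(b, panel$snp_ids)
  hit <- !is.na(ia) & !is.na(ib)
  out[hit] <- panel$r2[cbind(ia[hit], ib[hit])]
  out
}

#' Read an LD panel from disk
#'
#' Accepts either a long-format TSV with columns (snp_a, snp_b, r2) — missing
#' pairs default to r^2 = 0 — or a square CSV matrix whose header and first
#' column carry SNP ids.
#'
#' @param path file path.
#' @return an `ld_panel` object.
#' @export
read_ld_panel <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path),
              class = "mrmediate_io_error")
  header <- readLines(path, n = 1L)
  if (grepl("snp_a", header, fixed = TRUE)) {
    long <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    ids <- sort(unique(c(long$snp_a, long$snp_b)))
    r2 <- diag(1, length(ids))
    dimnames(r2) <- list(ids, ids)
    for (k in seq_len(nrow(long))) {
      i <- match(long$snp_a[k], ids)
      j <- match(long$snp_b[k], ids)
      if (i != j && r2[i, j] != 1 && abs(r2[i, j]) > 0 &&
          abs(r2[i, j] - long$r2[k]) > 1e-9) {
        assert_that(FALSE, "conflicting duplicate LD entries",
                    "mrmediate_format_error")
      }
      r2[i, j] <- r2[j, i] <- long$r2[k]
    }
    ld_panel(ids, r2)
  } else {
    m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
    ld_panel(colnames(m), m)
  }
}

#' Write an LD panel in long format
#'
#' Only off-diagonal pairs with r^2 > 0 are written; [read_ld_panel()]
#' restores absent pairs as unlinked.
#'
#' @param panel an `ld_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_panel <- function(panel, path) {
  idx <- which(upper.tri(panel$r2) & panel$r2 > 0, arr.ind = TRUE)
  long <- data.frame(snp_a = panel$snp_ids[idx[, 1]],
                     snp_b = panel$snp_ids[idx[, 2]],
                     r2 = panel$r2[idx])
  # ensure every snp id appears at least once so the roster round-trips
  lonely <- setdiff(panel$snp_ids,
                    unique(c(long$snp_a, long$snp_b)))
  if (length(lonely) > 0) {
    long <- rbind(long, data.frame(snp_a = lonely, snp_b = lonely, r2 = 1))
  }
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
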