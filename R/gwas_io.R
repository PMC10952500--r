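# Reading, harmonizing and filtering two-trait GWAS summary statistics.
#
# Records are plain data.frames with standardized column names so downstream
# code never needs to know what the input files called their columns.

STANDARD_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "beta", "se", "pvalue", "info", "n_studies", "eaf")
REQUIRED_COLS <- c("snp_id", "effect_allele", "other_allele", "beta", "se")

# common aliases seen in GWAS-catalog-style files, lowercased
DEFAULT_ALIASES <- list(
  snp_id        = c("snp_id", "snp", "rsid", "rs_id", "markername", "variant_id", "id"),
  chrom         = c("chrom", "chr", "chromosome"),
  pos           = c("pos", "bp", "position", "base_pair_location"),
  effect_allele = c("effect_allele", "a1", "ea", "allele1", "alt"),
  other_allele  = c("other_allele", "a2", "oa", "nea", "allele2", "ref",
                    "non_effect_allele"),
  beta          = c("beta", "b", "effect", "loghr", "log_hr", "logor", "log_or"),
  se            = c("se", "stderr", "standard_error", "sebeta"),
  pvalue        = c("pvalue", "p", "pval", "p_value", "p.value"),
  info          = c("info", "imputation_r2", "rsq", "r2"),
  n_studies     = c("n_studies", "nstudies", "n_cohorts"),
  eaf           = c("eaf", "effect_allele_frequency", "af", "maf", "freq1")
)

#' Read a GWAS summary-statistics file
#'
#' Reads a delimited text file (tab- or whitespace-separated, optionally
#' gzip-compressed) of per-SNP association results and returns a data.frame
#' with standardized columns. Column names are matched case-insensitively
#' against common conventions; `column_map` overrides the matching for
#' nonstandard headers.
#'
#' Rows whose `beta` or `se` fail numeric parsing, have `se <= 0`, carry
#' alleles outside A/C/G/T, or have identical effect and other alleles are
#' dropped with a logged count. Duplicate SNP ids keep the record with the
#' smallest standard error (ties broken by file order).
#'
#' @param path path to the file; `.gz` files are read transparently.
#' @param column_map optional named character vector mapping standard names
#'   (e.g. `beta`) to the column names used in the file (e.g. `"Effect"`).
#' @return data.frame with columns `snp_id`, `effect_allele`, `other_allele`,
#'   `beta`, `se` and, when present in the file, `chrom`, `pos`, `pvalue`,
#'   `info`, `n_studies`, `eaf`. The number of dropped rows is attached as
#'   attribute `n_dropped`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("snp_id\teffect_allele\tother_allele\tbeta\tse",
#'              "rs1\tA\tG\t0.2\t0.05"), tf)
#' read_sumstats(tf)
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  first <- readLines(con <- gzfile(path), n = 1L); close(con)
  if (length(first) == 0L || !nzchar(first)) stop("empty summary-statistics file: ", path)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ""
  raw <- read.table(gzfile(path), header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "\"",
                    colClasses = "character")
  if (nrow(raw) == 0L) stop("summary-statistics file has a header but no data rows: ", path)

  idx <- resolve_columns(names(raw), column_map)
  for (req in REQUIRED_COLS) {
    if (is.na(idx[[req]]))
      stop("required column '", req, "' not found in ", path,
           " (header: ", paste(names(raw), collapse = ", "), ")")
  }

  out <- data.frame(snp_id = as.character(raw[[idx[["snp_id"]]]]),
                    effect_allele = toupper(trimws(raw[[idx[["effect_allele"]]]])),
                    other_allele = toupper(trimws(raw[[idx[["other_allele"]]]])),
                    beta = suppressWarnings(as.numeric(raw[[idx[["beta"]]]])),
                    se = suppressWarnings(as.numeric(raw[[idx[["se"]]]])),
                    stringsAsFactors = FALSE)
  for (opt in c("chrom", "pos", "pvalue", "info", "n_studies", "eaf")) {
    if (!is.na(idx[[opt]])) {
      col <- raw[[idx[[opt]]]]
      out[[opt]] <- if (opt == "chrom") as.character(col)
                    else suppressWarnings(as.numeric(col))
    }
  }

  bad <- !is.finite(out$beta) | !is.finite(out$se) | out$se <= 0 |
    !(out$effect_allele %in% c("A", "C", "G", "T")) |
    !(out$other_allele %in% c("A", "C", "G", "T")) |
    out$effect_allele == out$other_allele |
    !nzchar(out$snp_id)
  if (!is.null(out$pos)) bad <- bad | (!is.na(out$pos) & out$pos < 1)
  n_dropped <- sum(bad)
  if (n_dropped > 0L) {
    ib_log("dropped ", n_dropped, " of ", nrow(out),
           " rows failing parse/validity checks in ", basename(path))
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("no valid rows remain in ", path)

  # duplicate ids: keep smallest se, deterministic tie-break by file order
  if (anyDuplicated(out$snp_id)) {
    ord <- order(out$snp_id, out$se, seq_len(nrow(out)))
    keep <- ord[!duplicated(out$snp_id[ord])]
    n_dup <- nrow(out) - length(keep)
    ib_log("removed ", n_dup, " duplicated snp_id rows (kept smallest se)")
    out <- out[sort(keep), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

resolve_columns <- function(header, column_map) {
  lower <- tolower(header)
  idx <- vapply(STANDARD_COLS, function(std) {
    if (!is.null(column_map) && std %in% names(column_map)) {
      m <- match(column_map[[std]], header)
      if (is.na(m)) return(NA_integer_)
      return(m)
    }
    hits <- which(lower %in% DEFAULT_ALIASES[[std]])
    if (length(hits)) hits[1L] else NA_integer_
  }, integer(1))
  idx
}

#' Write summary statistics or harmonized pairs to a TSV file
#'
#' Numeric columns are written with 17 significant digits so a write/read
#' round trip reproduces the doubles exactly. Paths ending in `.gz` are
#' gzip-compressed.
#'
#' @param x data.frame of summary records or harmonized pairs.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- x
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
write_pairs <- write_sumstats

#' Read a harmonized-pairs TSV written by [write_pairs()]
#'
#' @param path path to a tab-delimited file with columns `snp_id`, `beta_gx`,
#'   `se_gx`, `beta_gy`, `se_gy` and optionally `flipped`.
#' @return data.frame of harmonized pairs.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("pairs file not found: ", path)
  x <- read.table(gzfile(path), header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  need <- c("snp_id", "beta_gx", "se_gx", "beta_gy", "se_gy")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("pairs file missing column(s): ", paste(miss, collapse = ", "))
  if ("flipped" %in% names(x)) x$flipped <- as.logical(x$flipped)
  x
}

complement_allele <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic <- function(a1, a2) a1 == complement_allele(a2)

#' Harmonize risk and survival summary statistics to a common effect allele
#'
#' Intersects two summary-statistics tables on SNP id and aligns the survival
#' effect to the risk file's effect allele. When the survival file reports the
#' same alleles the effect is kept; when effect and other alleles are swapped
#' the survival beta is negated (`flipped = TRUE`); alleles reconcilable only
#' by strand complement are complemented first and then the same rules apply.
#' Palindromic SNPs (A/T or C/G) are strand-ambiguous and dropped by default;
#' SNPs with irreconcilable allele sets are dropped with a logged count.
#'
#' @param risk data.frame from [read_sumstats()] for the disease-risk GWAS
#'   (betas are log odds ratios).
#' @param survival data.frame from [read_sumstats()] for the case-only
#'   survival GWAS (betas are log hazard ratios).
#' @param drop_palindromic drop A/T and C/G SNPs (default `TRUE`).
#' @return data.frame with columns `snp_id`, `beta_gx`, `se_gx`, `beta_gy`,
#'   `se_gy`, `flipped`; attribute `n_dropped` counts SNPs lost to allele
#'   mismatch or palindromy (intersection losses are not counted).
#' @export
harmonize <- function(risk, survival, drop_palindromic = TRUE) {
  stopifnot(nrow(risk) > 0L, nrow(survival) > 0L)
  m <- merge(risk[, c("snp_id", "effect_allele", "other_allele", "beta", "se")],
             survival[, c("snp_id", "effect_allele", "other_allele", "beta", "se")],
             by = "snp_id", suffixes = c("_x", "_y"))
  if (nrow(m) == 0L)
    stop("no SNPs shared between risk and survival summary statistics")

  same      <- m$effect_allele_x == m$effect_allele_y & m$other_allele_x == m$other_allele_y
  swap      <- m$effect_allele_x == m$other_allele_y  & m$other_allele_x == m$effect_allele_y
  comp_same <- m$effect_allele_x == complement_allele(m$effect_allele_y) &
               m$other_allele_x  == complement_allele(m$other_allele_y)
  comp_swap <- m$effect_allele_x == complement_allele(m$other_allele_y) &
               m$other_allele_x  == complement_allele(m$effect_allele_y)
  palin <- is_palindromic(m$effect_allele_x, m$other_allele_x) |
           is_palindromic(m$effect_allele_y, m$other_allele_y)

  keep <- (same | swap | comp_same | comp_swap)
  if (drop_palindromic) keep <- keep & !palin
  flipped <- (swap | comp_swap) & !(same | comp_same)

  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    ib_log("dropped ", n_dropped, " SNPs with irreconcilable",
           if (drop_palindromic) " or palindromic", " alleles")

  out <- data.frame(snp_id = m$snp_id[keep],
                    beta_gx = m$beta_x[keep],
                    se_gx = m$se_x[keep],
                    beta_gy = ifelse(flipped[keep], -m$beta_y[keep], m$beta_y[keep]),
                    se_gy = m$se_y[keep],
                    flipped = flipped[keep],
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) stop("no SNPs remain after allele harmonization")
  out <- out[order(match(out$snp_id, risk$snp_id)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Filter harmonized pairs on imputation quality, study count and a keep-list
#'
#' Applies the panel-quality filters used when selecting SNPs for bias-slope
#' estimation: a minimum imputation quality (e.g. R-squared 0.99), a minimum
#' number of contributing studies (e.g. 4 in a meta-analysis), and an optional
#' explicit keep-list of SNP ids standing in for an LD-pruned panel (LD
#' pruning itself needs genotype data and is out of scope). QC fields are
#' looked up in `records` by SNP id; SNPs whose QC field is absent pass that
#' filter with a logged warning, since available columns differ across
#' datasets.
#'
#' @param pairs data.frame from [harmonize()].
#' @param records data.frame from [read_sumstats()] supplying `info` and/or
#'   `n_studies`; may be `NULL` when only `keep_list` is used.
#' @param min_info minimum imputation quality in \[0, 1\].
#' @param min_studies minimum number of studies (non-negative integer).
#' @param keep_list optional character vector of SNP ids to retain.
#' @return filtered pairs data.frame (possibly empty, which is logged).
#' @export
filter_snps <- function(pairs, records = NULL, min_info = 0, min_studies = 0,
                        keep_list = NULL) {
  stopifnot(min_info >= 0, min_info <= 1, min_studies >= 0)
  keep <- rep(TRUE, nrow(pairs))

  if (min_info > 0) {
    info <- lookup_qc(pairs$snp_id, records, "info")
    keep <- keep & (is.na(info) | info >= min_info)
  }
  if (min_studies > 0) {
    ns <- lookup_qc(pairs$snp_id, records, "n_studies")
    keep <- keep & (is.na(ns) | ns >= min_studies)
  }
  if (!is.null(keep_list)) keep <- keep & (pairs$snp_id %in% keep_list)

  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) ib_log("all SNPs removed by filters")
  out
}

lookup_qc <- function(ids, records, field) {
  if (is.null(records) || is.null(records[[field]])) {
    warning("QC column '", field, "' unavailable; treating all SNPs as passing",
            call. = FALSE)
    return(rep(NA_real_, length(ids)))
  }
  vals <- records[[field]][match(ids, records$snp_id)]
  if (anyNA(vals))
    warning(sum(is.na(vals)), " SNPs lack '", field,
            "'; treated as passing", call. = FALSE)
  vals
}
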