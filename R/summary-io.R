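# Reading, validation and writing of GWAS summary statistics and LD tables.

#' Canonical summary-statistic column names
#'
#' The canonical per-SNP fields used throughout the package. Input files may
#' use any column names; [read_summary_stats()] maps them onto this set.
#'
#' @format A character vector.
#' @keywords internal
CANONICAL_FIELDS <- c("snp_id", "chrom", "pos", "effect_allele",
                      "other_allele", "eaf", "beta", "se", "z", "p", "n")

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a summary table
#'
#' A summary table is a `data.frame` of per-SNP association records for one
#' trait, one row per SNP, with the canonical columns `snp_id`, `chrom`,
#' `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `z`, `p`,
#' `n`. Missing numeric fields are `NA`. The trait name and measurement
#' units are carried as attributes.
#'
#' @param records data.frame containing at least `snp_id`, alleles, `p`, `n`
#'   and one of (`beta` + `se`) or `z`.
#' @param trait_name Name of the trait the statistics describe.
#' @param trait_units Units of the per-allele effects (e.g. `"SD"`, `"mm^2"`,
#'   `"mm"`, `"mm^3"`).
#' @return A `data.frame` of class `summary_table`.
#' @export
summary_table <- function(records, trait_name = "trait", trait_units = "SD") {
  stopifnot(is.data.frame(records))
  for (f in CANONICAL_FIELDS) {
    if (is.null(records[[f]])) records[[f]] <- NA
  }
  records <- records[, CANONICAL_FIELDS]
  if (anyDuplicated(records$snp_id)) {
    stop("duplicate snp_id in summary table: ",
         paste(unique(records$snp_id[duplicated(records$snp_id)]),
               collapse = ", "))
  }
  structure(records,
            trait_name = trait_name,
            trait_units = trait_units,
            class = c("summary_table", "data.frame"))
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d SNPs\n",
              attr(x, "trait_name"), attr(x, "trait_units"), nrow(x)))
  NextMethod()
}

# Row-level validation used by read_summary_stats. Returns a character vector
# of rejection reasons, "" for valid rows.
.validate_rows <- function(d) {
  reason <- character(nrow(d))
  flag <- function(bad, why) {
    bad <- which(bad & reason == "")
    reason[bad] <<- why
  }
  flag(is.na(d$snp_id) | d$snp_id == "", "missing snp_id")
  flag(!(d$effect_allele %in% VALID_ALLELES) |
         !(d$other_allele %in% VALID_ALLELES), "invalid allele")
  flag(d$effect_allele == d$other_allele, "effect_allele == other_allele")
  flag(!is.na(d$pos) & d$pos < 0, "negative position")
  flag(!is.na(d$eaf) & (d$eaf < 0 | d$eaf > 1), "eaf outside [0,1]")
  flag(!is.na(d$se) & d$se <= 0, "non-positive se")
  has_beta_se <- !is.na(d$beta) & !is.na(d$se)
  flag(!has_beta_se & is.na(d$z), "neither beta+se nor z present")
  flag(is.na(d$p) | d$p < 0 | d$p > 1, "p outside (0,1]")
  flag(is.na(d$n) | d$n <= 0, "non-positive n")
  # duplicates are judged among rows still valid at this point, so a valid
  # row is never dropped for sharing an id with an already-rejected one
  ids <- d$snp_id
  ids[reason != ""] <- paste0("\r.invalid.", which(reason != ""))
  flag(duplicated(ids), "duplicate snp_id")
  reason
}

#' Read GWAS summary statistics
#'
#' Reads a header-bearing, tab- or whitespace-separated summary-statistic
#' file (optionally gzipped) into a [summary_table()]. Column names in the
#' file are mapped onto the canonical field set via `column_map`. Every input
#' row is either kept as a valid record or dropped with a recorded reason;
#' the drop log is attached as attribute `"drop_log"` and the counts always
#' sum to the number of data rows.
#'
#' Validation per row: alleles must be A/C/G/T and distinct; at least one of
#' (`beta` and `se`) or `z` must be present; `p` must lie in (0,1] (`p = 0`
#' is clamped to the smallest positive double, with a warning); `n` must be
#' positive. When `beta`, `se` and `p` are all present but `p` disagrees with
#' the two-sided normal p-value implied by `beta/se` by more than 10%
#' (relative), a warning is emitted; the row is kept.
#'
#' @param path Path to the file.
#' @param column_map Named character vector mapping canonical field names to
#'   source column names, e.g. `c(snp_id = "SNP", p = "pval")`. Canonical
#'   names absent from the map are looked up verbatim; canonical fields with
#'   no source column are filled with `NA` (subject to the row invariants).
#' @param trait_name,trait_units Passed to [summary_table()].
#' @return A `summary_table`. Attribute `"drop_log"` is a data.frame with
#'   columns `row`, `snp_id`, `reason`; attribute `"n_dropped"` its row count.
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               trait_name = basename(path),
                               trait_units = "SD") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE,
                           comment.char = "", check.names = FALSE)
  if (nrow(raw) == 0L) stop("no data rows in ", path)

  d <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in CANONICAL_FIELDS) {
    src <- if (!is.null(column_map) && f %in% names(column_map))
      column_map[[f]] else f
    if (!is.null(column_map) && f %in% names(column_map) &&
        !(src %in% names(raw))) {
      stop("column_map refers to absent column '", src, "' for field '",
           f, "'")
    }
    d[[f]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  d$snp_id <- as.character(d$snp_id)
  d$chrom <- as.character(d$chrom)
  d$effect_allele <- toupper(as.character(d$effect_allele))
  d$other_allele <- toupper(as.character(d$other_allele))
  for (f in c("pos", "eaf", "beta", "se", "z", "p", "n")) {
    d[[f]] <- suppressWarnings(as.numeric(d[[f]]))
  }

  zero_p <- !is.na(d$p) & d$p == 0
  if (any(zero_p)) {
    d$p[zero_p] <- .Machine$double.xmin
    warning(sum(zero_p), " rows had p = 0; clamped to smallest positive value")
  }

  reason <- .validate_rows(d)
  keep <- reason == ""
  drop_log <- data.frame(row = which(!keep),
                         snp_id = d$snp_id[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (!any(keep)) stop("zero valid rows in ", path)

  kept <- d[keep, , drop = FALSE]
  chk <- !is.na(kept$beta) & !is.na(kept$se) & !is.na(kept$p)
  if (any(chk)) {
    p_imp <- 2 * stats::pnorm(-abs(kept$beta[chk] / kept$se[chk]))
    bad <- p_imp > 0 & abs(kept$p[chk] - p_imp) / p_imp > 0.10
    if (any(bad)) {
      warning(sum(bad), " rows have p inconsistent with (beta/se)^2 ",
              "beyond 10% relative tolerance")
    }
  }

  out <- summary_table(kept, trait_name = trait_name,
                       trait_units = trait_units)
  attr(out, "drop_log") <- drop_log
  attr(out, "n_dropped") <- nrow(drop_log)
  out
}

# --- LD tables ---------------------------------------------------------------

.ld_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Construct an LD table
#'
#' A symmetric lookup of pairwise r-squared between SNPs. Pairs are stored
#' under an unordered key, so `ld_r2(ld, a, b) == ld_r2(ld, b, a)`. Absent
#' pairs are treated as r-squared 0 by consumers such as [ld_prune()].
#'
#' @param id_a,id_b Character vectors of SNP identifiers.
#' @param r2 Numeric vector of r-squared values in \[0, 1\].
#' @return An object of class `ld_table`.
#' @export
ld_table <- function(id_a = character(), id_b = character(),
                     r2 = numeric()) {
  stopifnot(length(id_a) == length(id_b), length(id_b) == length(r2))
  if (any(is.na(r2)) || any(r2 < 0 | r2 > 1)) {
    stop("r2 values must lie in [0, 1]")
  }
  self <- id_a == id_b
  if (any(r2[self] != 1)) stop("self-pairs must have r2 = 1")
  key <- .ld_key(id_a, id_b)
  # duplicate pairs keep the maximum r2
  if (anyDuplicated(key)) {
    agg <- tapply(r2, key, max)
    pairs <- stats::setNames(as.numeric(agg), names(agg))
  } else {
    pairs <- stats::setNames(r2, key)
  }
  structure(list(pairs = pairs), class = "ld_table")
}

#' @export
print.ld_table <- function(x, ...) {
  cat(sprintf("LD table: %d SNP pairs\n", length(x$pairs)))
  invisible(x)
}

#' Read a pairwise LD table
#'
#' Reads a three-column text file (`id_a`, `id_b`, `r2`, header optional)
#' into an [ld_table()]. Duplicate pairs keep the maximum r-squared; values
#' outside \[0, 1\] are an error.
#'
#' @param path Path to the file.
#' @return An `ld_table`.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- utils::read.table(path, header = FALSE, sep = "", nrows = 1,
                             stringsAsFactors = FALSE)
  has_header <- ncol(first) >= 3 && is.na(suppressWarnings(
    as.numeric(first[[3]])))
  d <- utils::read.table(path, header = has_header, sep = "",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("LD table must have three columns: id_a, id_b, r2")
  r2 <- suppressWarnings(as.numeric(d[[3]]))
  if (any(is.na(r2))) stop("non-numeric r2 in LD table")
  ld_table(as.character(d[[1]]), as.character(d[[2]]), r2)
}

#' Look up pairwise r-squared
#'
#' @param ld An `ld_table` (or `NULL`, in which case 0 is returned).
#' @param a,b SNP identifiers (vectorised).
#' @return Numeric vector of r-squared values; 0 for absent pairs.
#' @export
ld_r2 <- function(ld, a, b) {
  if (is.null(ld)) return(rep(0, length(a)))
  stopifnot(inherits(ld, "ld_table"))
  v <- unname(ld$pairs[.ld_key(a, b)])
  v[is.na(v)] <- 0
  v
}

# --- Report writing ----------------------------------------------------------

REPORT_COLUMNS <- c("exposure", "outcome", "method", "nSNP", "beta",
                    "ci_low", "ci_high", "p", "p_adjusted", "Q", "Q_p",
                    "egger_intercept", "egger_intercept_p")

#' Write an MR report table
#'
#' Serialises a collection of causal-estimate results to a tab-separated
#' table with the fixed column set `exposure`, `outcome`, `method`, `nSNP`,
#' `beta`, `ci_low`, `ci_high`, `p`, `p_adjusted`, `Q`, `Q_p`,
#' `egger_intercept`, `egger_intercept_p`. Numeric cells are written at 6
#' significant digits and the file round-trips losslessly at that precision;
#' unavailable diagnostics (e.g. MR-PRESSO with too few SNPs) render as
#' `NA`.
#'
#' @param results A data.frame with (a subset of) the report columns, or a
#'   list of [mr_result] objects.
#' @param path Output file path.
#' @return Invisibly, the data.frame written.
#' @seealso [read_report()]
#' @export
write_report <- function(results, path) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, as.data.frame))
  }
  stopifnot(is.data.frame(results), nrow(results) > 0)
  for (col in REPORT_COLUMNS) {
    if (is.null(results[[col]])) results[[col]] <- NA
  }
  out <- results[, REPORT_COLUMNS]
  num <- !(REPORT_COLUMNS %in% c("exposure", "outcome", "method", "nSNP"))
  for (col in REPORT_COLUMNS[num]) {
    out[[col]] <- signif(as.numeric(out[[col]]), 6)
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  utils::write.table(format(out, digits = 15, trim = TRUE, nsmall = 0,
                            scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(out)
}

#' Read back an MR report table
#'
#' @param path Path written by [write_report()].
#' @return data.frame with the report columns.
#' @export
read_report <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
}
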