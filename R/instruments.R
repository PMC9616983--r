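# Instrument selection and quality control.

#' Reconstruct beta and SE from a z-statistic
#'
#' Some GWAS (notably the hippocampal-volume meta-analysis used here as a
#' template) release only the per-SNP z-statistic and p-value. Under an
#' additive model the standard error of the standardized regression
#' coefficient is `se = 1 / sqrt(2 * MAF * (1 - MAF) * (N + z^2))` and the
#' coefficient itself is `beta = z * se`, where MAF is the minor-allele
#' frequency and N the sample size. `beta / se` reproduces `z` exactly.
#'
#' @param z z-statistic (vectorised).
#' @param maf Minor-allele frequency in (0, 0.5].
#' @param n Sample size (>= 1).
#' @return A data.frame with columns `beta` and `se`.
#' @export
beta_se_from_z <- function(z, maf, n) {
  if (any(is.na(maf)) || any(maf <= 0 | maf > 0.5)) {
    stop("maf must lie in (0, 0.5]")
  }
  if (any(is.na(n)) || any(n < 1)) stop("n must be >= 1")
  se <- 1 / sqrt(2 * maf * (1 - maf) * (n + z^2))
  data.frame(beta = z * se, se = se)
}

#' Variance in the exposure explained by one SNP
#'
#' `R^2 = (beta * sqrt(2 * MAF * (1 - MAF)))^2 = beta^2 * 2 * MAF * (1 - MAF)`
#' for an SD-scaled per-allele effect `beta`. Frequencies above 0.5 are taken
#' to be effect-allele frequencies and folded to `MAF = min(f, 1 - f)`.
#'
#' @param beta Per-allele effect in SD units of the exposure.
#' @param maf Allele frequency in \[0, 1\]; folded to the minor allele.
#' @return R-squared in \[0, 1\].
#' @export
variance_explained <- function(beta, maf) {
  if (any(!is.na(maf) & (maf < 0 | maf > 1))) {
    stop("maf must lie in [0, 1]")
  }
  maf <- pmin(maf, 1 - maf)
  beta^2 * 2 * maf * (1 - maf)
}

#' Instrument-strength F-statistic
#'
#' Per-SNP Wald form `F = (beta / se)^2`; values at or below 10 are flagged
#' as weak by convention. The approximation `F = R^2 (n - 2) / (1 - R^2)`
#' from the variance explained is available via `method = "r2"` (the two
#' agree asymptotically for a single SNP).
#'
#' @param beta,se Per-allele effect and its standard error (`method="wald"`).
#' @param r2,n Variance explained and sample size (`method="r2"`).
#' @param method `"wald"` (default) or `"r2"`.
#' @return Numeric vector of F-statistics with a logical attribute `"weak"`
#'   (`TRUE` where `F <= 10`).
#' @export
f_statistic <- function(beta = NULL, se = NULL, r2 = NULL, n = NULL,
                        method = c("wald", "r2")) {
  method <- match.arg(method)
  f <- if (method == "wald") {
    if (any(is.na(se)) || any(se <= 0)) stop("se must be positive")
    (beta / se)^2
  } else {
    stopifnot(!is.null(r2), !is.null(n))
    r2 * (n - 2) / (1 - r2)
  }
  attr(f, "weak") <- f <= 10
  f
}

#' Greedy LD pruning
#'
#' Enforces approximately independent instruments: records are visited in
#' order of ascending p-value (ties broken by chromosome, position, then
#' SNP id for determinism) and a SNP is accepted iff its r-squared with every
#' already-accepted SNP does not exceed `r2_max`. When two SNPs are in LD the
#' one with the smaller p-value is therefore retained. Pairs absent from the
#' LD table are treated as r-squared 0.
#'
#' @param records data.frame of summary records (needs `snp_id`, `p`, and
#'   optionally `chrom`, `pos`).
#' @param ld An [ld_table()] or `NULL` (no LD: everything retained).
#' @param r2_max Maximum tolerated pairwise r-squared (default 0.001, the
#'   usual clumping convention).
#' @return The retained rows, in the original record order, with attribute
#'   `"selection_log"`: a data.frame of `(snp_id, action, reason)` rows where
#'   each rejection names the retained partner.
#' @export
ld_prune <- function(records, ld = NULL, r2_max = 0.001) {
  stopifnot(r2_max >= 0, r2_max <= 1)
  n <- nrow(records)
  if (n == 0) {
    attr(records, "selection_log") <- data.frame(
      snp_id = character(), action = character(), reason = character())
    return(records)
  }
  chrom <- if (is.null(records$chrom)) rep("", n) else as.character(records$chrom)
  pos <- if (is.null(records$pos)) rep(0, n) else records$pos
  ord <- order(records$p, chrom, pos, records$snp_id)
  accepted <- character(0)
  action <- character(n)
  reason <- character(n)
  for (i in ord) {
    id <- records$snp_id[i]
    if (length(accepted) == 0) {
      accepted <- id; action[i] <- "retained"; reason[i] <- ""
      next
    }
    r2 <- ld_r2(ld, rep(id, length(accepted)), accepted)
    if (all(r2 <= r2_max)) {
      accepted <- c(accepted, id)
      action[i] <- "retained"; reason[i] <- ""
    } else {
      action[i] <- "pruned"
      reason[i] <- paste0("in LD (r2=", max(r2), ") with retained ",
                          accepted[which.max(r2)])
    }
  }
  keep <- records[records$snp_id %in% accepted, , drop = FALSE]
  attr(keep, "selection_log") <- data.frame(
    snp_id = records$snp_id[ord], action = action[ord], reason = reason[ord],
    stringsAsFactors = FALSE)
  keep
}

#' Select and QC genetic instruments for one exposure
#'
#' Pipeline: (1) exclude SNPs associated with more than one trait
#' (`cross_trait_snps`); (2) keep SNPs with `p <= p_threshold`;
#' (3) greedy LD pruning via [ld_prune()]; (4) per-SNP F-statistics and
#' variance explained, summed (additive model, no interactions) to a total
#' R-squared. If fewer than `min_snps` SNPs survive, an empty set flagged
#' `insufficient = TRUE` is returned — the caller may then retry at a more
#' relaxed threshold (the usual fallback is 5e-8 then 5e-6 with at least 3
#' SNPs required).
#'
#' SNPs lacking a beta/se but carrying a z-statistic are completed via
#' [beta_se_from_z()] (requires `eaf` and `n`). SNPs with missing `eaf`
#' contribute `NA` to the per-SNP R-squared and are omitted from the total,
#' with a warning.
#'
#' @param table A [summary_table()] for the exposure.
#' @param p_threshold Selection p-value threshold.
#' @param cross_trait_snps Character vector of SNP ids to exclude up front.
#' @param ld An [ld_table()] or `NULL`.
#' @param min_snps Minimum acceptable number of instruments (default 3).
#' @param r2_max LD pruning threshold (default 0.001).
#' @return An object of class `instrument_set`: list with `exposure_name`,
#'   `records`, `p_threshold`, `per_snp_f`, `per_snp_r2`, `total_r2`,
#'   `weak`, `selection_log`, `insufficient`, `n_snps`.
#' @export
select_instruments <- function(table, p_threshold, cross_trait_snps = character(),
                               ld = NULL, min_snps = 3, r2_max = 0.001) {
  stopifnot(p_threshold > 0, p_threshold < 1, min_snps >= 1)
  name <- attr(table, "trait_name")
  d <- as.data.frame(table)
  log <- list()

  cross <- d$snp_id %in% cross_trait_snps
  if (any(cross)) {
    log[[length(log) + 1]] <- data.frame(
      snp_id = d$snp_id[cross], action = "excluded",
      reason = "associated with multiple traits", stringsAsFactors = FALSE)
    d <- d[!cross, , drop = FALSE]
  }

  sub <- d$p > p_threshold
  if (any(sub)) {
    log[[length(log) + 1]] <- data.frame(
      snp_id = d$snp_id[sub], action = "excluded",
      reason = sprintf("p > %g", p_threshold), stringsAsFactors = FALSE)
    d <- d[!sub, , drop = FALSE]
  }

  d <- ld_prune(d, ld, r2_max)
  log[[length(log) + 1]] <- attr(d, "selection_log")
  selection_log <- do.call(rbind, log)

  # complete beta/se from z where needed (z-only sources)
  need <- is.na(d$beta) | is.na(d$se)
  if (any(need)) {
    if (any(is.na(d$eaf[need])) || any(is.na(d$n[need]))) {
      stop("cannot reconstruct beta/se from z without eaf and n")
    }
    maf <- pmin(d$eaf[need], 1 - d$eaf[need])
    bs <- beta_se_from_z(d$z[need], maf, d$n[need])
    d$beta[need] <- bs$beta
    d$se[need] <- bs$se
  }

  insufficient <- nrow(d) < min_snps
  per_snp_f <- stats::setNames(as.numeric(f_statistic(d$beta, d$se)), d$snp_id)
  no_eaf <- is.na(d$eaf)
  if (any(no_eaf)) {
    warning(sum(no_eaf), " instruments lack eaf; excluded from total R^2")
  }
  per_snp_r2 <- stats::setNames(variance_explained(d$beta, d$eaf), d$snp_id)
  structure(list(
    exposure_name = name,
    records = d,
    p_threshold = p_threshold,
    per_snp_f = per_snp_f,
    per_snp_r2 = per_snp_r2,
    total_r2 = sum(per_snp_r2, na.rm = TRUE),
    weak = per_snp_f <= 10,
    selection_log = selection_log,
    insufficient = insufficient,
    n_snps = nrow(d)
  ), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for %s: %d SNPs at p <= %g%s\n",
              x$exposure_name, x$n_snps, x$p_threshold,
              if (x$insufficient) " [INSUFFICIENT]" else ""))
  if (x$n_snps > 0) {
    cat(sprintf("  total R^2 = %.4f; F range %.1f-%.1f; %d weak (F <= 10)\n",
                x$total_r2, min(x$per_snp_f), max(x$per_snp_f), sum(x$weak)))
  }
  invisible(x)
}

#' SNPs associated with more than one trait
#'
#' Identifies SNP ids reaching `p <= p_threshold` in two or more of the
#' supplied summary tables. Used to exclude potentially pleiotropic variants
#' before instrument selection (e.g. SNPs associated with several cytokines).
#'
#' @param tables List of [summary_table()] objects.
#' @param p_threshold Association threshold defining "associated".
#' @return Character vector of SNP ids.
#' @export
cross_trait_snps <- function(tables, p_threshold) {
  hits <- unlist(lapply(tables, function(t) unique(t$snp_id[t$p <= p_threshold])))
  sort(unique(hits[duplicated(hits)]))
}
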