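# Allele harmonization between exposure and outcome summary statistics.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize one exposure/outcome record pair
#'
#' Aligns the outcome association to the exposure's effect allele so that
#' both betas refer to the same allele on the same strand. Rules, in order:
#'
#' 1. Outcome alleles equal the exposure's as-is: keep (`kept`).
#' 2. Outcome alleles are the exposure's swapped: negate the outcome beta
#'    (and mirror its frequency), `flipped`.
#' 3. Outcome alleles match after complementing both (reported on the
#'    opposite strand), possibly also swapped: `strand_corrected` (with the
#'    sign flip where swapped).
#' 4. Palindromic pair (A/T or C/G): strand cannot be resolved from alleles.
#'    If both allele frequencies are available and both fall outside the
#'    ambiguity window, the minor-allele orientation decides the alignment;
#'    otherwise `dropped_palindromic`.
#' 5. Anything else: `dropped_incompatible`.
#'
#' Harmonization is an involution: applying it to an already-aligned pair is
#' the identity, and the Wald ratio `by/bx` is invariant to which allele the
#' exposure study chose as its effect allele.
#'
#' @param exp,out Single summary records (one-row data.frames or lists) with
#'   the canonical fields; `snp_id` must agree.
#' @param ambiguity_window Numeric length-2: effect-allele-frequency interval
#'   within which a palindromic SNP is considered unresolvable. Default
#'   `c(0.42, 0.58)`; use `c(0, 1)` to drop all palindromic SNPs.
#' @return One-row data.frame: `snp_id`, `bx`, `se_x`, `by`, `se_y`,
#'   `eaf_x`, `eaf_y`, `action`. Dropped pairs carry `NA` effects.
#' @export
harmonize_pair <- function(exp, out, ambiguity_window = c(0.42, 0.58)) {
  if (exp$snp_id != out$snp_id) {
    stop("snp_id mismatch: ", exp$snp_id, " vs ", out$snp_id)
  }
  res <- function(action, by = NA_real_, se_y = NA_real_,
                  eaf_y = NA_real_) {
    data.frame(snp_id = exp$snp_id,
               bx = if (grepl("^dropped", action)) NA_real_ else exp$beta,
               se_x = if (grepl("^dropped", action)) NA_real_ else exp$se,
               by = by, se_y = se_y,
               eaf_x = .na_num(exp$eaf), eaf_y = eaf_y,
               action = action, stringsAsFactors = FALSE)
  }
  ea_x <- exp$effect_allele; oa_x <- exp$other_allele
  ea_y <- out$effect_allele; oa_y <- out$other_allele
  by <- out$beta; se_y <- out$se; eaf_y <- .na_num(out$eaf)
  eaf_x <- .na_num(exp$eaf)

  if (.is_palindromic(ea_x, oa_x)) {
    # nominal alignment ignoring strand (complement == swap for palindromes)
    if (ea_y == ea_x && oa_y == oa_x) {
      sgn <- 1
    } else if (ea_y == oa_x && oa_y == ea_x) {
      sgn <- -1; eaf_y <- 1 - eaf_y
    } else {
      return(res("dropped_incompatible"))
    }
    lo <- ambiguity_window[1]; hi <- ambiguity_window[2]
    resolvable <- !is.na(eaf_x) && !is.na(eaf_y) &&
      (eaf_x < lo || eaf_x > hi) && (eaf_y < lo || eaf_y > hi)
    if (!resolvable) return(res("dropped_palindromic"))
    if ((eaf_x < 0.5) == (eaf_y < 0.5)) {
      # frequencies concordant under the nominal alignment: same strand
      action <- if (sgn == 1) "kept" else "flipped"
      return(res(action, sgn * by, se_y, eaf_y))
    }
    # discordant: outcome is on the opposite strand, which for a palindrome
    # reverses the nominal alignment
    return(res("strand_corrected", -sgn * by, se_y, 1 - eaf_y))
  }

  if (ea_y == ea_x && oa_y == oa_x) {
    return(res("kept", by, se_y, eaf_y))
  }
  if (ea_y == oa_x && oa_y == ea_x) {
    return(res("flipped", -by, se_y, 1 - eaf_y))
  }
  cea <- .COMPLEMENT[[ea_y]]; coa <- .COMPLEMENT[[oa_y]]
  if (cea == ea_x && coa == oa_x) {
    return(res("strand_corrected", by, se_y, eaf_y))
  }
  if (cea == oa_x && coa == ea_x) {
    return(res("strand_corrected", -by, se_y, 1 - eaf_y))
  }
  res("dropped_incompatible")
}

.na_num <- function(x) if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)

#' Harmonize an instrument set against an outcome GWAS
#'
#' Intersects the instruments with the outcome table on `snp_id`
#' (instruments absent from the outcome are logged and skipped; no proxy
#' substitution), applies [harmonize_pair()] to each, and preserves
#' instrument order. Outcome tables carrying only z-statistics (no beta/se)
#' are completed via [beta_se_from_z()] beforehand when `eaf` and `n` are
#' available; when the outcome lacks `eaf` entirely, palindromic SNPs are
#' always dropped.
#'
#' @param exposure An [select_instruments()] result, a [summary_table()], or
#'   a plain data.frame of exposure records.
#' @param outcome A [summary_table()] (or data.frame) for the outcome.
#' @param ambiguity_window See [harmonize_pair()].
#' @return Object of class `harmonized_data`: list with `exposure_name`,
#'   `outcome_name`, `pairs` (all pairs incl. dropped, with `action`),
#'   `n_dropped_palindromic`, `n_dropped_incompatible`, `missing_in_outcome`.
#' @export
harmonize_set <- function(exposure, outcome, ambiguity_window = c(0.42, 0.58)) {
  if (inherits(exposure, "instrument_set")) {
    exp_name <- exposure$exposure_name
    exp_rec <- exposure$records
  } else {
    exp_name <- attr(exposure, "trait_name") %||% "exposure"
    exp_rec <- as.data.frame(exposure)
  }
  out_name <- attr(outcome, "trait_name") %||% "outcome"
  out_rec <- as.data.frame(outcome)

  # complete z-only outcome records
  need <- (is.na(out_rec$beta) | is.na(out_rec$se)) & !is.na(out_rec$z)
  can <- need & !is.na(out_rec$eaf) & !is.na(out_rec$n)
  if (any(can)) {
    maf <- pmin(out_rec$eaf[can], 1 - out_rec$eaf[can])
    bs <- beta_se_from_z(out_rec$z[can], maf, out_rec$n[can])
    out_rec$beta[can] <- bs$beta
    out_rec$se[can] <- bs$se
  }

  idx <- match(exp_rec$snp_id, out_rec$snp_id)
  missing <- exp_rec$snp_id[is.na(idx)]
  present <- which(!is.na(idx))
  pairs <- vector("list", length(present))
  for (k in seq_along(present)) {
    i <- present[k]
    pairs[[k]] <- harmonize_pair(exp_rec[i, ], out_rec[idx[i], ],
                                 ambiguity_window)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(snp_id = character(), bx = numeric(), se_x = numeric(),
               by = numeric(), se_y = numeric(), eaf_x = numeric(),
               eaf_y = numeric(), action = character())
  structure(list(
    exposure_name = exp_name,
    outcome_name = out_name,
    pairs = pairs,
    n_dropped_palindromic = sum(pairs$action == "dropped_palindromic"),
    n_dropped_incompatible = sum(pairs$action == "dropped_incompatible"),
    missing_in_outcome = missing
  ), class = "harmonized_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.harmonized_data <- function(x, ...) {
  cat(sprintf("Harmonized %s -> %s: %d pairs usable (%d palindromic, %d incompatible dropped; %d missing in outcome)\n",
              x$exposure_name, x$outcome_name,
              sum(!grepl("^dropped", x$pairs$action)),
              x$n_dropped_palindromic, x$n_dropped_incompatible,
              length(x$missing_in_outcome)))
  invisible(x)
}

# Usable (non-dropped) pairs of a harmonized_data object, or coerce a plain
# data.frame with bx/se_x/by/se_y columns.
.usable_pairs <- function(data) {
  if (inherits(data, "harmonized_data")) {
    p <- data$pairs
    p <- p[!grepl("^dropped", p$action), , drop = FALSE]
  } else {
    p <- as.data.frame(data)
  }
  stopifnot(all(c("bx", "by", "se_y") %in% names(p)))
  if (is.null(p$se_x)) p$se_x <- NA_real_
  if (is.null(p$snp_id)) p$snp_id <- paste0("snp", seq_len(nrow(p)))
  p
}
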