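# Heterogeneity and influence diagnostics.

#' Cochran's Q heterogeneity test
#'
#' Between-SNP heterogeneity of the Wald ratios about the fixed-effect IVW
#' estimate: `Q = sum_j w_j (r_j - beta_IVW)^2` with first-order weights,
#' referred to a chi-square distribution with `J - 1` degrees of freedom.
#' This is the same Q that drives the multiplicative random-effects
#' inflation in [mr_ivw()].
#'
#' @inheritParams mr_ivw
#' @return Object of class `q_result`: list with `q`, `df`, `p`.
#' @export
cochran_q <- function(data) {
  p <- .usable_pairs(data)
  j <- nrow(p)
  if (j < 2) stop("Cochran's Q requires at least 2 SNPs")
  core <- .ivw_core(p$bx, p$by, p$se_y)
  structure(list(q = core$q, df = j - 1L,
                 p = stats::pchisq(core$q, j - 1, lower.tail = FALSE)),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g\n", x$q, x$df, x$p))
  invisible(x)
}

#' Single-SNP analysis
#'
#' One Wald-ratio MR per SNP, in input order. SNPs with `bx = 0` (undefined
#' ratio) are skipped and listed in attribute `"skipped"`.
#'
#' @inheritParams mr_ivw
#' @return data.frame with columns `snp_id`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
single_snp <- function(data) {
  p <- .usable_pairs(data)
  if (nrow(p) < 1) stop("no usable pairs")
  ok <- !is.na(p$bx) & p$bx != 0
  rows <- lapply(which(ok), function(i) {
    r <- wald_ratio(p$bx[i], p$by[i], p$se_y[i], snp_id = p$snp_id[i])
    data.frame(snp_id = p$snp_id[i], beta = r$beta, se = r$se,
               ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- p$snp_id[!ok]
  out
}

#' Leave-one-out analysis
#'
#' Recomputes the IVW estimate omitting each SNP in turn, to assess whether
#' a single variant drives the pooled association. A result is flagged
#' influential when omitting that SNP moves the estimate by more than
#' `threshold` full-sample standard errors (default 1; a package convention,
#' configurable).
#'
#' @inheritParams mr_ivw
#' @param model IVW model passed to [mr_ivw()].
#' @param threshold Influence threshold in units of the full-sample SE.
#' @return data.frame with columns `snp_id` (the omitted SNP), `beta`, `se`,
#'   `ci_low`, `ci_high`, `p`, `influential`; attribute `"full"` holds the
#'   full-sample [mr_ivw()] result.
#' @export
leave_one_out <- function(data, model = "auto", threshold = 1) {
  p <- .usable_pairs(data)
  j <- nrow(p)
  if (j < 3) stop("leave-one-out requires at least 3 SNPs")
  full <- mr_ivw(p, model = model)
  rows <- lapply(seq_len(j), function(i) {
    r <- mr_ivw(p[-i, , drop = FALSE], model = model)
    data.frame(snp_id = p$snp_id[i], beta = r$beta, se = r$se,
               ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
               influential = abs(r$beta - full$beta) > threshold * full$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  out
}
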