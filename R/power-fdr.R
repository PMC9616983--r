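# Analytic power for continuous outcomes and grouped BH-FDR adjustment.

#' Minimal detectable causal effect
#'
#' Normal-approximation power calculation for two-sample MR with a
#' continuous outcome (the mRnd-style formula). The smallest standardized
#' causal effect detectable with probability `power` at two-sided level
#' `alpha`, given an outcome GWAS of `n` individuals and instruments
#' explaining a fraction `r2` of the exposure variance, is
#'
#' `beta_min = (z_(1-alpha/2) + z_power) / sqrt(n * r2)`
#'
#' using the dominant rejection tail of the two-sided test.
#'
#' @param n Outcome GWAS sample size.
#' @param r2 Variance in the exposure explained by the instruments, in
#'   \[0, 1\].
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @return The detectable effect (outcome units per SD of exposure).
#' @seealso [mr_power()] for the inverse calculation.
#' @export
detectable_effect <- function(n, r2, alpha = 0.05, power = 0.8) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, r2 >= 0, r2 <= 1)
  if (any(n * r2 == 0)) stop("n * r2 must be positive")
  (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / sqrt(n * r2)
}

#' Analytic power for a hypothesized causal effect
#'
#' Inverse of [detectable_effect()]:
#' `power = Phi(sqrt(n * r2) * |beta| - z_(1-alpha/2))`. At `beta = 0` this
#' returns `alpha/2` (the dominant tail of the two-sided test); evaluated at
#' the output of [detectable_effect()] it returns the target power.
#'
#' @inheritParams detectable_effect
#' @param beta Hypothesized causal effect (outcome units per SD exposure).
#' @return Power in \[alpha/2, 1).
#' @export
mr_power <- function(n, r2, beta, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, r2 >= 0, r2 <= 1)
  if (any(n * r2 == 0)) stop("n * r2 must be positive")
  stats::pnorm(sqrt(n * r2) * abs(beta) - stats::qnorm(1 - alpha / 2))
}

#' Grouped Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR adjustment applied independently within each group label:
#' within a group of m p-values sorted ascending, the adjusted value at rank
#' i is `min_(k >= i) p_k * m / k`, capped at 1, with the original order
#' restored. Grouping avoids excessive stringency when several outcome
#' traits are tested against many exposures: each trait (or pooled trait
#' family, e.g. cortical surface area together with thickness) forms its own
#' adjustment family.
#'
#' @param pvalues Numeric vector of p-values in (0, 1\].
#' @param groups Vector of group labels, same length (default: one group).
#' @return data.frame with columns `p`, `p_adjusted`, `group` in the input
#'   order.
#' @export
bh_adjust <- function(pvalues, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(pvalues))
  stopifnot(length(pvalues) == length(groups))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  adj <- rep(NA_real_, length(pvalues))
  for (g in unique(groups)) {
    i <- which(groups == g)
    adj[i] <- stats::p.adjust(pvalues[i], method = "BH")
  }
  data.frame(p = pvalues, p_adjusted = adj, group = as.character(groups),
             stringsAsFactors = FALSE)
}
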