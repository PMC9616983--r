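# Synthetic paired GWAS summary statistics with known causal effect.

#' Simulation configuration
#'
#' Parameters of the canonical two-sample MR data-generating process: for
#' SNP j with minor-allele frequency `m_j`, a SNP-exposure effect `gamma_j`
#' is drawn from a normal truncated from below (`gamma >= lower`, so the
#' effect allele is the exposure-increasing allele and the instruments are
#' detectable at the configured exposure sample size), a
#' direct SNP-outcome (pleiotropic) effect `alpha_j` is drawn according to
#' `pleiotropy_mode`, and the true SNP-outcome effect is
#' `Gamma_j = causal_beta * gamma_j + alpha_j`. Observed betas are the true
#' effects plus normal noise with the standardized-trait standard error
#' `se = 1 / sqrt(2 m_j (1 - m_j) n)`.
#'
#' Defaults emulate the template study: a cytokine GWAS of 8293 individuals
#' (SD-scaled effects) as exposure and a cognitive-performance GWAS of
#' 257,841 as outcome, with effect sizes large enough to reach the relaxed
#' 5e-6 selection threshold.
#'
#' @param n_snps Number of SNPs (default 50).
#' @param n_exposure,n_outcome GWAS sample sizes (defaults 8293, 257841).
#' @param causal_beta True causal effect, SD outcome per SD exposure
#'   (default 0.1).
#' @param gamma_dist List `(mean, sd, lower)` for the SNP-exposure effects
#'   (default mean 0, sd 0.15, truncated below at 0.15).
#' @param pleiotropy_mode `"none"`, `"balanced"`, `"directional"` or
#'   `"correlated"`.
#' @param pleiotropy_sd SD of the direct SNP-outcome effects (default 0.05
#'   where applicable).
#' @param pleiotropy_mean Mean direct effect under `"directional"`
#'   (default 0.05).
#' @param frac_pleiotropic Fraction of SNPs carrying a direct effect
#'   (default 1; set below 0.5 to stay within the weighted median's
#'   breakdown point).
#' @param inside_corr Correlation between instrument strength `|gamma|` and
#'   the direct effect under `"correlated"` (InSIDE violation; default 0.5).
#' @param maf_range Interval within (0, 0.5\] for minor-allele frequencies
#'   (default c(0.1, 0.5)).
#' @param ld_block_size SNPs per LD block (default 1: independent SNPs).
#' @param ld_within_r2 Pairwise r-squared within a block (default 0.3).
#' @param frac_palindromic Fraction of SNPs given A/T or C/G allele pairs.
#' @param frac_strand_flipped Fraction of (non-palindromic) SNPs whose
#'   outcome alleles are reported on the opposite strand.
#' @param z_only_outcome If `TRUE` the outcome table omits beta/se and
#'   carries only z and p (as the hippocampal-volume GWAS does).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_snps = 50,
                              n_exposure = 8293,
                              n_outcome = 257841,
                              causal_beta = 0.1,
                              gamma_dist = list(mean = 0, sd = 0.15,
                                                lower = 0.15),
                              pleiotropy_mode = c("none", "balanced",
                                                  "directional", "correlated"),
                              pleiotropy_sd = 0.05,
                              pleiotropy_mean = 0.05,
                              frac_pleiotropic = 1,
                              inside_corr = 0.5,
                              maf_range = c(0.1, 0.5),
                              ld_block_size = 1,
                              ld_within_r2 = 0.3,
                              frac_palindromic = 0,
                              frac_strand_flipped = 0,
                              z_only_outcome = FALSE,
                              seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snps >= 1, n_exposure >= 1, n_outcome >= 1,
            gamma_dist$sd >= 0, is.numeric(gamma_dist$lower),
            pleiotropy_sd >= 0,
            frac_pleiotropic >= 0, frac_pleiotropic <= 1,
            inside_corr >= -1, inside_corr <= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            ld_block_size >= 1, ld_within_r2 >= 0, ld_within_r2 <= 1,
            frac_palindromic >= 0, frac_palindromic <= 1,
            frac_strand_flipped >= 0, frac_strand_flipped <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

# Normal draw truncated from below at `lower`, by rejection.
.rtrunc_lower <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lower
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lower
  }
  x
}

NON_PALINDROMIC_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
PALINDROMIC_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate a paired exposure/outcome GWAS
#'
#' Generates exposure and outcome summary-statistic tables under the
#' structural model described in [simulation_config()], together with the
#' emitted LD table (SNPs within a block share the configured r-squared) and
#' the generating truth. Strand-flipped SNPs have both outcome alleles
#' complemented; palindromic SNPs receive A/T or C/G allele pairs (and are
#' never strand-flipped, to keep the truth well defined).
#'
#' @param config A [simulation_config()].
#' @return List with elements `exposure` and `outcome`
#'   ([summary_table()]s), `ld` ([ld_table()]) and `truth` (list:
#'   `causal_beta`, `per_snp_gamma`, `per_snp_alpha`, `outlier_ids`).
#' @export
simulate_gwas_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_snps
  ids <- sprintf("rs%05d", seq_len(n))
  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])

  gd <- config$gamma_dist
  gamma <- .rtrunc_lower(n, gd$mean, gd$sd, gd$lower)
  alpha <- rep(0, n)
  carrier <- stats::runif(n) < config$frac_pleiotropic
  if (config$pleiotropy_mode == "balanced") {
    alpha[carrier] <- stats::rnorm(sum(carrier), 0, config$pleiotropy_sd)
  } else if (config$pleiotropy_mode == "directional") {
    alpha[carrier] <- stats::rnorm(sum(carrier), config$pleiotropy_mean,
                                   config$pleiotropy_sd)
  } else if (config$pleiotropy_mode == "correlated") {
    rho <- config$inside_corr
    strength <- abs(gamma[carrier])
    zs <- if (length(strength) > 1 && stats::sd(strength) > 0)
      as.numeric(scale(strength)) else rep(0, length(strength))
    alpha[carrier] <- config$pleiotropy_sd *
      (rho * zs + sqrt(1 - rho^2) * stats::rnorm(sum(carrier)))
  }
  Gamma <- config$causal_beta * gamma + alpha

  se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * config$n_outcome)
  bx <- gamma + stats::rnorm(n, 0, se_x)
  by <- Gamma + stats::rnorm(n, 0, se_y)

  # alleles: palindromic subset first, remainder non-palindromic
  n_pal <- round(config$frac_palindromic * n)
  pal <- seq_len(n) %in% sample.int(n, n_pal)
  alle <- matrix("", n, 2)
  alle[pal, ] <- PALINDROMIC_PAIRS[
    sample.int(nrow(PALINDROMIC_PAIRS), sum(pal), replace = TRUE), ,
    drop = FALSE]
  alle[!pal, ] <- NON_PALINDROMIC_PAIRS[
    sample.int(nrow(NON_PALINDROMIC_PAIRS), sum(!pal), replace = TRUE), ,
    drop = FALSE]
  eaf <- ifelse(stats::runif(n) < 0.5, maf, 1 - maf)

  blocks <- rep(seq_len(ceiling(n / config$ld_block_size)),
                each = config$ld_block_size)[seq_len(n)]
  exposure <- summary_table(data.frame(
    snp_id = ids, chrom = as.character(blocks), pos = 1e4 * seq_len(n),
    effect_allele = alle[, 1], other_allele = alle[, 2],
    eaf = eaf, beta = bx, se = se_x, z = bx / se_x,
    p = 2 * stats::pnorm(-abs(bx / se_x)), n = config$n_exposure,
    stringsAsFactors = FALSE), trait_name = "sim_exposure",
    trait_units = "SD")

  out_alle <- alle
  flip <- stats::runif(n) < config$frac_strand_flipped & !pal
  out_alle[flip, ] <- cbind(.COMPLEMENT[alle[flip, 1]],
                            .COMPLEMENT[alle[flip, 2]])
  out_rec <- data.frame(
    snp_id = ids, chrom = as.character(blocks), pos = 1e4 * seq_len(n),
    effect_allele = out_alle[, 1], other_allele = out_alle[, 2],
    eaf = eaf, beta = by, se = se_y, z = by / se_y,
    p = 2 * stats::pnorm(-abs(by / se_y)), n = config$n_outcome,
    stringsAsFactors = FALSE)
  if (config$z_only_outcome) {
    out_rec$beta <- NA_real_
    out_rec$se <- NA_real_
  }
  outcome <- summary_table(out_rec, trait_name = "sim_outcome",
                           trait_units = "SD")

  # within-block pairwise LD
  ld_a <- character(0); ld_b <- character(0); ld_v <- numeric(0)
  if (config$ld_block_size > 1 && config$ld_within_r2 > 0) {
    for (b in unique(blocks)) {
      members <- ids[blocks == b]
      if (length(members) > 1) {
        cmb <- utils::combn(members, 2)
        ld_a <- c(ld_a, cmb[1, ]); ld_b <- c(ld_b, cmb[2, ])
        ld_v <- c(ld_v, rep(config$ld_within_r2, ncol(cmb)))
      }
    }
  }
  ld <- ld_table(ld_a, ld_b, ld_v)

  truth <- list(causal_beta = config$causal_beta,
                per_snp_gamma = stats::setNames(gamma, ids),
                per_snp_alpha = stats::setNames(alpha, ids),
                outlier_ids = ids[abs(alpha) > 2 * se_y])
  list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
}

#' Deterministic 3-SNP worked example
#'
#' A fixed fixture used across the estimator documentation and tests: three
#' non-palindromic, pre-aligned SNPs with exposure betas (0.1, 0.2, 0.15),
#' exposure SEs (0.01, 0.02, 0.015), outcome betas (0.02, 0.05, 0.03) and
#' outcome SEs (0.01, 0.02, 0.015). The Wald ratios are (0.2, 0.25, 0.2)
#' with equal first-order IVW weights of 100, so the fixed-effect IVW
#' estimate is 13/60 = 0.21667 with SE `1/sqrt(300)` = 0.057735, and
#' Cochran's Q is 1/6.
#'
#' @return List with `exposure` and `outcome` [summary_table()]s.
#' @export
make_worked_example <- function() {
  bx <- c(0.1, 0.2, 0.15); se_x <- c(0.01, 0.02, 0.015)
  by <- c(0.02, 0.05, 0.03); se_y <- c(0.01, 0.02, 0.015)
  base <- data.frame(
    snp_id = c("rs001", "rs002", "rs003"),
    chrom = c("1", "2", "3"), pos = c(1000, 2000, 3000),
    effect_allele = c("A", "C", "G"), other_allele = c("G", "T", "A"),
    eaf = c(0.3, 0.25, 0.4), stringsAsFactors = FALSE)
  exposure <- summary_table(
    cbind(base, data.frame(beta = bx, se = se_x, z = bx / se_x,
                           p = 2 * stats::pnorm(-abs(bx / se_x)), n = 8293)),
    trait_name = "worked_exposure", trait_units = "SD")
  outcome <- summary_table(
    cbind(base, data.frame(beta = by, se = se_y, z = by / se_y,
                           p = 2 * stats::pnorm(-abs(by / se_y)), n = 33536)),
    trait_name = "worked_outcome", trait_units = "SD")
  list(exposure = exposure, outcome = outcome)
}
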