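# Causal estimators for harmonized two-sample summary data.
#
# All estimators use first-order weights w_j = bx_j^2 / se_y_j^2 on the Wald
# ratios (equivalently 1/se_y^2 in the regression parameterisation), the
# default of the standard two-sample MR tooling; the uncertainty of the
# SNP-exposure association enters only through the parametric bootstrap and
# simulation procedures.

Z975 <- stats::qnorm(0.975)

#' Construct an MR result
#'
#' Container for one estimator's causal estimate: point estimate, standard
#' error, 95% confidence interval, two-sided p-value, number of SNPs, and a
#' method-specific `extras` list (e.g. the Egger intercept or the PRESSO
#' verdicts).
#'
#' @param method One of `"wald"`, `"ivw"`, `"egger"`, `"weighted_median"`,
#'   `"presso"`.
#' @param beta,se Estimate and standard error.
#' @param n_snp Number of SNPs used.
#' @param extras Named list of method-specific quantities.
#' @param df Degrees of freedom for a t reference; `Inf` (default) uses the
#'   normal reference.
#' @param exposure,outcome Optional trait labels.
#' @return Object of class `mr_result`.
#' @export
mr_result <- function(method, beta, se, n_snp, extras = list(), df = Inf,
                      exposure = NA_character_, outcome = NA_character_) {
  crit <- if (is.finite(df)) stats::qt(0.975, df) else Z975
  p <- if (is.na(beta) || is.na(se) || se == 0) {
    if (!is.na(beta) && !is.na(se) && se == 0) {
      if (beta == 0) 1 else .Machine$double.xmin
    } else NA_real_
  } else if (is.finite(df)) {
    2 * stats::pt(-abs(beta / se), df)
  } else {
    2 * stats::pnorm(-abs(beta / se))
  }
  if (!is.na(p)) p <- max(p, .Machine$double.xmin)
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = beta - crit * se, ci_high = beta + crit * se,
    p = p, n_snp = n_snp, extras = extras,
    exposure = exposure, outcome = outcome
  ), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (95%% CI %.4g, %.4g), se = %.4g, p = %.3g, nSNP = %d\n",
              x$method, x$beta, x$ci_low, x$ci_high, x$se, x$p, x$n_snp))
  for (nm in names(x$extras)) {
    v <- x$extras[[nm]]
    if (length(v) <= 4 && (is.numeric(v) || is.character(v)))
      cat(sprintf("  %s: %s\n", nm, paste(signif_any(v), collapse = ", ")))
  }
  invisible(x)
}

signif_any <- function(v) if (is.numeric(v)) signif(v, 4) else v

#' @export
as.data.frame.mr_result <- function(x, ...) {
  e <- x$extras
  data.frame(
    exposure = x$exposure, outcome = x$outcome, method = x$method,
    nSNP = x$n_snp, beta = x$beta, ci_low = x$ci_low, ci_high = x$ci_high,
    p = x$p, p_adjusted = NA_real_,
    Q = e$Q %||% NA_real_, Q_p = e$Q_p %||% NA_real_,
    egger_intercept = e$intercept %||% NA_real_,
    egger_intercept_p = e$intercept_p %||% NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Wald ratio for a single SNP
#'
#' Per-SNP causal estimate: the SNP-outcome association divided by the
#' SNP-exposure association, `beta = by / bx`, with first-order standard
#' error `se_y / |bx|`. Invariant to a simultaneous sign flip of `bx` and
#' `by` (allele reorientation).
#'
#' @param bx,by SNP-exposure and SNP-outcome effects (same effect allele).
#' @param se_y Standard error of `by`.
#' @param snp_id Optional SNP label, stored in `extras`.
#' @return An [mr_result()] with method `"wald"`.
#' @export
wald_ratio <- function(bx, by, se_y, snp_id = NULL) {
  if (is.na(bx) || bx == 0) stop("Wald ratio undefined for bx = 0")
  mr_result("wald", beta = by / bx, se = se_y / abs(bx), n_snp = 1L,
            extras = if (is.null(snp_id)) list() else list(snp_id = snp_id))
}

# Shared IVW/Q core: fixed-effect weighted mean of Wald ratios and Cochran's
# Q about it. Single source of truth for the Q used everywhere.
.ivw_core <- function(bx, by, se_y) {
  w <- bx^2 / se_y^2
  r <- by / bx
  beta <- sum(w * r) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (r - beta)^2)
  list(beta = beta, se_fixed = se_fixed, q = q, w = w, r = r,
       j = length(bx))
}

#' Inverse-variance-weighted estimator
#'
#' Meta-analysis of the per-SNP Wald ratios weighted by the inverse of their
#' (first-order) variances: `w_j = bx_j^2 / se_y_j^2`. The fixed-effect
#' standard error is `1/sqrt(sum(w))`; the multiplicative random-effects
#' model inflates it by `sqrt(max(1, Q/(J-1)))` where Q is Cochran's
#' heterogeneity statistic. `model = "auto"` (default) uses random effects
#' when four or more SNPs are available and fixed effects otherwise; the
#' result records which was used.
#'
#' @param data A `harmonized_data` object (or data.frame with `bx`, `by`,
#'   `se_y`).
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @return An [mr_result()] with method `"ivw"`; `extras` carries `Q`,
#'   `Q_df`, `Q_p` and `model`.
#' @export
mr_ivw <- function(data, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  p <- .usable_pairs(data)
  j <- nrow(p)
  if (j < 2) stop("IVW requires at least 2 SNPs; use wald_ratio()")
  core <- .ivw_core(p$bx, p$by, p$se_y)
  if (model == "auto") model <- if (j >= 4) "random" else "fixed"
  infl <- if (model == "random") sqrt(max(1, core$q / (j - 1))) else 1
  q_p <- stats::pchisq(core$q, df = j - 1, lower.tail = FALSE)
  mr_result("ivw", beta = core$beta, se = core$se_fixed * infl, n_snp = j,
            extras = list(Q = core$q, Q_df = j - 1L, Q_p = q_p,
                          model = model),
            exposure = data$exposure_name %||% NA_character_,
            outcome = data$outcome_name %||% NA_character_)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure effects
#' with a free intercept, each pair first oriented so that `bx_j > 0`.
#' The slope is the pleiotropy-adjusted causal estimate; the intercept
#' estimates the average directional pleiotropic effect across variants — an
#' intercept different from zero signals directional pleiotropy (valid under
#' the InSIDE assumption). Weights are `1/se_y^2`; standard errors use a
#' multiplicative residual scale bounded below by 1 (no deflation), and
#' p-values use a t reference with `J - 2` degrees of freedom.
#'
#' @inheritParams mr_ivw
#' @return An [mr_result()] with method `"egger"`; `extras` carries
#'   `intercept`, `intercept_se`, `intercept_p`, `Q` (Egger residual
#'   heterogeneity) and `Q_p`.
#' @export
mr_egger <- function(data) {
  p <- .usable_pairs(data)
  j <- nrow(p)
  if (j < 3) stop("MR-Egger requires at least 3 SNPs")
  s <- sign(p$bx); s[s == 0] <- 1
  bx <- p$bx * s
  by <- p$by * s
  if (stats::var(bx) == 0) stop("degenerate design: all |bx| equal")
  w <- 1 / p$se_y^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  fit <- solve(XtWX, crossprod(X, w * by))
  resid <- by - X %*% fit
  rss <- sum(w * resid^2)
  sigma2 <- max(1, rss / (j - 2))
  cov <- sigma2 * solve(XtWX)
  int <- fit[1]; slope <- fit[2]
  int_se <- sqrt(cov[1, 1]); slope_se <- sqrt(cov[2, 2])
  int_p <- 2 * stats::pt(-abs(int / int_se), df = j - 2)
  mr_result("egger", beta = slope, se = slope_se, n_snp = j, df = j - 2,
            extras = list(intercept = int, intercept_se = int_se,
                          intercept_p = int_p, Q = rss,
                          Q_p = stats::pchisq(rss, j - 2, lower.tail = FALSE)),
            exposure = data$exposure_name %||% NA_character_,
            outcome = data$outcome_name %||% NA_character_)
}

# Weighted median of ratios r with weights w: sort ascending, normalise,
# linearly interpolate r against the cumulative weight midpoints
# p_k = S_k - w_k/2 at 0.5.
.weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w)
  pk <- s - w / 2
  if (0.5 <= pk[1]) return(r[1])
  if (0.5 >= pk[length(pk)]) return(r[length(r)])
  stats::approx(pk, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' The weighted 50th-percentile Wald ratio: consistent as long as at least
#' half of the total instrument weight comes from valid instruments, making
#' it robust to a minority of pleiotropic SNPs. Ratios are ordered and the
#' estimate is obtained by linear interpolation of the cumulative-weight
#' midpoints at 50%. The standard error comes from a parametric bootstrap:
#' `n_boot` resamples of `(bx_j, by_j)` from normal distributions centred on
#' the observed effects with their standard errors.
#'
#' @inheritParams mr_ivw
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @return An [mr_result()] with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = NULL) {
  p <- .usable_pairs(data)
  j <- nrow(p)
  if (j < 3) stop("weighted median requires at least 3 SNPs")
  w <- p$bx^2 / p$se_y^2
  est <- .weighted_median_point(p$by / p$bx, w)
  if (!is.null(seed)) set.seed(seed)
  se_x <- ifelse(is.na(p$se_x), 0, p$se_x)
  bxm <- matrix(stats::rnorm(n_boot * j, mean = rep(p$bx, each = n_boot),
                             sd = rep(se_x, each = n_boot)), n_boot, j)
  bym <- matrix(stats::rnorm(n_boot * j, mean = rep(p$by, each = n_boot),
                             sd = rep(p$se_y, each = n_boot)), n_boot, j)
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- bxm[b, ]
    bx[bx == 0] <- .Machine$double.eps
    .weighted_median_point(bym[b, ] / bx, bx^2 / p$se_y^2)
  }, numeric(1))
  mr_result("weighted_median", beta = est, se = stats::sd(boots), n_snp = j,
            exposure = data$exposure_name %||% NA_character_,
            outcome = data$outcome_name %||% NA_character_)
}

#' MR-PRESSO style outlier detection and correction
#'
#' Pleiotropy residual-sum-and-outlier procedure, assuming >50% valid
#' instruments, balanced pleiotropy and InSIDE:
#'
#' * **Global test** — the observed weighted residual sum of squares
#'   `RSS = sum_j w_j (by_j - beta_(-j) bx_j)^2`, with leave-one-out IVW
#'   slopes `beta_(-j)` and weights `w_j = 1/se_y_j^2`, is compared to its
#'   distribution under `n_sim` parametric simulations of `(bx, by)` from
#'   the fitted no-pleiotropy model; the empirical p-value uses the
#'   `(1 + #exceedances) / (1 + n_sim)` convention.
#' * **Outlier test** — each SNP's observed weighted squared residual is
#'   compared to its simulated distribution, Bonferroni-corrected at
#'   `outlier_alpha / J`.
#' * **Distortion test** — the shift between the all-SNP and
#'   outlier-removed IVW estimates is compared to a null built by removing
#'   random subsets of the same size.
#'
#' With fewer than 4 SNPs the procedure is not applicable and an
#' "unavailable" result (NA estimate, `extras$status = "unavailable"`) is
#' returned, mirroring how reports handle small instrument sets.
#'
#' @inheritParams mr_ivw
#' @param n_sim Number of parametric simulations (>= 100; default 1000).
#' @param outlier_alpha Family-wise level for the outlier test (default 0.05).
#' @param seed Optional integer seed.
#' @return An [mr_result()] with method `"presso"`; `extras` carries
#'   `global_rss`, `global_p`, `outlier_ids`, `outlier_p`, `distortion_p`,
#'   `beta_raw`, `beta_corrected`, `status`.
#' @export
mr_presso <- function(data, n_sim = 1000, outlier_alpha = 0.05, seed = NULL) {
  p <- .usable_pairs(data)
  j <- nrow(p)
  if (j < 4) {
    return(mr_result("presso", beta = NA_real_, se = NA_real_, n_snp = j,
                     extras = list(status = "unavailable",
                                   reason = "fewer than 4 SNPs"),
                     exposure = data$exposure_name %||% NA_character_,
                     outcome = data$outcome_name %||% NA_character_))
  }
  if (n_sim < 100) stop("n_sim must be at least 100 for an empirical p-value")
  if (!is.null(seed)) set.seed(seed)
  bx <- p$bx; by <- p$by; se_y <- p$se_y
  se_x <- ifelse(is.na(p$se_x), 0, p$se_x)
  w <- 1 / se_y^2

  loo_slopes <- function(bx, by, w) {
    sxy <- sum(w * bx * by); sxx <- sum(w * bx^2)
    (sxy - w * bx * by) / (sxx - w * bx^2)
  }
  b_loo <- loo_slopes(bx, by, w)
  res2_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(res2_obs)

  # parametric simulations under the fitted no-pleiotropy model
  bxm <- matrix(stats::rnorm(n_sim * j, rep(bx, each = n_sim),
                             rep(se_x, each = n_sim)), n_sim, j)
  bym <- matrix(stats::rnorm(n_sim * j, rep(b_loo * bx, each = n_sim),
                             rep(se_y, each = n_sim)), n_sim, j)
  wm <- matrix(rep(w, each = n_sim), n_sim, j)
  sxy <- rowSums(wm * bxm * bym)
  sxx <- rowSums(wm * bxm^2)
  bl <- (sxy - wm * bxm * bym) / (sxx - wm * bxm^2)
  res2_sim <- wm * (bym - bl * bxm)^2
  rss_sim <- rowSums(res2_sim)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (1 + n_sim)
  outlier_p <- (1 + colSums(res2_sim >= rep(res2_obs, each = n_sim))) /
    (1 + n_sim)
  is_out <- outlier_p < outlier_alpha / j
  outlier_ids <- p$snp_id[is_out]

  raw <- .ivw_core(bx, by, se_y)
  beta_raw <- raw$beta
  beta_corr <- NA_real_
  distortion_p <- NA_real_
  if (any(is_out) && sum(!is_out) >= 2) {
    corr <- .ivw_core(bx[!is_out], by[!is_out], se_y[!is_out])
    beta_corr <- corr$beta
    d_obs <- beta_raw - beta_corr
    k <- sum(is_out)
    d_null <- vapply(seq_len(n_sim), function(i) {
      drop <- sample.int(j, k)
      sub <- .ivw_core(bx[-drop], by[-drop], se_y[-drop])
      beta_raw - sub$beta
    }, numeric(1))
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (1 + n_sim)
    use <- corr
    j_eff <- sum(!is_out)
  } else {
    use <- raw
    j_eff <- j
  }
  infl <- sqrt(max(1, use$q / (j_eff - 1)))
  mr_result("presso", beta = use$beta, se = use$se_fixed * infl, n_snp = j,
            extras = list(global_rss = rss_obs, global_p = global_p,
                          outlier_ids = outlier_ids, outlier_p = outlier_p,
                          distortion_p = distortion_p, beta_raw = beta_raw,
                          beta_corrected = beta_corr, status = "ok"),
            exposure = data$exposure_name %||% NA_character_,
            outcome = data$outcome_name %||% NA_character_)
}
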