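# Independent oracles used to cross-check the estimators. These deliberately
# take different computational routes than the package implementation.

# Weighted least squares via base lm(): slope/intercept and their standard
# errors for the regression of by on bx with weights w. With `intercept =
# FALSE` this is the IVW estimator in its regression parameterisation.
wls_oracle <- function(bx, by, w, intercept = TRUE) {
  fit <- if (intercept) stats::lm(by ~ bx, weights = w)
  else stats::lm(by ~ 0 + bx, weights = w)
  s <- summary(fit)
  coefs <- s$coefficients
  slope_row <- if (intercept) 2 else 1
  list(slope = coefs[slope_row, 1],
       slope_se_raw = coefs[slope_row, 2] / s$sigma,  # sigma = 1 reference
       slope_se_model = coefs[slope_row, 2],
       sigma = s$sigma,
       intercept = if (intercept) coefs[1, 1] else 0,
       intercept_se_model = if (intercept) coefs[1, 2] else NA_real_)
}

# Brute-force Benjamini-Hochberg step-up: literal min over k >= i of
# p_(k) * m / k, capped at 1, order restored.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exhaustive grid search for the weighted median: the estimate is the value
# where the piecewise-linear interpolant of the cumulative-weight midpoints
# crosses 0.5; scan a dense grid of candidate values and return the
# minimiser of |F(m) - 0.5|.
weighted_median_grid <- function(r, w, grid_n = 2e5) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord] / sum(w)
  pk <- cumsum(w) - w / 2
  if (0.5 <= pk[1]) return(r[1])
  if (0.5 >= pk[length(pk)]) return(r[length(r)])
  grid <- seq(min(r), max(r), length.out = grid_n)
  fv <- stats::approx(r, pk, xout = grid, ties = "ordered")$y
  grid[which.min(abs(fv - 0.5))]
}

# Minimal harmonized data.frame for estimator tests.
hpairs <- function(bx, by, se_y, se_x = NA_real_, ids = NULL) {
  data.frame(snp_id = ids %||% paste0("s", seq_along(bx)),
             bx = bx, se_x = se_x, by = by, se_y = se_y,
             eaf_x = NA_real_, eaf_y = NA_real_, action = "kept",
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-row summary record for harmonization tests.
rec <- function(id = "rs1", ea, oa, beta = 0.1, se = 0.01, eaf = NA,
                p = 1e-9, n = 10000) {
  data.frame(snp_id = id, chrom = "1", pos = 100, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             z = beta / se, p = p, n = n, stringsAsFactors = FALSE)
}
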