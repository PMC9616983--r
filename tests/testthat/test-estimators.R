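# The 3-SNP worked fixture: ratios (0.2, 0.25, 0.2), equal weights 100.
fixture_pairs <- function() {
  we <- make_worked_example()
  harmonize_set(we$exposure, we$outcome)
}

test_that("Wald ratio divides effects and is orientation-invariant", {
  r <- wald_ratio(bx = 0.1, by = 0.02, se_y = 0.01)
  expect_equal(r$beta, 0.2)
  expect_equal(r$se, 0.1)
  expect_equal(r$ci_low, 0.2 - stats::qnorm(0.975) * 0.1)
  # null effect
  r0 <- wald_ratio(0.1, 0, 0.01)
  expect_equal(r0$beta, 0)
  expect_equal(r0$p, 1)
  # simultaneous sign flip of bx and by
  rf <- wald_ratio(-0.1, -0.02, 0.01)
  expect_equal(rf$beta, r$beta)
  expect_equal(rf$se, r$se)
  expect_error(wald_ratio(0, 0.1, 0.01), "bx = 0")
})

test_that("IVW on the worked fixture matches hand arithmetic and a WLS oracle", {
  h <- fixture_pairs()
  r <- mr_ivw(h, model = "fixed")
  expect_equal(r$beta, 13 / 60)           # (0.2+0.25+0.2)/3
  expect_equal(r$beta, 0.21667, tolerance = 1e-4)
  expect_equal(r$se, 1 / sqrt(300))
  expect_equal(r$se, 0.057735, tolerance = 1e-5)
  expect_equal(r$n_snp, 3)
  # oracle: weighted least squares of by on bx through the origin
  p <- h$pairs
  o <- wls_oracle(p$bx, p$by, 1 / p$se_y^2, intercept = FALSE)
  expect_equal(r$beta, o$slope, tolerance = 1e-10)
  expect_equal(r$se, o$slope_se_raw, tolerance = 1e-10)
})

test_that("IVW degenerates correctly: identical ratios, duplication, one pair", {
  h <- hpairs(c(0.1, 0.2, 0.4), c(0.02, 0.04, 0.08), c(0.01, 0.02, 0.01))
  r <- mr_ivw(h, model = "fixed")
  expect_equal(r$beta, 0.2)
  expect_equal(r$extras$Q, 0)
  expect_equal(mr_ivw(h, model = "random")$se, r$se)  # Q=0: fixed = random

  h1 <- fixture_pairs()$pairs
  r1 <- mr_ivw(h1, model = "fixed")
  r2 <- mr_ivw(rbind(h1, h1), model = "fixed")
  expect_equal(r2$beta, r1$beta)
  expect_equal(r2$se, r1$se / sqrt(2))

  # forced single-pair IVW equals the Wald ratio
  w <- wald_ratio(h1$bx[1], h1$by[1], h1$se_y[1])
  expect_error(mr_ivw(h1[1, ]), "at least 2")
  expect_equal(sum(h1$bx[1]^2 / h1$se_y[1]^2 * (h1$by[1] / h1$bx[1])) /
                 sum(h1$bx[1]^2 / h1$se_y[1]^2), w$beta)
})

test_that("random-effects IVW inflates the SE by sqrt(max(1, Q/(J-1)))", {
  set.seed(3)
  h <- hpairs(runif(8, 0.05, 0.3), runif(8, -0.05, 0.08),
              runif(8, 0.005, 0.02))
  rf <- mr_ivw(h, model = "fixed")
  rr <- mr_ivw(h, model = "random")
  expect_equal(rr$se, rf$se * sqrt(max(1, rf$extras$Q / 7)))
  expect_equal(mr_ivw(h, model = "auto")$extras$model, "random")
  expect_equal(mr_ivw(h[1:3, ], model = "auto")$extras$model, "fixed")
})

test_that("Egger recovers exact lines and agrees with the WLS oracle", {
  # collinear through the origin: slope 0.2, intercept 0
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h0 <- hpairs(bx, 0.2 * bx, rep(0.01, 4))
  r0 <- mr_egger(h0)
  expect_equal(r0$beta, 0.2, tolerance = 1e-12)
  expect_equal(r0$extras$intercept, 0, tolerance = 1e-12)
  expect_gt(r0$extras$intercept_p, 0.999)

  # exact affine points: slope 0.2, intercept 0.01
  h1 <- hpairs(bx, 0.01 + 0.2 * bx, rep(0.01, 4))
  r1 <- mr_egger(h1)
  expect_equal(r1$beta, 0.2, tolerance = 1e-12)
  expect_equal(r1$extras$intercept, 0.01, tolerance = 1e-12)

  # noisy heterogeneous case against lm() with residual scale >= 1
  set.seed(9)
  h2 <- hpairs(runif(10, 0.05, 0.4), rnorm(10, 0.02, 0.03),
               runif(10, 0.005, 0.02))
  r2 <- mr_egger(h2)
  o <- wls_oracle(h2$bx, h2$by, 1 / h2$se_y^2, intercept = TRUE)
  expect_equal(r2$beta, o$slope, tolerance = 1e-10)
  expect_equal(r2$extras$intercept, o$intercept, tolerance = 1e-10)
  scale <- max(1, o$sigma)
  expect_equal(r2$se, o$slope_se_model / o$sigma * scale, tolerance = 1e-10)
})

test_that("Egger orients pairs to positive bx and rejects degenerate designs", {
  h <- hpairs(c(0.1, -0.2, 0.3), c(0.02, -0.04, 0.066), rep(0.01, 3))
  hpos <- hpairs(c(0.1, 0.2, 0.3), c(0.02, 0.04, 0.066), rep(0.01, 3))
  expect_equal(mr_egger(h)$beta, mr_egger(hpos)$beta)
  expect_equal(mr_egger(h)$extras$intercept, mr_egger(hpos)$extras$intercept)
  expect_error(mr_egger(hpairs(c(0.1, 0.1, 0.1), c(1, 2, 3), rep(0.1, 3))),
               "degenerate")
  expect_error(mr_egger(fixture_pairs()$pairs[1:2, ]), "at least 3")
})

test_that("weighted median interpolates cumulative weight midpoints", {
  # midpoints (1/6, 1/2, 5/6): lands on the middle ratio
  h <- hpairs(c(1, 1, 1), c(0.2, 0.2, 0.25), c(1, 1, 1))
  r <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(r$beta, 0.2)
  # two equal-weight ratios 0.1, 0.3: midpoint interpolation gives 0.2
  h2 <- hpairs(c(1, 1, 1, 1), c(0.1, 0.1, 0.3, 0.3), c(1, sqrt(2), sqrt(2), 1))
  # collapse to the two-ratio case by exhaustive check instead:
  expect_equal(mrpipe:::.weighted_median_point(c(0.1, 0.3), c(1, 1)), 0.2)
  expect_error(mr_weighted_median(fixture_pairs()$pairs[1:2, ]), "at least 3")
})

test_that("weighted median matches exhaustive grid search on <= 6 SNPs", {
  set.seed(21)
  for (i in 1:25) {
    j <- sample(3:6, 1)
    r <- stats::runif(j, -0.5, 0.5)
    w <- stats::runif(j, 0.1, 5)
    expect_equal(mrpipe:::.weighted_median_point(r, w),
                 weighted_median_grid(r, w), tolerance = 1e-4)
  }
})

test_that("weighted median resists a minority outlier", {
  set.seed(4)
  bx <- rep(0.2, 10)
  by <- 0.2 * bx + rnorm(10, 0, 0.002)
  by[10] <- 0.2 * bx[10] + 10 * 0.01  # one ratio displaced by 10 SE
  h <- hpairs(bx, by, rep(0.01, 10))
  r <- mr_weighted_median(h, n_boot = 500, seed = 2)
  expect_lt(abs(r$beta - 0.2), 2 * r$se)
})

test_that("estimators are invariant to per-SNP sign flips and SNP order", {
  set.seed(8)
  h <- hpairs(runif(8, 0.05, 0.3), rnorm(8, 0.03, 0.02),
              runif(8, 0.005, 0.02), se_x = runif(8, 0.005, 0.02))
  flip <- sample(c(-1, 1), 8, replace = TRUE)
  hf <- h; hf$bx <- h$bx * flip; hf$by <- h$by * flip
  perm <- sample(8)
  hp <- h[perm, ]
  for (f in list(function(d) mr_ivw(d)$beta,
                 function(d) mr_egger(d)$beta,
                 function(d) mr_egger(d)$extras$intercept,
                 function(d) mr_weighted_median(d, n_boot = 50, seed = 1)$beta)) {
    expect_equal(f(hf), f(h), tolerance = 1e-12)
    expect_equal(f(hp), f(h), tolerance = 1e-12)
  }
})

test_that("all-identical ratios collapse every estimator to that ratio", {
  bx <- c(0.1, 0.15, 0.2, 0.3)
  h <- hpairs(bx, 0.25 * bx, c(0.01, 0.012, 0.009, 0.02))
  expect_equal(mr_ivw(h)$beta, 0.25)
  expect_equal(mr_egger(h)$beta, 0.25, tolerance = 1e-10)
  expect_equal(mr_egger(h)$extras$intercept, 0, tolerance = 1e-12)
  expect_equal(mr_weighted_median(h, n_boot = 100, seed = 1)$beta, 0.25)
})

test_that("PRESSO is unavailable below 4 SNPs and needs enough simulations", {
  r <- mr_presso(fixture_pairs(), seed = 1)
  expect_equal(r$extras$status, "unavailable")
  expect_true(is.na(r$beta))
  h4 <- hpairs(c(0.1, 0.2, 0.3, 0.4), c(0.02, 0.04, 0.06, 0.08),
               rep(0.01, 4))
  expect_error(mr_presso(h4, n_sim = 50, seed = 1), "at least 100")
})

test_that("PRESSO finds a planted 10-SE outlier and corrects toward truth", {
  set.seed(6)
  bx <- runif(10, 0.1, 0.3)
  se_y <- rep(0.01, 10)
  by <- 0.2 * bx + rnorm(10, 0, se_y)
  by[4] <- 0.2 * bx[4] + 10 * se_y[4]
  h <- hpairs(bx, by, se_y, se_x = rep(1e-4, 10))
  r <- mr_presso(h, n_sim = 1000, seed = 2)
  expect_equal(r$extras$status, "ok")
  expect_lt(r$extras$global_p, 0.05)
  expect_true("s4" %in% r$extras$outlier_ids)
  expect_lt(abs(r$extras$beta_corrected - 0.2),
            abs(r$extras$beta_raw - 0.2))
  expect_false(is.na(r$extras$distortion_p))
})

test_that("PRESSO global test keeps its size under the null", {
  # concordant pairs, no pleiotropy: global p should rarely fall below 0.05
  n_rej <- 0
  for (s in 1:60) {
    set.seed(100 + s)
    bx <- runif(10, 0.1, 0.3)
    se_y <- rep(0.01, 10)
    by <- 0.2 * bx + rnorm(10, 0, se_y)
    h <- hpairs(bx, by, se_y, se_x = rep(1e-4, 10))
    r <- mr_presso(h, n_sim = 300, seed = s)
    if (r$extras$global_p <= 0.05) n_rej <- n_rej + 1
  }
  expect_lte(n_rej / 60, 0.10)
})
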