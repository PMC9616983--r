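test_that("beta/se reconstruction from z matches the closed form", {
  # z = 0: beta 0, se = 1/sqrt(2 maf (1-maf) n)
  r0 <- beta_se_from_z(0, 0.3, 10000)
  expect_equal(r0$beta, 0)
  expect_equal(r0$se, 1 / sqrt(0.42 * 10000))
  # hand arithmetic: 2*0.25*0.75 = 0.375; 0.375 * (10000 + 9) = 3753.375
  r3 <- beta_se_from_z(3, 0.25, 10000)
  expect_equal(r3$se, 1 / sqrt(3753.375))
  expect_equal(r3$se, 0.016323, tolerance = 1e-4)
  expect_equal(r3$beta, 0.048968, tolerance = 1e-4)
  # algebraic identity: beta/se recovers z
  z <- c(-4.2, 0.5, 7.7)
  rr <- beta_se_from_z(z, c(0.1, 0.2, 0.5), c(5e3, 1e4, 3e4))
  expect_equal(rr$beta / rr$se, z)
  expect_error(beta_se_from_z(1, 0.6, 100), "maf")
  expect_error(beta_se_from_z(1, 0.3, 0), "n")
})

test_that("variance explained follows beta^2 * 2 maf (1-maf), folding eaf", {
  expect_equal(variance_explained(0, 0.3), 0)
  expect_equal(variance_explained(0.2, 0.3), 0.0168)
  expect_equal(variance_explained(5, 0), 0)
  # frequencies above 0.5 are effect-allele frequencies: folded
  expect_equal(variance_explained(0.2, 0.7), variance_explained(0.2, 0.3))
  # invariant to allele flipping (beta sign)
  expect_equal(variance_explained(-0.2, 0.3), variance_explained(0.2, 0.3))
})

test_that("F statistics flag weak instruments at F <= 10", {
  f <- f_statistic(0.1, 0.02)
  expect_equal(as.numeric(f), 25)
  expect_false(attr(f, "weak"))
  f2 <- f_statistic(0.0632, 0.02)
  expect_equal(as.numeric(f2), 9.9856, tolerance = 1e-6)
  expect_true(attr(f2, "weak"))
  expect_true(attr(f_statistic(0, 0.1), "weak"))
  expect_error(f_statistic(0.1, 0), "positive")
  # the R^2-based form agrees with the Wald form asymptotically (large n,
  # small r2): F_wald = (beta/se)^2 with se = 1/sqrt(2 maf (1-maf) n)
  n <- 1e6; maf <- 0.3; beta <- 0.01
  se <- 1 / sqrt(2 * maf * (1 - maf) * n)
  r2 <- variance_explained(beta, maf)
  expect_equal(as.numeric(f_statistic(r2 = r2, n = n, method = "r2")),
               as.numeric(f_statistic(beta, se)), tolerance = 1e-3)
})

test_that("LD pruning retains the smallest-p member of each correlated set", {
  recs <- rbind(rec("a", "A", "G", p = 1e-9), rec("b", "C", "T", p = 1e-8))
  ld <- ld_table("a", "b", 0.5)
  kept <- ld_prune(recs, ld, r2_max = 0.001)
  expect_equal(kept$snp_id, "a")
  log <- attr(kept, "selection_log")
  expect_equal(log$action, c("retained", "pruned"))
  expect_match(log$reason[2], "retained a")
})

test_that("uncorrelated SNPs all survive pruning, order-independently", {
  recs <- rbind(rec("a", "A", "G", p = 1e-9), rec("b", "C", "T", p = 1e-8),
                rec("c", "G", "A", p = 1e-7))
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    kept <- ld_prune(recs[perm, ], ld = NULL)
    expect_setequal(kept$snp_id, c("a", "b", "c"))
  }
})

test_that("greedy pruning of an LD chain matches brute-force enumeration", {
  # chain: a-b r2 .9, b-c r2 .9, a-c r2 0, p(a) < p(b) < p(c)
  recs <- rbind(rec("a", "A", "G", p = 1e-9), rec("b", "C", "T", p = 1e-8),
                rec("c", "G", "A", p = 1e-7))
  ld <- ld_table(c("a", "b"), c("b", "c"), c(0.9, 0.9))
  kept <- ld_prune(recs, ld)
  expect_setequal(kept$snp_id, c("a", "c"))

  # brute force: replay the greedy acceptance over the p-sorted order and
  # confirm no rejected SNP is compatible with all retained smaller-p SNPs
  log <- attr(kept, "selection_log")
  for (i in which(log$action == "pruned")) {
    before <- log$snp_id[seq_len(i - 1)][log$action[seq_len(i - 1)] == "retained"]
    expect_true(any(ld_r2(ld, rep(log$snp_id[i], length(before)), before) > 0.001))
  }
})

test_that("pruning output is a maximal greedy independent set (random LD)", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 8
    ids <- letters[1:n]
    recs <- do.call(rbind, lapply(seq_len(n), function(i)
      rec(ids[i], "A", "G", p = stats::runif(1, 1e-10, 1e-6))))
    cmb <- utils::combn(ids, 2)
    r2 <- ifelse(stats::runif(ncol(cmb)) < 0.3,
                 stats::runif(ncol(cmb), 0.1, 1), 0)
    ld <- ld_table(cmb[1, ], cmb[2, ], r2)
    kept <- ld_prune(recs, ld)$snp_id
    # retained set is internally independent
    if (length(kept) >= 2) {
      kc <- utils::combn(kept, 2)
      expect_true(all(ld_r2(ld, kc[1, ], kc[2, ]) <= 0.001))
    }
    # every rejected SNP conflicts with some retained smaller-p SNP
    rej <- setdiff(ids, kept)
    for (s in rej) {
      smaller <- kept[recs$p[match(kept, recs$snp_id)] <
                        recs$p[match(s, recs$snp_id)]]
      expect_true(any(ld_r2(ld, rep(s, length(smaller)), smaller) > 0.001))
    }
  }
})

test_that("selection applies cross-trait exclusion, thresholding, pruning, QC", {
  d <- rbind(rec("s1", "A", "G", beta = 0.2, se = 0.02, eaf = 0.3, p = 1e-10),
             rec("s2", "C", "T", beta = 0.15, se = 0.02, eaf = 0.2, p = 1e-9),
             rec("s3", "G", "A", beta = 0.12, se = 0.02, eaf = 0.4, p = 2e-7),
             rec("s4", "T", "C", beta = 0.11, se = 0.02, eaf = 0.1, p = 1e-6),
             rec("s5", "A", "C", beta = 0.05, se = 0.02, eaf = 0.3, p = 1e-2))
  tab <- summary_table(d, trait_name = "cytokine_x")

  # only 2 SNPs reach 5e-8: insufficient at min_snps = 3
  strict <- select_instruments(tab, 5e-8, min_snps = 3)
  expect_true(strict$insufficient)
  # rerun at the relaxed threshold: 4 qualify
  relaxed <- select_instruments(tab, 5e-6, min_snps = 3)
  expect_false(relaxed$insufficient)
  expect_equal(relaxed$n_snps, 4)
  expect_true(all(relaxed$records$p <= 5e-6))

  # per-SNP QC: F = (beta/se)^2, R^2 = beta^2 2 maf (1-maf), total additive
  expect_equal(unname(relaxed$per_snp_f["s1"]), 100)
  expect_equal(unname(relaxed$per_snp_r2["s1"]), 0.2^2 * 2 * 0.3 * 0.7)
  expect_equal(relaxed$total_r2, sum(relaxed$per_snp_r2))

  # the cross-trait SNP with the smallest p is excluded before pruning
  excl <- select_instruments(tab, 5e-6, cross_trait_snps = "s1")
  expect_false("s1" %in% excl$records$snp_id)
  expect_equal(excl$n_snps, 3)

  # degenerate parameters reduce selection to pure p-thresholding
  pure <- select_instruments(tab, 5e-6, r2_max = 1, min_snps = 1)
  expect_equal(pure$n_snps, 4)
})

test_that("total R^2 is invariant to record order and allele orientation", {
  d <- rbind(rec("s1", "A", "G", beta = 0.2, se = 0.02, eaf = 0.3, p = 1e-10),
             rec("s2", "C", "T", beta = -0.15, se = 0.02, eaf = 0.2, p = 1e-9),
             rec("s3", "G", "A", beta = 0.12, se = 0.02, eaf = 0.4, p = 2e-8))
  t1 <- summary_table(d, "x")
  t2 <- summary_table(d[3:1, ], "x")
  i1 <- select_instruments(t1, 5e-6, min_snps = 1)
  i2 <- select_instruments(t2, 5e-6, min_snps = 1)
  expect_equal(i1$total_r2, i2$total_r2)
  # flipping an allele negates beta and mirrors eaf; squares are unchanged
  d3 <- d
  d3$beta[1] <- -d3$beta[1]
  d3$eaf[1] <- 1 - d3$eaf[1]
  i3 <- select_instruments(summary_table(d3, "x"), 5e-6, min_snps = 1)
  expect_equal(i3$total_r2, i1$total_r2)
  expect_equal(i3$per_snp_f, i1$per_snp_f)
})

test_that("total R^2 on synthetic data matches the generating sum", {
  cfg <- simulation_config(n_snps = 200, n_exposure = 5e5, seed = 7)
  sim <- simulate_gwas_pair(cfg)
  inst <- select_instruments(sim$exposure, 5e-6, min_snps = 1)
  truth_r2 <- sum(variance_explained(sim$truth$per_snp_gamma,
                                     pmin(sim$exposure$eaf,
                                          1 - sim$exposure$eaf)))
  expect_equal(inst$total_r2, truth_r2, tolerance = 0.05)
})

test_that("cross-trait SNP identification finds shared associations", {
  t1 <- summary_table(rbind(rec("a", "A", "G", p = 1e-9),
                            rec("b", "C", "T", p = 1e-9)), "c1")
  t2 <- summary_table(rbind(rec("b", "C", "T", p = 1e-8),
                            rec("c", "G", "A", p = 0.5)), "c2")
  expect_equal(cross_trait_snps(list(t1, t2), 5e-6), "b")
  expect_equal(cross_trait_snps(list(t1), 5e-6), character(0))
})
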