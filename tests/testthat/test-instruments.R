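test_that("selection applies the p-value and minor-allele-frequency thresholds", {
  df <- variant_df(paste0("rs", 1:3), beta = 0.2, se = 0.03,
                   pval = c(1e-6, 2e-5, 1e-8))
  x <- sumstats(df, "t", "quantitative")
  sel <- select_instruments(x)
  expect_equal(sel$rsid, c("rs3", "rs1"))      # ascending p, 1e-8 then 1e-6

  # EAF filter acts on the minor allele: 0.005 and 0.995 are both excluded
  df2 <- variant_df(paste0("rs", 1:3), beta = 0.2, se = 0.03, pval = 1e-9)
  df2$eaf <- c(0.005, 0.995, 0.3)
  expect_equal(select_instruments(sumstats(df2, "t", "quantitative"))$rsid,
               "rs3")

  empty <- sumstats(variant_df(character(0), numeric(0), numeric(0)),
                    "t", "quantitative")
  expect_warning(sel0 <- select_instruments(empty), "no instruments")
  expect_equal(nrow(sel0), 0)
})

test_that("greedy clumping keeps the most significant SNP of each clump", {
  # unlinked candidates are all retained
  cand <- variant_df(paste0("rs", 1:4), beta = 0.2, se = 0.03,
                     pval = c(1e-9, 1e-7, 1e-6, 1e-8), pos = c(1, 2, 3, 4) * 1e5)
  expect_equal(nrow(ld_clump(cand, ld_reference())), 4)

  # two linked SNPs 500 kb apart: only the smaller p survives
  two <- variant_df(c("rsA", "rsB"), beta = 0.2, se = 0.03,
                    pval = c(1e-8, 1e-6), pos = c(1e6, 1.5e6))
  ld <- ld_reference(data.frame(rsid_a = "rsA", rsid_b = "rsB", r2 = 0.5))
  kept <- ld_clump(two, ld)
  expect_equal(kept$rsid, "rsA")
  expect_equal(attr(kept, "removed")$rsid, "rsB")

  # 4 SNPs, the top SNP linked only to the p=1e-8 SNP: 3 survive
  ld4 <- ld_reference(data.frame(rsid_a = "rs1", rsid_b = "rs4", r2 = 0.5))
  kept4 <- ld_clump(cand, ld4)
  expect_setequal(kept4$rsid, c("rs1", "rs2", "rs3"))

  # beyond the window (or across chromosomes) r2 is ignored
  far <- variant_df(c("rsA", "rsB"), beta = 0.2, se = 0.03,
                    pval = c(1e-8, 1e-6), pos = c(1e6, 2.5e6))
  expect_equal(nrow(ld_clump(far, ld)), 2)
  cross <- variant_df(c("rsA", "rsB"), beta = 0.2, se = 0.03,
                      pval = c(1e-8, 1e-6), pos = c(1e6, 1.2e6),
                      chrom = c("1", "2"))
  expect_equal(nrow(ld_clump(cross, ld)), 2)
})

test_that("clumping is order-invariant and matches the maximal-subset oracle", {
  for (case in 1:20) {
    seed <- 100 + case
    n <- 6
    cand <- with_seed_test(seed, {
      df <- variant_df(paste0("rs", 1:n), beta = 0.2, se = 0.03,
                       pval = runif(n, 1e-9, 1e-5),
                       pos = sort(sample(1:30, n)) * 1e5)
      df
    })
    pairs <- with_seed_test(seed + 1, {
      cmb <- combn(n, 2)
      keep <- runif(ncol(cmb)) < 0.4
      data.frame(rsid_a = paste0("rs", cmb[1, keep]),
                 rsid_b = paste0("rs", cmb[2, keep]),
                 r2 = runif(sum(keep)))
    })
    ld <- ld_reference(pairs)
    kept <- ld_clump(cand, ld)
    # order invariance
    kept_shuf <- ld_clump(cand[rev(seq_len(n)), ], ld)
    expect_equal(kept$rsid, kept_shuf$rsid)
    # every retained pair within the window has r2 below the threshold
    if (nrow(kept) > 1) {
      cmb <- combn(nrow(kept), 2)
      for (k in seq_len(ncol(cmb))) {
        i <- cmb[1, k]; j <- cmb[2, k]
        if (kept$chrom[i] == kept$chrom[j] &&
            abs(kept$pos[i] - kept$pos[j]) <= 1e6) {
          expect_lt(ld_r2(ld, kept$rsid[i], kept$rsid[j]), 0.1)
        }
      }
    }
    # greedy result is one of the maximal valid subsets
    maximal <- clump_oracle(cand, ld, r2_max = 0.1, window_kb = 1000)
    expect_true(list(sort(kept$rsid)) %in% maximal)
  }
})

test_that("proxy search returns the strongest qualifying proxy", {
  outcome <- make_sumstats(c("rsP1", "rsP2", "rsP3"), beta = 0.01, se = 0.02,
                           trait_id = "out")
  ld <- ld_reference(data.frame(rsid_a = "rsQ", rsid_b = c("rsP1", "rsP2", "rsP3"),
                                r2 = c(0.85, 0.92, 0.7)))
  expect_equal(find_proxy("rsQ", outcome, ld), "rsP2")
  # nothing above the threshold
  ld_lo <- ld_reference(data.frame(rsid_a = "rsQ", rsid_b = "rsP1", r2 = 0.7))
  expect_null(find_proxy("rsQ", outcome, ld_lo))
  # ties broken by exposure p-value
  ld_tie <- ld_reference(data.frame(rsid_a = "rsQ", rsid_b = c("rsP1", "rsP2"),
                                    r2 = 0.9))
  expect_equal(find_proxy("rsQ", outcome, ld_tie,
                          exposure_pval = c(rsP1 = 1e-7, rsP2 = 1e-6)),
               "rsP1")
})

test_that("variance explained and F-statistic match their closed forms", {
  expect_equal(variance_explained(0, 0.02, 0.5, 1539), 0)
  r2 <- variance_explained(0.1, 0.02, 0.5, 1539)
  expect_equal(r2, 0.015985, tolerance = 1e-4)
  expect_equal(f_statistic(r2, 1539), 24.97, tolerance = 1e-3)
  expect_equal(f_statistic(0, 100), 0)
  # EAF symmetry
  expect_equal(variance_explained(0.1, 0.02, 0.3, 1539),
               variance_explained(0.1, 0.02, 0.7, 1539))
  # independent algebraic route: F = (N-2) * beta^2 / (N * se^2)
  for (k in 1:10) {
    beta <- 0.05 * k; se <- 0.01 + 0.002 * k; n <- 500 + 100 * k; eaf <- 0.1 + 0.05 * k
    expect_equal(f_statistic(variance_explained(beta, se, eaf, n), n),
                 (n - 2) * beta^2 / (n * se^2), tolerance = 1e-12)
  }
  # monotonicity: F increasing in R2 at fixed N; R2 increasing in |beta|
  r2s <- variance_explained(seq(0.05, 0.5, by = 0.05), 0.03, 0.4, 1539)
  expect_true(all(diff(r2s) > 0))
  expect_true(all(diff(f_statistic(seq(0, 0.5, by = 0.05), 1539)) > 0))
  expect_error(f_statistic(1, 100), "r2")
  expect_error(variance_explained(0.1, 0, 0.5, 100), "se")
})

test_that("strength summary flags weak instruments", {
  inst <- mr_instruments(paste0("rs", 1:3), beta_exp = c(0.12, 0.12, 0.12),
                         se_exp = 0.026, beta_out = rep(0.01, 3),
                         se_out = rep(0.03, 3), n_exp = rep(1539, 3))
  s <- strength_summary(inst)
  expect_equal(s$min_f, s$median_f)
  expect_false(s$weak_flag)

  weak <- mr_instruments(paste0("rs", 1:3), beta_exp = c(0.04, 0.2, 0.25),
                         se_exp = 0.013, beta_out = rep(0.01, 3),
                         se_out = rep(0.03, 3), n_exp = rep(1539, 3))
  expect_true(strength_summary(weak)$weak_flag)

  single <- subset_inst(inst, 1)
  s1 <- strength_summary(single)
  expect_equal(s1$min_f, s1$median_f)
  expect_equal(s1$n_snp, 1)
})
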