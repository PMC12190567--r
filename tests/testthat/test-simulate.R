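test_that("the generator is deterministic given the seed and config", {
  cfg <- sim_config(seed = 101, theta = 0.2,
                    mediator = list(beta1 = 0.3, beta2 = 0.2))
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$exposure$data, b$exposure$data)
  expect_identical(a$outcome$data, b$outcome$data)
  expect_identical(a$mediator$data, b$mediator$data)
  expect_identical(a$truth, b$truth)
  c <- simulate_study(sim_config(seed = 102, theta = 0.2,
                                 mediator = list(beta1 = 0.3, beta2 = 0.2)))
  expect_false(identical(a$exposure$data, c$exposure$data))
  # the generator never touches the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_study(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("generated tables pass summary-statistics validation (closed loop)", {
  s <- simulate_study(sim_config(seed = 5, theta = 0.1,
                                 mediator = list(beta1 = 0.3, beta2 = 0.2)))
  for (tab in list(s$exposure, s$outcome, s$mediator)) {
    expect_equal(nrow(tab$rejects), 0)
    expect_equal(tab$n_warnings, 0)
  }
  # every exposure instrument clears the selection thresholds by design
  sel <- select_instruments(s$exposure)
  expect_equal(nrow(sel), nrow(s$exposure$data))
  expect_true(all(s$exposure$data$pval < 1e-5))
  # outcome SEs reflect the case-control effective sample size
  expect_equal(s$truth$n_eff, 4 / (1 / 489 + 1 / 75531), tolerance = 1e-9)
})

test_that("noise-free valid instruments recover theta to machine precision", {
  s <- simulate_study(sim_config(seed = 9, theta = 0.17, noise_free = TRUE))
  df <- instruments_from_study(s)$data
  fit <- gutmr:::ivw_engine(df$beta_exp, df$beta_out, df$se_out, "fixed")
  expect_equal(fit$beta, 0.17, tolerance = 1e-12)
  wm <- gutmr:::weighted_median_point(df$beta_out / df$beta_exp,
                                      (df$beta_exp / df$se_out)^2)
  expect_equal(wm, 0.17, tolerance = 1e-12)
})

test_that("unreachable selection threshold fails with guidance", {
  expect_error(simulate_study(sim_config(seed = 1, gamma_sd = 1e-4)),
               "gamma_sd")
})

test_that("pleiotropy modes shape the planted effects as documented", {
  d <- simulate_study(sim_config(seed = 31, pleiotropy = list(
    mode = "directional", mean = 0.06, sd = 0, frac = 0.4)))
  expect_equal(length(d$truth$pleiotropy_idx), 8)  # 40% of 20
  # directional: same direction as the exposure-increasing allele
  a <- d$truth$alpha[d$truth$pleiotropy_idx]
  g <- d$truth$gamma[d$truth$pleiotropy_idx]
  expect_true(all(a * sign(g) > 0))
  expect_equal(abs(a), rep(0.06, 8), tolerance = 1e-12)
  b <- simulate_study(sim_config(seed = 32, pleiotropy = list(
    mode = "balanced", mean = 0, sd = 0.05)))
  expect_equal(length(b$truth$pleiotropy_idx), 20)
  n <- simulate_study(sim_config(seed = 33))
  expect_equal(n$truth$alpha, rep(0, 20))
  expect_length(n$truth$pleiotropy_idx, 0)
})

test_that("LD blocks exercise clumping down to one index SNP per block", {
  cfg <- sim_config(seed = 55, n_snp = 12,
                    ld_blocks = list(size = 3, r2 = 0.6))
  s <- simulate_study(cfg)
  expect_s3_class(s$ld, "ld_ref")
  cand <- select_instruments(s$exposure)
  kept <- ld_clump(cand, s$ld)
  # one SNP per block survives at r2 threshold 0.1 < 0.6
  expect_equal(nrow(kept), 4)
  expect_equal(length(unique(s$truth$block_id[match(kept$rsid,
                                                    s$exposure$data$rsid)])), 4)
})

test_that("feature panels are stable, unique, and sized as requested", {
  cfg <- sim_config(seed = 77, n_snp = 5)
  p1 <- simulate_feature_panel(cfg, n_features = 8, n_causal = 2,
                               theta_causal = 0.3)
  p2 <- simulate_feature_panel(cfg, n_features = 8, n_causal = 2,
                               theta_causal = 0.3)
  expect_equal(names(p1), sprintf("feature_%04d", 1:8))
  expect_identical(lapply(p1, function(s) s$exposure$data),
                   lapply(p2, function(s) s$exposure$data))
  expect_equal(vapply(p1, function(s) s$truth$theta, numeric(1)),
               setNames(c(0.3, 0.3, rep(0, 6)), names(p1)))
  single <- simulate_feature_panel(cfg, n_features = 1)
  expect_length(single, 1)
  expect_error(simulate_feature_panel(cfg, n_features = 2, n_causal = 3),
               "n_causal")
})

test_that("the mediator chain encodes the intended proportion mediated", {
  s <- simulate_study(sim_config(seed = 13, theta = 0.2,
                                 mediator = list(beta1 = 0.3, beta2 = 0.2)))
  expect_equal(s$truth$proportion, 0.3, tolerance = 1e-12)
  # mediator table carries both exposure instruments and its own
  expect_equal(nrow(s$mediator$data), 20 + 15)
  expect_equal(sum(grepl("^rsM", s$mediator$data$rsid)), 15)
  # outcome table covers both instrument sets
  expect_true(all(s$mediator$data$rsid %in% s$outcome$data$rsid |
                    !grepl("^rsM", s$mediator$data$rsid)))
})

test_that("calibration report returns rates with binomial intervals", {
  cfg <- sim_config(seed = 3, n_snp = 10, theta = 0)
  cr <- calibration_report(100, cfg, estimators = c("ivw_fixed", "egger"),
                           seed = 12)
  expect_s3_class(cr, "calibration_report")
  expect_equal(cr$estimator, c("ivw_fixed", "egger"))
  expect_true(all(cr$reject_low <= cr$reject_rate &
                    cr$reject_rate <= cr$reject_high))
  # null simulation: estimator means sit within Monte-Carlo error of zero
  expect_true(all(abs(cr$bias) < 4 * cr$mc_se))
  expect_error(calibration_report(10, cfg, seed = 1), "100")
})
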