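test_that("Cochran's Q matches the hand-worked example and is reorder-invariant", {
  inst <- mr_instruments(paste0("rs", 1:3), beta_exp = c(0.1, 0.2, 0.15),
                         se_exp = 0.03, beta_out = c(0.02, 0.05, 0.03),
                         se_out = c(0.01, 0.02, 0.015))
  q <- cochran_q(inst)
  expect_equal(q$q, 0.1666667, tolerance = 1e-6)
  expect_equal(q$df, 2)
  expect_equal(q$pval, 0.9200444, tolerance = 1e-6)
  q2 <- cochran_q(subset_inst(inst, c(3, 1, 2)))
  expect_equal(q2$q, q$q)
  # identical ratios: Q = 0, p = 1
  cons <- mr_instruments(paste0("rs", 1:3), beta_exp = c(0.1, 0.2, 0.15),
                         se_exp = 0.03, beta_out = 0.2 * c(0.1, 0.2, 0.15),
                         se_out = c(0.01, 0.02, 0.015))
  qc <- cochran_q(cons)
  expect_equal(qc$q, 0, tolerance = 1e-12)
  expect_equal(qc$pval, 1)
  expect_error(cochran_q(subset_inst(inst, 1)), "at least 2")
})

test_that("leave-one-out emits J + 1 rows and collapses under consensus", {
  cons <- mr_instruments(paste0("rs", 1:4), beta_exp = c(0.1, 0.2, 0.15, 0.3),
                         se_exp = 0.03, beta_out = 0.2 * c(0.1, 0.2, 0.15, 0.3),
                         se_out = rep(0.02, 4))
  loo <- leave_one_out(cons)
  expect_equal(nrow(loo), 5)
  expect_equal(loo$rsid[5], "(all)")
  expect_true(all(abs(loo$beta - 0.2) < 1e-12))
})

test_that("removing a planted outlier moves the estimate toward the truth", {
  study <- default_study(19, theta = 0.2,
                         contaminate = data.frame(index = 1, offset = 10))
  inst <- instruments_from_study(study)
  loo <- leave_one_out(inst)
  full <- loo$beta[loo$rsid == "(all)"]
  without <- loo$beta[loo$rsid == "rs0000001"]
  expect_lt(abs(without - 0.2), abs(full - 0.2))
})

test_that("funnel coordinates are one per instrument with NOME precision", {
  inst <- mr_instruments(paste0("rs", 1:3), beta_exp = c(0.1, 0.2, 0.15),
                         se_exp = 0.03, beta_out = c(0.02, 0.05, 0.03),
                         se_out = c(0.01, 0.02, 0.015))
  fc <- funnel_coordinates(inst)
  expect_equal(nrow(fc), 3)
  expect_equal(fc$ratio, inst$data$beta_out / inst$data$beta_exp)
  expect_equal(fc$precision, abs(inst$data$beta_exp) / inst$data$se_out)
  # precision grows as the outcome SE shrinks
  small <- mr_instruments("rs1", 0.1, 0.03, 0.02, 1e-5)
  expect_gt(funnel_coordinates(small)$precision, fc$precision[1])
  # weighted mean of ratios equals the IVW estimate (funnel symmetry center)
  w <- (inst$data$beta_exp / inst$data$se_out)^2
  expect_equal(sum(w * fc$ratio) / sum(w),
               gutmr:::ivw_engine(inst$data$beta_exp, inst$data$beta_out,
                                  inst$data$se_out, "fixed")$beta,
               tolerance = 1e-12)
})

test_that("MR-PRESSO is reproducible and respects its degenerate branches", {
  inst <- instruments_from_study(default_study(7, theta = 0.1))
  a <- mr_presso(inst, n_sim = 200, seed = 5)
  b <- mr_presso(inst, n_sim = 200, seed = 5)
  expect_identical(a$global_pval, b$global_pval)
  expect_identical(a$outlier_pvals, b$outlier_pvals)
  expect_gte(a$global_pval, 1 / 201)   # add-one: never exactly zero
  # clean data: no outliers, no distortion test, no corrected estimate
  expect_length(a$outlier_rsids, 0)
  expect_true(is.na(a$distortion_pval))
  expect_null(a$corrected)
  expect_error(mr_presso(subset_inst(inst, 1:3)), "at least 4")
})

test_that("MR-PRESSO flags a strongly contaminated instrument and corrects", {
  study <- default_study(23, theta = 0.2,
                         contaminate = data.frame(index = 2, offset = 10))
  inst <- instruments_from_study(study)
  pr <- mr_presso(inst, n_sim = 1000, seed = 11)
  expect_true("rs0000002" %in% pr$outlier_rsids)
  expect_lt(pr$global_pval, 0.05)
  expect_false(is.na(pr$distortion_pval))
  # corrected estimate equals plain IVW on the complement set
  keep <- !(inst$data$rsid %in% pr$outlier_rsids)
  manual <- gutmr:::ivw_engine(inst$data$beta_exp[keep],
                               inst$data$beta_out[keep],
                               inst$data$se_out[keep], model = "random")
  expect_equal(pr$corrected$beta, manual$beta, tolerance = 1e-12)
  expect_equal(pr$corrected$se, manual$se, tolerance = 1e-12)
})

test_that("sensitivity report bundles all diagnostics consistently", {
  inst <- instruments_from_study(default_study(3, theta = 0.15))
  rep <- mr_sensitivity(inst, n_sim = 200, seed = 2)
  expect_equal(rep$q$df, nrow(inst$data) - 1)
  expect_equal(nrow(rep$loo), nrow(inst$data) + 1)
  expect_equal(nrow(rep$funnel), nrow(inst$data))
  expect_true(all(rep$presso$outlier_rsids %in% inst$data$rsid))
  expect_output(print(rep), "Cochran's Q")
  # 3-instrument sets skip MR-PRESSO but keep the rest
  small <- subset_inst(inst, 1:3)
  rep3 <- mr_sensitivity(small, seed = 2)
  expect_null(rep3$presso)
  expect_equal(nrow(rep3$loo), 4)
})
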