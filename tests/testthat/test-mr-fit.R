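three_inst <- function() {
  mr_instruments(paste0("rs", 1:3), beta_exp = c(0.1, 0.2, 0.15),
                 se_exp = rep(0.03, 3), beta_out = c(0.02, 0.05, 0.03),
                 se_out = c(0.01, 0.02, 0.015))
}

test_that("Wald ratio arithmetic and orientation invariance", {
  wr <- wald_ratio(0.1, 0.02, 0.01)
  expect_equal(wr$beta, 0.2)
  expect_equal(wr$se, 0.1)
  expect_equal(wald_ratio(0.1, 0, 0.01)$beta, 0)
  flip <- wald_ratio(-0.1, -0.02, 0.01)
  expect_equal(flip$beta, wr$beta)
  expect_equal(flip$se, wr$se)
  expect_error(wald_ratio(0, 0.02, 0.01), "non-zero")
  # second-order SE exceeds the NOME SE
  so <- wald_ratio(0.1, 0.02, 0.01, se_exp = 0.03, second_order = TRUE)
  expect_gt(so$se, wr$se)
})

test_that("IVW reproduces the hand-computed worked example", {
  fit <- mr_fit(three_inst(), methods = "ivw", ivw_model = "fixed")
  est <- fit$estimates
  expect_equal(est$beta, 0.2166667, tolerance = 1e-6)
  expect_equal(est$se, 0.0577350, tolerance = 1e-6)
  expect_equal(est$or, exp(est$beta))
  expect_equal(fit$q$q, 0.1666667, tolerance = 1e-6)
  expect_equal(fit$q$df, 2)
  expect_equal(fit$q$pval, 0.9200444, tolerance = 1e-6)
})

test_that("IVW equals the common ratio when all ratios agree, any weights", {
  inst <- mr_instruments(paste0("rs", 1:4), beta_exp = c(0.1, 0.2, 0.3, 0.05),
                         se_exp = 0.02, beta_out = 0.2 * c(0.1, 0.2, 0.3, 0.05),
                         se_out = c(0.01, 0.05, 0.002, 0.03))
  for (model in c("fixed", "random")) {
    fit <- gutmr:::ivw_engine(inst$data$beta_exp, inst$data$beta_out,
                              inst$data$se_out, model = model)
    expect_equal(fit$beta, 0.2, tolerance = 1e-12)
  }
})

test_that("random-effects IVW never reports less uncertainty than fixed", {
  for (seed in 1:10) {
    df <- instruments_from_study(default_study(seed, theta = 0.1))$data
    f <- gutmr:::ivw_engine(df$beta_exp, df$beta_out, df$se_out, "fixed")
    r <- gutmr:::ivw_engine(df$beta_exp, df$beta_out, df$se_out, "random")
    expect_gte(r$se, f$se)
    expect_equal(r$beta, f$beta)
  }
})

test_that("MR-Egger recovers an exact linear relationship regardless of weights", {
  bx <- c(0.1, 0.2, 0.15, 0.3)
  inst <- mr_instruments(paste0("rs", 1:4), beta_exp = bx, se_exp = 0.02,
                         beta_out = 0.01 + 0.3 * bx,
                         se_out = c(0.01, 0.03, 0.02, 0.005))
  eg <- gutmr:::egger_engine(inst$data$beta_exp, inst$data$beta_out,
                             inst$data$se_out)
  expect_equal(eg$slope, 0.3, tolerance = 1e-12)
  expect_equal(eg$intercept, 0.01, tolerance = 1e-12)
  expect_error(gutmr:::egger_engine(rep(0.2, 4), rnorm(4), rep(0.01, 4)),
               "degenerate")
})

test_that("IVW and Egger agree with the brute-force WLS oracle", {
  for (case in 1:50) {
    dat <- with_seed_test(case, {
      J <- sample(3:40, 1)
      list(bx = rnorm(J, 0.2, 0.1) + 0.05, by = rnorm(J, 0.05, 0.05),
           sy = runif(J, 0.005, 0.05))
    })
    ivw <- gutmr:::ivw_engine(dat$bx, dat$by, dat$sy, model = "fixed")
    o1 <- wls_oracle(matrix(dat$bx), dat$by, 1 / dat$sy^2)
    expect_equal(ivw$beta, unname(o1$coef), tolerance = 1e-10)
    expect_equal(ivw$se, sqrt(o1$vcov_fixed[1, 1]), tolerance = 1e-10)

    s <- sign(dat$bx)
    eg <- gutmr:::egger_engine(dat$bx, dat$by, dat$sy)
    o2 <- wls_oracle(cbind(1, dat$bx * s), dat$by * s, 1 / dat$sy^2)
    expect_equal(eg$intercept, unname(o2$coef[1]), tolerance = 1e-10)
    expect_equal(eg$slope, unname(o2$coef[2]), tolerance = 1e-10)
    expect_equal(eg$se_intercept, sqrt(o2$vcov[1, 1]), tolerance = 1e-10)
    expect_equal(eg$se_slope, sqrt(o2$vcov[2, 2]), tolerance = 1e-10)
  }
})

test_that("Egger with the intercept forced to zero is exactly IVW", {
  df <- three_inst()$data
  o <- wls_oracle(matrix(df$beta_exp), df$beta_out, 1 / df$se_out^2)
  ivw <- gutmr:::ivw_engine(df$beta_exp, df$beta_out, df$se_out, "fixed")
  expect_equal(ivw$beta, unname(o$coef), tolerance = 1e-12)
})

test_that("Egger intercept vanishes as instrument count grows without pleiotropy", {
  df <- instruments_from_study(default_study(3, theta = 0.2, n_snp = 2000))$data
  eg <- gutmr:::egger_engine(df$beta_exp, df$beta_out, df$se_out)
  expect_lt(abs(eg$intercept), 3 * eg$se_intercept)
  expect_lt(abs(eg$intercept), 0.005)
})

test_that("weighted median interpolation matches hand-worked values", {
  expect_equal(gutmr:::weighted_median_point(c(0.1, 0.2, 0.3), c(1, 1, 1)), 0.2)
  expect_equal(gutmr:::weighted_median_point(c(0.1, 0.2, 0.3),
                                             c(0.25, 0.25, 0.5)),
               0.2333333, tolerance = 1e-6)
  # majority of weight on one ratio pins the estimate there
  expect_equal(gutmr:::weighted_median_point(c(0.1, 0.5, 0.5, 0.9),
                                             c(0.2, 0.3, 0.3, 0.2)), 0.5)
  # order of input does not matter
  expect_equal(gutmr:::weighted_median_point(c(0.3, 0.1, 0.2),
                                             c(0.5, 0.25, 0.25)),
               0.2333333, tolerance = 1e-6)
})

test_that("weighted median bootstrap is seeded and reproducible", {
  inst <- three_inst()
  a <- mr_fit(inst, methods = "weighted_median", seed = 42)
  b <- mr_fit(inst, methods = "weighted_median", seed = 42)
  c <- mr_fit(inst, methods = "weighted_median", seed = 43)
  expect_identical(a$estimates$se, b$estimates$se)
  expect_false(identical(a$estimates$se, c$estimates$se))
})

test_that("rescaling the exposure rescales every causal estimate by 1/c", {
  df <- instruments_from_study(default_study(8, theta = 0.15))$data
  cscale <- 2.5
  fit1 <- mr_fit(mr_instruments(df$rsid, df$beta_exp, df$se_exp, df$beta_out,
                                df$se_out), seed = 5)
  fit2 <- mr_fit(mr_instruments(df$rsid, cscale * df$beta_exp,
                                cscale * df$se_exp, df$beta_out, df$se_out),
                 seed = 5)
  for (m in c("IVW", "MR-Egger", "Weighted median")) {
    b1 <- fit1$estimates$beta[fit1$estimates$method == m]
    b2 <- fit2$estimates$beta[fit2$estimates$method == m]
    expect_equal(b2, b1 / cscale, tolerance = 1e-8)
  }
  # the Egger intercept (outcome-scale pleiotropy) is unchanged
  i1 <- fit1$estimates$beta[fit1$estimates$method == "MR-Egger intercept"]
  i2 <- fit2$estimates$beta[fit2$estimates$method == "MR-Egger intercept"]
  expect_equal(i1, i2, tolerance = 1e-10)
})

test_that("mr_fit object obeys its contract and methods work", {
  fit <- mr_fit(three_inst(), seed = 2)
  est <- fit$estimates
  expect_true(all(est$ci_low <= est$beta & est$beta <= est$ci_high))
  expect_equal(est$or, exp(est$beta))
  expect_true(all(est$pval > 0 & est$pval <= 1))
  expect_named(coef(fit), est$method)
  ci <- confint(fit)
  expect_equal(unname(ci[, 1]), est$ci_low)
  expect_equal(length(residuals(fit)), 3)
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "mr_instruments")
  expect_output(print(summary(fit)), "Cochran's Q")
  # too few instruments is a hard error
  expect_error(mr_fit(subset_inst(three_inst(), 1:2), methods = "egger"),
               "at least 3")
  expect_error(mr_fit(subset_inst(three_inst(), 1), methods = "ivw"),
               "at least 2")
})
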