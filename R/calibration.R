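#' Operating characteristics of the MR estimators by simulation
#'
#' Repeatedly simulates a study from `config` and applies the estimator
#' suite, reporting empirical rejection rate (type-I error when
#' `config$theta == 0`, power otherwise) with exact binomial 95% intervals,
#' bias, RMSE and CI coverage per estimator.
#'
#' `"ivw_fixed"` is the fixed-effect z-test (the exactly calibrated nominal
#' test); `"ivw_random"` is the default multiplicative-random-effects model,
#' whose SE is floored at the fixed-effect SE and whose test is therefore
#' conservative under homogeneity. `"egger"`/`"egger_intercept"` use the
#' t-test with J-2 df; the intercept's target value is the mean planted
#' pleiotropy (zero unless directional). `"weighted_median"` uses the
#' bootstrap-SE normal test and `"presso_global"` the simulation p-value of
#' the MR-PRESSO global test (rejection only; no estimate).
#'
#' @param replicates number of simulated studies (>= 100).
#' @param config a `"sim_config"`; per-replicate seeds derive from `seed`.
#' @param estimators subset of `c("ivw_fixed", "ivw_random", "egger",
#'   "egger_intercept", "weighted_median", "presso_global")`.
#' @param alpha nominal two-sided level.
#' @param seed master seed for the simulation stream.
#' @param n_boot weighted-median bootstrap replicates per study.
#' @param n_sim MR-PRESSO simulations per study.
#' @return An object of class `"calibration_report"`: data.frame with one row
#'   per estimator (`reject_rate`, `reject_low`, `reject_high`, `bias`,
#'   `rmse`, `coverage`, `coverage_low`, `coverage_high`, `replicates`).
#' @export
calibration_report <- function(replicates, config,
                               estimators = c("ivw_fixed", "ivw_random",
                                              "egger", "egger_intercept",
                                              "weighted_median",
                                              "presso_global"),
                               alpha = 0.05, seed = 1, n_boot = 1000,
                               n_sim = 1000) {
  stopifnot(inherits(config, "sim_config"))
  if (replicates < 100) stop("use at least 100 replicates", call. = FALSE)
  estimators <- match.arg(estimators, several.ok = TRUE)
  theta <- config$theta
  pl <- config$pleiotropy
  intercept_target <- if (pl$mode == "directional") pl$mean * pl$frac else 0

  est_names <- estimators
  beta_mat <- matrix(NA_real_, replicates, length(est_names),
                     dimnames = list(NULL, est_names))
  rej_mat <- cover_mat <- matrix(NA, replicates, length(est_names),
                                 dimnames = list(NULL, est_names))

  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, r)
    inst <- instruments_from_study(simulate_study(cfg))
    df <- inst$data
    bx <- df$beta_exp; by <- df$beta_out; sx <- df$se_exp; sy <- df$se_out
    J <- length(bx)

    if (any(c("ivw_fixed", "ivw_random") %in% est_names)) {
      fit_f <- ivw_engine(bx, by, sy, model = "fixed")
      if ("ivw_fixed" %in% est_names) {
        beta_mat[r, "ivw_fixed"] <- fit_f$beta
        rej_mat[r, "ivw_fixed"] <- fit_f$pval < alpha
        cover_mat[r, "ivw_fixed"] <-
          abs(fit_f$beta - theta) <= stats::qnorm(1 - alpha / 2) * fit_f$se
      }
      if ("ivw_random" %in% est_names) {
        infl <- if (J > 2) max(1, sqrt(fit_f$q / (J - 1))) else 1
        se_r <- fit_f$se_fixed * infl
        beta_mat[r, "ivw_random"] <- fit_f$beta
        rej_mat[r, "ivw_random"] <- z_pvalue(fit_f$beta / se_r) < alpha
        cover_mat[r, "ivw_random"] <-
          abs(fit_f$beta - theta) <= stats::qnorm(1 - alpha / 2) * se_r
      }
    }
    if (any(c("egger", "egger_intercept") %in% est_names)) {
      eg <- egger_engine(bx, by, sy)
      tq <- stats::qt(1 - alpha / 2, eg$df)
      if ("egger" %in% est_names) {
        beta_mat[r, "egger"] <- eg$slope
        rej_mat[r, "egger"] <- eg$pval_slope < alpha
        cover_mat[r, "egger"] <- abs(eg$slope - theta) <= tq * eg$se_slope
      }
      if ("egger_intercept" %in% est_names) {
        beta_mat[r, "egger_intercept"] <- eg$intercept
        rej_mat[r, "egger_intercept"] <- eg$pval_intercept < alpha
        cover_mat[r, "egger_intercept"] <-
          abs(eg$intercept - intercept_target) <= tq * eg$se_intercept
      }
    }
    if ("weighted_median" %in% est_names) {
      wm <- weighted_median_engine(bx, by, sx, sy, n_boot = n_boot,
                                   seed = derive_seed(seed, r + replicates))
      beta_mat[r, "weighted_median"] <- wm$beta
      rej_mat[r, "weighted_median"] <- wm$pval < alpha
      cover_mat[r, "weighted_median"] <-
        abs(wm$beta - theta) <= stats::qnorm(1 - alpha / 2) * wm$se
    }
    if ("presso_global" %in% est_names && J >= 4) {
      pr <- mr_presso(inst, n_sim = n_sim,
                      seed = derive_seed(seed, r + 2L * replicates))
      rej_mat[r, "presso_global"] <- pr$global_pval < alpha
    }
  }

  target <- ifelse(est_names == "egger_intercept", intercept_target, theta)
  rows <- lapply(seq_along(est_names), function(k) {
    rej <- rej_mat[, k]
    rej <- rej[!is.na(rej)]
    ci <- stats::binom.test(sum(rej), length(rej))$conf.int
    bet <- beta_mat[, k]
    has_beta <- any(!is.na(bet))
    cov <- cover_mat[, k]
    cov <- cov[!is.na(cov)]
    cci <- if (length(cov)) stats::binom.test(sum(cov), length(cov))$conf.int
           else c(NA_real_, NA_real_)
    data.frame(
      estimator = est_names[k], replicates = length(rej),
      reject_rate = mean(rej), reject_low = ci[1], reject_high = ci[2],
      bias = if (has_beta) mean(bet, na.rm = TRUE) - target[k] else NA_real_,
      rmse = if (has_beta) sqrt(mean((bet - target[k])^2, na.rm = TRUE))
             else NA_real_,
      mc_se = if (has_beta) stats::sd(bet, na.rm = TRUE) /
                sqrt(sum(!is.na(bet))) else NA_real_,
      coverage = if (length(cov)) mean(cov) else NA_real_,
      coverage_low = cci[1], coverage_high = cci[2],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("calibration_report", "data.frame")
  attr(out, "theta") <- theta
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration over %d replicate(s), theta = %g, alpha = %g\n",
              max(x$replicates), attr(x, "theta"), attr(x, "alpha")))
  df <- as.data.frame(x)
  df[, -1] <- lapply(df[, -1], function(col) signif(col, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
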