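#' Cochran's Q heterogeneity test
#'
#' Q = sum over instruments of w_j (r_j - beta_IVW)^2 with r_j the Wald ratios
#' and w_j = beta_exp_j^2 / se_out_j^2 their inverse variances (NOME), which
#' equals the weighted residual sum of squares of the fixed-effect IVW
#' regression; p from chi-square with J - 1 df.
#'
#' @param instruments an `"mr_instruments"` object (>= 2 instruments).
#' @return list with `q`, `df`, `pval`.
#' @export
cochran_q <- function(instruments) {
  stopifnot(inherits(instruments, "mr_instruments"))
  df <- instruments$data
  fit <- ivw_engine(df$beta_exp, df$beta_out, df$se_out, model = "fixed")
  list(q = fit$q, df = fit$df,
       pval = stats::pchisq(fit$q, fit$df, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimate excluding each instrument in turn, plus the
#' all-instrument estimate as a reference row (`rsid = "(all)"`).
#'
#' @param instruments an `"mr_instruments"` object (>= 3 instruments).
#' @param ivw_model IVW model passed through.
#' @return data.frame with columns `rsid`, `beta`, `se`, `pval`.
#' @export
leave_one_out <- function(instruments, ivw_model = c("random", "fixed")) {
  stopifnot(inherits(instruments, "mr_instruments"))
  ivw_model <- match.arg(ivw_model)
  df <- instruments$data
  J <- nrow(df)
  if (J < 3L) stop("leave-one-out requires at least 3 instruments", call. = FALSE)
  one <- function(idx) {
    keep <- setdiff(seq_len(J), idx)
    ivw_engine(df$beta_exp[keep], df$beta_out[keep], df$se_out[keep],
               model = ivw_model)
  }
  fits <- lapply(seq_len(J), one)
  full <- ivw_engine(df$beta_exp, df$beta_out, df$se_out, model = ivw_model)
  data.frame(
    rsid = c(df$rsid, "(all)"),
    beta = c(vapply(fits, `[[`, numeric(1), "beta"), full$beta),
    se = c(vapply(fits, `[[`, numeric(1), "se"), full$se),
    pval = c(vapply(fits, `[[`, numeric(1), "pval"), full$pval),
    stringsAsFactors = FALSE
  )
}

#' Funnel-plot coordinates
#'
#' Per-SNP Wald ratio and its precision (1/se of the ratio, NOME
#' approximation). Coordinates only; no rendering.
#'
#' @param instruments an `"mr_instruments"` object (>= 1 instrument).
#' @return data.frame with columns `rsid`, `ratio`, `precision`.
#' @export
funnel_coordinates <- function(instruments) {
  stopifnot(inherits(instruments, "mr_instruments"))
  df <- instruments$data
  if (nrow(df) < 1L) stop("empty instrument set", call. = FALSE)
  data.frame(rsid = df$rsid,
             ratio = df$beta_out / df$beta_exp,
             precision = abs(df$beta_exp) / df$se_out,
             stringsAsFactors = FALSE)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Global test: the observed residual sum of squares
#' RSS = sum_j w_j (beta_out_j - b(-j) * beta_exp_j)^2, where b(-j) is the
#' leave-one-out fixed-effect IVW slope and w_j = 1/se_out_j^2, is compared
#' with a null distribution obtained by simulating
#' beta_out_j* ~ Normal(b(-j) * beta_exp_j, se_out_j) `n_sim` times and
#' recomputing RSS; the empirical p-value carries an add-one pseudo-count so
#' finite simulation never reports p = 0. Outlier test: each SNP's observed
#' weighted squared residual is referred to its own simulated residual
#' distribution, two-sided via the squared residual, Bonferroni-corrected
#' across instruments; SNPs below `outlier_alpha` are flagged. Distortion
#' test: the relative difference between the all-SNP and outlier-removed IVW
#' estimates is compared with the distribution obtained by re-removing
#' randomly chosen non-outlier sets of the same size. The corrected estimate
#' is IVW on the unflagged instruments (absent when no or all SNPs are
#' flagged).
#'
#' @param instruments an `"mr_instruments"` object (>= 4 instruments).
#' @param n_sim simulated replicates for the global/outlier null (default 1000).
#' @param outlier_alpha flagging threshold on Bonferroni-corrected p (0.05).
#' @param seed master seed; the distortion test derives its own sub-seed.
#' @param ivw_model model for the corrected estimate.
#' @return An object of class `"mr_presso"`: list with `global_rss_obs`,
#'   `global_pval`, `outlier_pvals` (Bonferroni-corrected, named),
#'   `outlier_rsids`, `distortion_pval`, `corrected` (an estimate row or
#'   `NULL`) and `n_sim`.
#' @export
mr_presso <- function(instruments, n_sim = 1000, outlier_alpha = 0.05,
                      seed = 1, ivw_model = c("random", "fixed")) {
  stopifnot(inherits(instruments, "mr_instruments"))
  ivw_model <- match.arg(ivw_model)
  df <- instruments$data
  J <- nrow(df)
  if (J < 4L) stop("MR-PRESSO requires at least 4 instruments", call. = FALSE)
  bx <- df$beta_exp; by <- df$beta_out; sy <- df$se_out
  w <- 1 / sy^2
  sxx <- sum(w * bx^2)
  sxy <- sum(w * bx * by)
  b_loo <- (sxy - w * bx * by) / (sxx - w * bx^2)
  resid_obs <- by - b_loo * bx
  d_obs <- w * resid_obs^2
  rss_obs <- sum(d_obs)

  sim <- with_seed(seed, {
    mu <- b_loo * bx
    bys <- matrix(stats::rnorm(J * n_sim, mu, sy), nrow = J)
    sxy_s <- colSums(w * bx * bys)
    # per-sim leave-one-out slopes, vectorized over the J x n_sim grid
    b_loo_s <- sweep(-(w * bx) * bys, 2, sxy_s, "+") / (sxx - w * bx^2)
    resid_s <- bys - b_loo_s * bx
    d_s <- w * resid_s^2
    list(rss = colSums(d_s), d = d_s)
  })
  global_pval <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)
  outlier_raw <- (1 + rowSums(sim$d >= d_obs)) / (n_sim + 1)
  outlier_pvals <- stats::setNames(pmin(1, outlier_raw * J), df$rsid)
  flagged <- outlier_pvals < outlier_alpha
  outlier_rsids <- df$rsid[flagged]

  corrected <- NULL
  distortion_pval <- NA_real_
  if (any(flagged) && !all(flagged)) {
    keep <- which(!flagged)
    fit_all <- ivw_engine(bx, by, sy, model = ivw_model)
    fit_cor <- ivw_engine(bx[keep], by[keep], sy[keep], model = ivw_model)
    corrected <- estimate_row("IVW (outlier-corrected)", fit_cor$beta,
                              fit_cor$se, fit_cor$pval,
                              fit_cor$beta - 1.96 * fit_cor$se,
                              fit_cor$beta + 1.96 * fit_cor$se, fit_cor$n_snp)
    n_out <- sum(flagged)
    denom <- max(abs(fit_cor$beta), .Machine$double.eps)
    d_obs_stat <- (fit_all$beta - fit_cor$beta) / denom
    n_d <- 1000L
    d_null <- with_seed(derive_seed(seed, 1L), {
      vapply(seq_len(n_d), function(b) {
        pseudo <- sample(keep, n_out, replace = TRUE)
        rest <- setdiff(seq_len(J), pseudo)
        if (length(rest) < 2L) return(NA_real_)
        fb <- ivw_engine(bx[rest], by[rest], sy[rest], model = ivw_model)
        (fit_all$beta - fb$beta) / max(abs(fb$beta), .Machine$double.eps)
      }, numeric(1))
    })
    d_null <- d_null[is.finite(d_null)]
    distortion_pval <- (1 + sum(abs(d_null) >= abs(d_obs_stat))) /
      (length(d_null) + 1)
  }

  structure(list(global_rss_obs = rss_obs, global_pval = global_pval,
                 outlier_pvals = outlier_pvals, outlier_rsids = outlier_rsids,
                 distortion_pval = distortion_pval, corrected = corrected,
                 n_sim = n_sim, seed = seed, all_flagged = all(flagged)),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS %.4g, p = %.4g (%d simulations)\n",
              x$global_rss_obs, x$global_pval, x$n_sim))
  if (length(x$outlier_rsids)) {
    cat("  outliers:", paste(x$outlier_rsids, collapse = ", "),
        sprintf(" (distortion p = %.4g)\n", x$distortion_pval))
  } else {
    cat("  no outliers flagged; distortion test not run\n")
  }
  invisible(x)
}

#' Full sensitivity report for one exposure-outcome pair
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, leave-one-out IVW
#' estimates, funnel coordinates and (when at least 4 instruments are
#' available) MR-PRESSO.
#'
#' @param instruments an `"mr_instruments"` object (>= 3 instruments).
#' @param n_sim,outlier_alpha,seed passed to [mr_presso()].
#' @param ivw_model IVW model used throughout.
#' @return An object of class `"mr_sensitivity"` with elements `q`,
#'   `egger_intercept`, `loo`, `funnel`, `presso` (`NULL` if too few
#'   instruments) and `n_snp`.
#' @export
mr_sensitivity <- function(instruments, n_sim = 1000, outlier_alpha = 0.05,
                           seed = 1, ivw_model = c("random", "fixed")) {
  stopifnot(inherits(instruments, "mr_instruments"))
  ivw_model <- match.arg(ivw_model)
  df <- instruments$data
  if (nrow(df) < 3L) {
    stop("sensitivity analysis requires at least 3 instruments", call. = FALSE)
  }
  eg <- egger_engine(df$beta_exp, df$beta_out, df$se_out)
  presso <- if (nrow(df) >= 4L) {
    mr_presso(instruments, n_sim = n_sim, outlier_alpha = outlier_alpha,
              seed = seed, ivw_model = ivw_model)
  } else NULL
  structure(list(
    exposure_id = instruments$exposure_id,
    outcome_id = instruments$outcome_id,
    q = cochran_q(instruments),
    egger_intercept = list(estimate = eg$intercept, se = eg$se_intercept,
                           pval = eg$pval_intercept),
    loo = leave_one_out(instruments, ivw_model = ivw_model),
    funnel = funnel_coordinates(instruments),
    presso = presso,
    n_snp = nrow(df)
  ), class = "mr_sensitivity")
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat(sprintf("Sensitivity report: %s -> %s (%d instruments)\n",
              x$exposure_id, x$outcome_id, x$n_snp))
  cat(sprintf("  Cochran's Q %.4g on %d df (p = %.4g)\n",
              x$q$q, x$q$df, x$q$pval))
  cat(sprintf("  Egger intercept %.4g (se %.4g, p = %.4g)\n",
              x$egger_intercept$estimate, x$egger_intercept$se,
              x$egger_intercept$pval))
  if (!is.null(x$presso)) print(x$presso) else
    cat("  MR-PRESSO skipped (fewer than 4 instruments)\n")
  invisible(x)
}
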