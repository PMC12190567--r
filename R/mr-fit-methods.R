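#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR fit: %s -> %s (%d instruments, IVW model: %s)\n",
              x$instruments$exposure_id, x$instruments$outcome_id,
              nrow(x$instruments$data), x$ivw_model))
  est <- x$estimates
  est_fmt <- data.frame(method = est$method, n_snp = est$n_snp,
                        beta = signif(est$beta, digits),
                        se = signif(est$se, digits),
                        or = signif(est$or, digits),
                        ci95 = sprintf("[%s, %s]", signif(est$or_lci95, digits),
                                       signif(est$or_uci95, digits)),
                        pval = signif(est$pval, digits))
  print(est_fmt, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat(sprintf("\nCochran's Q: %.4g on %d df (p = %.4g)\n",
              fit$q$q, fit$q$df, fit$q$pval))
  int <- fit$estimates[fit$estimates$method == "MR-Egger intercept", ]
  if (nrow(int)) {
    cat(sprintf("Egger intercept: %.4g (se %.4g, p = %.4g)\n",
                int$beta, int$se, int$pval))
  }
  s <- strength_summary(fit$instruments)
  cat(sprintf("Instrument strength: min F %.4g, median F %.4g, total R2 %.4g%s\n",
              s$min_f, s$median_f, s$total_r2,
              if (s$weak_flag) "  [weak-instrument warning: min F < 10]" else ""))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  est <- object$estimates
  out <- cbind(est$ci_low, est$ci_high)
  dimnames(out) <- list(est$method,
                        sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Diagnostic plots for an MR fit
#'
#' `which = "scatter"` draws outcome vs exposure effects with the IVW line
#' through the origin and the MR-Egger line (when fitted); `which = "funnel"`
#' draws per-SNP Wald ratios against their precision with the IVW estimate as
#' a vertical reference.
#'
#' @param x an `"mr_fit"` object.
#' @param which `"scatter"` or `"funnel"`.
#' @param ... passed to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.mr_fit <- function(x, which = c("scatter", "funnel"), ...) {
  which <- match.arg(which)
  df <- x$instruments$data
  est <- x$estimates
  ivw_beta <- est$beta[est$method == "IVW"][1]
  if (which == "scatter") {
    s <- ifelse(df$beta_exp < 0, -1, 1)
    bx <- df$beta_exp * s
    by <- df$beta_out * s
    graphics::plot(bx, by, xlab = "SNP effect on exposure (oriented)",
                   ylab = "SNP effect on outcome",
                   main = sprintf("%s -> %s", x$instruments$exposure_id,
                                  x$instruments$outcome_id), ...)
    graphics::segments(bx, by - 1.96 * df$se_out, bx, by + 1.96 * df$se_out,
                       col = "grey70")
    if (!is.na(ivw_beta)) graphics::abline(0, ivw_beta, col = "steelblue")
    eg <- est[est$method == "MR-Egger", ]
    egi <- est[est$method == "MR-Egger intercept", ]
    if (nrow(eg) && nrow(egi)) {
      graphics::abline(egi$beta, eg$beta, col = "firebrick", lty = 2)
    }
  } else {
    fc <- funnel_coordinates(x$instruments)
    graphics::plot(fc$ratio, fc$precision, xlab = "Wald ratio",
                   ylab = "Precision (1/se)", main = "Funnel", ...)
    if (!is.na(ivw_beta)) graphics::abline(v = ivw_beta, col = "steelblue")
  }
  invisible(x)
}

#' Simulate outcome associations from a fitted MR model
#'
#' Draws new SNP-outcome effects under the fitted IVW causal slope,
#' `beta_out* ~ Normal(beta_ivw * beta_exp, se_out)`, returning instrument
#' sets that can be refitted — a parametric-bootstrap building block.
#'
#' @param object an `"mr_fit"` object.
#' @param nsim number of simulated instrument sets.
#' @param seed seed for the draws.
#' @param ... unused.
#' @return list of `"mr_instruments"` objects of length `nsim`.
#' @export
simulate.mr_fit <- function(object, nsim = 1, seed = 1, ...) {
  df <- object$instruments$data
  est <- object$estimates
  beta <- est$beta[est$method == "IVW"][1]
  if (is.na(beta)) stop("simulate() requires an IVW fit", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      out <- object$instruments
      out$data$beta_out <- stats::rnorm(nrow(df), beta * df$beta_exp, df$se_out)
      out
    })
  })
}

#' Residuals of an MR fit
#'
#' Weighted IVW residuals `(beta_out - beta_ivw * beta_exp) / se_out`.
#'
#' @param object an `"mr_fit"` object.
#' @param ... unused.
#' @return named numeric vector, one value per instrument.
#' @export
residuals.mr_fit <- function(object, ...) {
  df <- object$instruments$data
  est <- object$estimates
  beta <- est$beta[est$method == "IVW"][1]
  stats::setNames((df$beta_out - beta * df$beta_exp) / df$se_out, df$rsid)
}
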